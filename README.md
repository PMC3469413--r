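# phasecode

**phasecode** asks a concrete question about neural coding: when a sensory
cortical neuron responds to a long dynamic stimulus, how much of the
information carried by the *temporal pattern* of its spikes can a downstream
circuit read out using the phase of a slow network oscillation as its clock,
instead of a millisecond-precise stimulus-locked clock it has no access to?

The package is written for computational neuroscientists who want to run the
full comparison pipeline — response partitioning, single-trial decoding,
robustness analyses — on synthetic data with controlled ground truth, or on
their own spike + LFP recordings.

## The codes and the decoder

Within a response window of length *T* (default 160 ms), three codes are
built from the same spikes:

| code | definition |
|---|---|
| time-partitioned | counts **r** = (r₁…r_N) in N stimulus-locked time bins |
| phase-partitioned | counts **x** = (x₁…x_N) in N bins of the 2–6 Hz LFP phase at each spike time |
| spike count | total count in *T* (scalar, or bin-shuffled N-vector) |
| dual | concatenation (**r**, **x**), for redundancy analysis |

K = 10 non-overlapping epochs sampled from the stimulus stream act as the
stimulus classes; the stream's repeats are the trials. Each trial is decoded
by leave-one-out template matching,

&nbsp;&nbsp;&nbsp;&nbsp;ŝ = argminᵢ ‖ r_test − r̄ⁱ ‖,

with the test trial excluded from its own class mean, and results are
averaged over independently re-sampled epoch sets. Six classifiers share
the same harness (nearest mean, linear and quadratic Gaussian
discriminants, Poisson and multinomial naive Bayes, k-NN). Robustness
experiments jitter the codebook windows by uniform lags in ±J/2 (temporal
uncertainty), sweep the LFP band from 4 to 32 Hz, sweep T and N, and mix a
trial-unique background-noise component into the firing rate at +6/0/−6 dB
relative to the stimulus profile.

Because the original primate recordings are not public, the package
includes a first-class synthetic generator: an LFP whose theta-band phase
is partially entrained to the stimulus across trials (von Mises trial
offsets with concentration κ), and inhomogeneous-Poisson spikes whose rate
follows both a smooth stimulus profile and the oscillation phase. The
methods vignette (`vignettes/phase-partitioned-decoding.Rmd`) documents the
model, every parameter, and all numerical conventions.

## Worked example

```r
library(phasecode)

cfg <- standard_unit_config(seed = 1)   # strongly entrained 4 Hz unit
rec <- generate_recording(cfg)
rec
#> <recording> 30 trials x 12000 ms, 120.9 spikes/trial on average

ph <- extract_phase(rec, filter_spec("butterworth", 2, 6))
round(window_coherence(ph, 3000, 160), 3) # inter-trial phase coherence
#> [1] 0.951

codes <- list(code_spec("time"), code_spec("phase"),
              code_spec("count_scalar"), code_spec("dual"))
res <- run_comparison(rec, codes, classifier = "nearest_mean",
                      K = 10, n_sets = 10, seed = 1)
glance(res)
#> # A tibble: 4 × 5
#>   code         classifier   mean_pc   sem n_sets
#>   <chr>        <chr>          <dbl> <dbl>  <int>
#> 1 count_scalar nearest_mean    14.3 0.964     10
#> 2 dual         nearest_mean    31.2 1.18      10
#> 3 phase        nearest_mean    23.7 1.37      10
#> 4 time         nearest_mean    25.8 1.14      10
```

Chance is 10% (one of ten epochs). Both partitioned codes decode far above
the bare spike count (time 25.8%, phase 23.7%, count 14.3%): the phase of
the entrained oscillation recovers most of the stimulus information that
stimulus-locked time bins see. `unit_summary()` turns these into the
derived metrics — here an excess of 9.4 points for the phase code against
11.5 for the time code (a relative excess of 82%), and a chance-subtracted
phase/count ratio of 3.2.

Temporal uncertainty reverses the ranking, the signature phenomenon:

```r
jit <- jitter_sweep(rec, codes[1:3], J_values = c(0, 80, 160),
                    n_sets = 5, seed = 1)
tidyr::pivot_wider(glance(jit)[, c("code", "jitter_ms", "mean_pc")],
                   names_from = jitter_ms, values_from = mean_pc)
#> # A tibble: 3 × 4
#>   code           `0`  `80` `160`
#>   <chr>        <dbl> <dbl> <dbl>
#> 1 count_scalar  14.1  14.1  13.2
#> 2 phase         23.1  22.6  20.2
#> 3 time          24.1  19.3  14
```

With a codebook blurred by ±40 ms (J = 80), the time-partitioned code has
lost five points while the phase-partitioned code barely moves; at J = 160
the time code is close to the bare count. A reference frame carried by the
network's own oscillation survives temporal uncertainty that destroys a
stimulus-locked one.

Other entry points: `frequency_sweep()` (band specificity of the phase
code), `parameter_sweep()` (T and N), `noise_level_experiment()`
(background noise), `coherence_performance()` (ITC vs. accuracy),
`population_tests()` (across-unit statistics), and `autoplot()` methods on
every result object.

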