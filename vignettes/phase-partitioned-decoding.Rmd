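---
title: "Comparing time-binned, phase-binned and spike-count neural codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing time-binned, phase-binned and spike-count neural codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Sensory cortical responses to dynamic natural stimuli carry information in
temporal spike patterns on the scale of tens of milliseconds. Reading such a
pattern requires a temporal reference frame. An *external* reference — time
bins locked precisely to stimulus onset — is the conventional analysis
choice, but a downstream neural circuit has no direct access to stimulus
time. Slow network oscillations (delta/theta, here the 2–6 Hz band of the
local field potential) entrain to dynamic stimuli, so their instantaneous
phase is a network-*intrinsic* copy of the stimulus clock. This package
quantifies how much stimulus information each reference frame supports, by
single-trial decoding of three codes built from the same response window of
length $T$:

* **time-partitioned**: spike counts $\mathbf r = (r_1,\dots,r_N)$ in $N$
  equally spaced, stimulus-locked time bins of $[0,T)$;
* **phase-partitioned**: spike counts $\mathbf x = (x_1,\dots,x_N)$ in $N$
  equally spaced bins of the oscillation phase $[0,2\pi)$, each spike
  assigned by the instantaneous phase at its spike time;
* **spike count**: the total count in $T$, as a scalar or as a bin-shuffled
  $N$-vector (same information, same dimensionality as the partitioned
  codes; decoding averaged over 20 shuffles);
* a **dual** code (concatenation $(\mathbf r, \mathbf x)$) measures how
  redundant the two partitioned codes are.

Decoding follows the standard template-matching design: $K = 10$
non-overlapping epochs of length $T$ are sampled from the continuous
stimulus stream and act as the stimulus classes; the repeats of the stream
are the trials. Each trial is decoded by leave-one-out cross-validation
against the per-epoch mean responses (the codebook),

$$\hat s = \arg\min_i \; \lVert \mathbf r^{\text{test}} -
\bar{\mathbf r}^i \rVert_2 ,$$

with the test trial excluded from its own class mean, and performance is the
percent of correctly decoded trials averaged over independently re-sampled
epoch sets. Besides nearest-mean matching, the same leave-one-out harness
runs linear and quadratic Gaussian discriminants, Poisson and multinomial
naive Bayes, and a k-nearest-neighbour vote, so that conclusions about codes
are not conclusions about one classifier.

## The synthetic generator

No public recordings exist for this paradigm, so the package ships a
generator whose output has the statistical structure the analysis assumes,
with every assumption exposed as a parameter ([`generator_config()`]):

* One stimulus-locked phase trajectory $\varphi^\ast(t)$ is drawn per unit
  (frequency `osc_freq_hz`, default 4 Hz, with a slow frequency drift of
  s.d. `freq_jitter_hz`). Trial $j$'s oscillation runs at
  $\varphi^\ast(t) + \delta_j$ with $\delta_j \sim$ von Mises$(0,\kappa)$,
  $\kappa$ = `entrainment_kappa`. $\kappa$ tunes the inter-trial phase
  coherence (ITC) continuously from 0 (no locking) to 1; offsets are
  constant within a trial, the simplest model with tunable ITC.
* LFP = `osc_amplitude` $\cdot\cos\varphi$ + `noise_amplitude` $\cdot$
  1/f-shaped noise (trial-unique).
* The firing rate is
  $$\lambda(t, j) = \lambda_0\,\bigl[1 + d\,s(t) + \eta_j(t)\bigr]\,
  \bigl[1 + c\,\cos(\varphi(t,j) - \varphi_{\text{pref}})\bigr],
  \qquad \lambda \ge 0 \text{ enforced},$$
  with $\lambda_0$ = `baseline_rate_hz`, $d$ = `rate_mod_depth`, $c$ =
  `phase_coupling`. The stimulus profile $s(t)$ is smooth correlated
  Gaussian noise (moving average of white noise, window
  `profile_timescale_ms`), standardized to zero mean and unit variance, and
  shared across trials — a stand-in for the slow envelope of a natural
  stimulus, not a model of any sensory pathway.
* $\eta_j(t)$ is a trial-unique smooth "background noise" profile whose
  r.m.s. relative to $d\,s(t)$ is set by `noise_level_db` using the mapping
  $x$ dB $\to 10^{x/20}$: `"+6"` (background 6 dB softer than the target,
  factor 0.5), `"0"` (equal), `"-6"` (background twice the target's
  r.m.s.).
* Spikes are drawn from an inhomogeneous Poisson process by continuous-time
  thinning against the trial's maximal rate, with the rate held
  piecewise-constant at the 1 ms resolution of the LFP. Counts in any
  window are therefore exactly Poisson with mean equal to the integrated
  rate — a property the test suite verifies by a chi-square test — rather
  than the slightly sub-Poisson counts a Bernoulli-per-millisecond scheme
  would give.

All randomness derives from one master seed through named sub-streams
(oscillation, trial offsets, LFP noise, stimulus profile, spikes,
background noise, bin shuffles, epoch sampling, jitter lags, classifier
jitter), so any component can be reproduced bit-for-bit in isolation.

### What the generator does and does not emulate

It reproduces the *structure* the analysis relies on: partial entrainment of
a slow oscillation to a repeated dynamic stimulus, rate modulation locked to
the stimulus, spike-phase coupling, trial-unique background noise at
controlled relative intensity. It does not model receptive fields, real
sound or movie waveforms, multi-band oscillatory dynamics, non-stationary
adaptation, spike-sorting noise, or within-trial drift of the trial phase
offset. Passing qualitative tests on this generator shows the pipeline
measures what it claims to measure under the stated assumptions; it does not
certify effect sizes in any real dataset, and no attempt is made to
reproduce published performance values from undeposited recordings.

## Study conditions

Two reference configurations are exported:

* `standard_unit_config()`: 12 s stream, 30 trials, $\kappa = 8$,
  $c = 0.8$, $d = 0.8$, `noise_amplitude` 0.3, and
  `profile_timescale_ms = 20`. The 20 ms correlation length matches the
  width of one time bin ($T/N = 160/8$ ms), so the time-partitioned code
  genuinely relies on bin-scale stimulus-locked structure — the premise of
  a temporal-pattern code, and what makes it fragile under codebook jitter.
  With the default 50 ms profile the time code's fine structure is weaker
  and its jitter robustness artificially high.
* `noise_unit_config()`: 15 s stream and a 30 Hz baseline rate for the
  background-noise experiment. At the default 10 Hz, about 1.6 spikes fall
  in a 160 ms window and Poisson sampling noise, not the background,
  limits decoding; at 30 Hz the noise level is the binding constraint, so
  the graded degradation across `none`, `"+6"`, `"0"`, `"-6"` is resolvable.

These values were fixed once, by the reasoning above, as the conditions
under which the qualitative phenomena (code ordering, jitter robustness,
band specificity, noise degradation) are expressed; they are not fitted to
any recorded dataset.

## Signal processing choices

* **Filters.** Default band 2–6 Hz, 3rd-order Butterworth; Kaiser-window
  FIR (designed from transition width, ripple and attenuation) and complex
  Morlet convolution are available, and phase-code performance is verified
  to change by less than 10% across the five conventional variants.
* **Zero-phase filtering.** IIR filters run forward–backward and the
  symmetric FIR is applied as a centred convolution, so the extracted phase
  has no group delay relative to the spikes. A causal single pass is
  available (`zero_phase = FALSE`); with it, phase-binned codes see a
  lagged oscillation, which changes nothing about the comparison logic.
* **Phase convention.** Phase is the argument of the analytic signal
  (Hilbert transform; computed in-package by FFT) mapped to $[0, 2\pi)$,
  with a cosine peak at phase 0. All phase-bin edges derive from this one
  convention; phase exactly $2\pi$ wraps to 0. The phase at a spike is the
  phase at the nearest 1 ms sample.
* **Edge handling.** Samples within two time constants of the low band edge
  (or half the kernel support, for FIR/Morlet) are flagged as
  edge-contaminated, and epoch sampling is restricted to the unflagged
  interior, further shrunk by $J/2$ when the codebook is jittered.
* **ITC.** $\mathrm{ITC}(t) = \lvert\langle e^{i\varphi_j(t)}\rangle_j\rvert$,
  averaged over the samples of a window for per-epoch coherence; undefined
  for a single trial (an error, not a silent 1).

## Decoding choices

* **Bin conventions.** Time and phase bins are half-open on the right; a
  spike at exactly $T$ after window start is outside the window.
* **Tie-breaking.** All classifiers resolve ties deterministically toward
  the lowest stimulus index (distance ties, vote ties, likelihood ties), so
  fully degenerate ensembles decode at exactly $100/K$ percent.
* **Regularization.** The linear/quadratic discriminants add i.i.d.
  Gaussian jitter of s.d. 0.001 to the integer counts, redrawn in each
  leave-one-out fold from a dedicated RNG stream (per-fold rather than
  per-dataset, so no fold sees the test trial's jitter during training).
  Covariances that remain singular raise an error naming the stimulus.
* **Naive Bayes floors.** Poisson class means are floored at
  $1/(2\,n_{\text{train}})$; multinomial count tables use add-one smoothing
  over the observed count range, so no log-likelihood is $-\infty$.
* **Epoch sampling.** $K$ non-overlapping starts are drawn by the spacings
  construction — sort $K$ uniforms on the slack $L - KT$ and add cumulative
  window lengths — which is the exact uniform distribution over ordered
  non-overlapping placements and still works at zero slack (the exact
  tiling), where naive rejection would never terminate.
* **Temporal uncertainty.** Jitter $J$ shifts each trial's *codebook*
  window by an i.i.d. uniform lag in $[-J/2, +J/2]$; the test trial is
  extracted at the true position. Jittering the test trial as well is
  possible through the same per-trial-starts interface but is off by
  default, since the question is robustness of the stored reference, not of
  the incoming trial.
* **Coherence–performance correlation.** Per epoch set, window-averaged ITC
  is correlated with per-epoch decoding accuracy (confusion diagonal over
  trials) across the 10 epochs; per-set coefficients are averaged. Pearson
  and Spearman are both reported; sets with zero coherence variance are
  flagged and excluded rather than coerced to zero.
* **Derived metrics.** Excess performance (code − count, percentage
  points), relative excess of phase vs. time (per unit, then averaged;
  the population-mean variant can be formed from the same table),
  chance-subtracted ratio $(code - 100/K)/(count - 100/K)$ with the
  denominator guarded, and dual-code gain
  $100\,(dual - best)/(best - 100/K)$, negative values (overfitting of the
  $2N$-dimensional code) reported as such. Population comparisons use
  paired t-tests (uncorrected, with a Bonferroni column) and the Spearman
  correlation of per-unit excesses; s.e.m. is across units.

## Problem sizes used by the test suite

The packaged experiments run at desk scale: 12–20 s streams, 30–50 trials,
20 synthetic units for population-level claims, 2–8 epoch sets per unit
(100 sets for the chance-recovery computation in `scripts/acceptance.R`).
At these sizes the large effects (code ordering, time-code jitter
fragility, band specificity, noise degradation) are reproduced with paired
significance across units. One quantity sits below this resolution by
nature: the spike-count code is almost independent of codebook jitter, its
true step between adjacent $J$ values being of the order of 0.1 percentage
points. Its non-increase in $J$ is therefore assessed by paired one-sided
tests (no significant increase anywhere, significant overall decrease),
with common random numbers coupling the draws across $J$, rather than by
strict ordering of noisy sample means.

## Known limitations

* Single units only; no population or interspike-interval codes.
* The oscillation is a single band; cross-frequency structure is absent.
* Trial phase offsets are constant within a trial, so very long windows see
  more coherent phase than real drifting rhythms would provide.
* The linear/quadratic classifiers use jitter regularization, not a
  pseudo-inverse; with dual codes ($2N$ dimensions) and few trials the
  quadratic discriminant needs $n_{\text{trials}} > 2N + 1$ per class.
* Imported data must already be spike-sorted and sampled at 1 kHz; the
  package performs no spike sorting or resampling.
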