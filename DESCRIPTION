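Package: phasecode
Title: Phase-of-Firing and Time-Binned Neural Codes via Single-Trial Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare stimulus-locked time-binned, oscillation-phase-binned,
    and spike-count representations of single-unit responses to long dynamic stimuli
    by single-trial template-matching decoding with leave-one-out cross-validation.
    Includes a synthetic generator of local field potentials with tunable theta-band
    stimulus entrainment and inhomogeneous-Poisson spike trains with phase-coupled
    rates; band-pass filtering and Hilbert instantaneous phase with inter-trial phase
    coherence; six single-trial classifiers; robustness experiments for temporal
    uncertainty (jittered codebooks), frequency bands, window/bin sweeps, and sensory
    noise; and population-level summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
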