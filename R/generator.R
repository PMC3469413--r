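#' Configuration for the synthetic recording generator
#'
#' Describes one synthetic "unit": a long continuous dynamic stimulus repeated
#' over many trials, an LFP whose slow (theta-range) oscillation is partially
#' entrained to the stimulus, and spikes from an inhomogeneous Poisson process
#' whose rate is modulated both by a stimulus-specific temporal profile and by
#' the oscillation phase.
#'
#' @param duration_ms total stimulus-stream length in ms (default 52000, i.e.
#'   a 52 s continuous sequence).
#' @param n_trials number of stimulus repeats (default 50).
#' @param osc_freq_hz oscillation frequency in Hz (default 4).
#' @param entrainment_kappa von Mises concentration of per-trial phase offsets
#'   around the stimulus-locked phase trajectory; 0 = no locking, `Inf` =
#'   perfect locking.
#' @param osc_amplitude amplitude of the oscillatory LFP component.
#' @param noise_amplitude standard deviation of the additive 1/f-shaped LFP
#'   noise.
#' @param freq_jitter_hz s.d. of the slow within-trial drift of the
#'   instantaneous oscillation frequency (Hz).
#' @param baseline_rate_hz mean firing rate before modulation (default 10 Hz).
#' @param rate_mod_depth depth in [0, 1] of the stimulus temporal-profile
#'   modulation of the firing rate.
#' @param phase_coupling depth in [0, 1] of the multiplicative modulation of
#'   the rate by the oscillation phase.
#' @param phase_pref preferred firing phase in radians (rate is maximal when
#'   the oscillation phase equals this value).
#' @param profile_timescale_ms correlation length of the stimulus rate
#'   profile (default 50 ms).
#' @param noise_level_db trial-unique background-noise rate component:
#'   `"none"`, or the intensity of the target relative to the background in
#'   dB — `"+6"` (low noise), `"0"` (medium), `"-6"` (high noise, background
#'   r.m.s. twice the target's).
#' @param seed integer master seed; all randomness derives from it through
#'   named sub-streams.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(duration_ms = 52000, n_trials = 50,
                             osc_freq_hz = 4, entrainment_kappa = 8,
                             osc_amplitude = 1, noise_amplitude = 0.3,
                             freq_jitter_hz = 0.2,
                             baseline_rate_hz = 10, rate_mod_depth = 0.8,
                             phase_coupling = 0.8, phase_pref = 0,
                             profile_timescale_ms = 50,
                             noise_level_db = c("none", "+6", "0", "-6"),
                             seed = 1L) {
  noise_level_db <- match.arg(as.character(noise_level_db),
                              c("none", "+6", "0", "-6"))
  if (!is.numeric(duration_ms) || length(duration_ms) != 1 ||
      duration_ms < 1 || duration_ms != round(duration_ms)) {
    stop("`duration_ms` must be a positive integer number of milliseconds")
  }
  if (!is.numeric(n_trials) || n_trials < 1 || n_trials != round(n_trials)) {
    stop("`n_trials` must be a positive integer")
  }
  if (osc_freq_hz <= 0) stop("`osc_freq_hz` must be positive")
  if (entrainment_kappa < 0) stop("`entrainment_kappa` must be non-negative")
  if (freq_jitter_hz < 0) stop("`freq_jitter_hz` must be non-negative")
  if (baseline_rate_hz <= 0) stop("`baseline_rate_hz` must be positive")
  if (rate_mod_depth < 0 || rate_mod_depth > 1) {
    stop("`rate_mod_depth` must lie in [0, 1]")
  }
  if (phase_coupling < 0 || phase_coupling > 1) {
    stop("`phase_coupling` must lie in [0, 1]")
  }
  if (profile_timescale_ms <= 0) stop("`profile_timescale_ms` must be positive")
  structure(
    list(duration_ms = as.integer(duration_ms),
         n_trials = as.integer(n_trials),
         sampling_rate_hz = 1000L,
         osc_freq_hz = osc_freq_hz,
         entrainment_kappa = entrainment_kappa,
         osc_amplitude = osc_amplitude,
         noise_amplitude = noise_amplitude,
         freq_jitter_hz = freq_jitter_hz,
         baseline_rate_hz = baseline_rate_hz,
         rate_mod_depth = rate_mod_depth,
         phase_coupling = phase_coupling,
         phase_pref = phase_pref,
         profile_timescale_ms = profile_timescale_ms,
         noise_level_db = noise_level_db,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  %d trials x %d ms @ 1 kHz; oscillation %.3g Hz (kappa = %.3g)\n",
              x$n_trials, x$duration_ms, x$osc_freq_hz, x$entrainment_kappa))
  cat(sprintf("  rate %.3g Hz, stimulus depth %.3g, phase coupling %.3g, noise level %s\n",
              x$baseline_rate_hz, x$rate_mod_depth, x$phase_coupling,
              x$noise_level_db))
  invisible(x)
}

# Smooth standardized profile: moving average of white noise with the given
# correlation length, rescaled to zero mean and unit variance.
smooth_profile <- function(n, timescale_ms) {
  w <- max(3L, as.integer(round(timescale_ms)))
  pad <- stats::rnorm(n + 2L * w)
  s <- stats::filter(pad, rep(1 / w, w), sides = 2)
  s <- as.numeric(s[(w + 1L):(w + n)])
  as.numeric(scale(s))
}

# 1/f-amplitude ("pink") noise via spectral shaping, unit variance.
pink_noise <- function(n) {
  nf <- n %/% 2L
  f <- seq_len(nf)
  amp <- 1 / sqrt(f)
  spec <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * amp
  full <- complex(length.out = n)
  full[2L:(nf + 1L)] <- spec
  full[n:(n - nf + 2L)] <- Conj(spec[seq_len(nf - 1L)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Generate the synthetic LFP and its latent phase trajectories
#'
#' One stimulus-locked phase trajectory is drawn (frequency `osc_freq_hz`
#' with slow drift of s.d. `freq_jitter_hz`); each trial's oscillation runs at
#' that trajectory plus a constant von Mises offset with concentration
#' `entrainment_kappa`, so inter-trial phase coherence is tunable from 0
#' (uniform offsets) to 1 (identical trials). The LFP is the cosine of the
#' per-trial phase scaled by `osc_amplitude` plus 1/f-shaped noise scaled by
#' `noise_amplitude`.
#'
#' @param config a [generator_config()].
#' @return a list with `lfp` (`n_trials` x `duration_ms` matrix), `phase`
#'   (latent per-trial phase matrix, radians in `[0, 2*pi)`), and
#'   `phi_star` (the stimulus-locked trajectory).
#' @export
generate_lfp <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$duration_ms
  dt <- 1 / config$sampling_rate_hz
  phi_star <- with_substream(config$seed, "lfp", {
    drift <- if (config$freq_jitter_hz > 0) {
      config$freq_jitter_hz * smooth_profile(n, 1000)
    } else {
      numeric(n)
    }
    f_inst <- pmax(config$osc_freq_hz + drift, 0.1)
    c(0, 2 * pi * cumsum(f_inst[-n]) * dt)
  })
  deltas <- with_substream(config$seed, "lfp_offsets",
                           rvonmises(config$n_trials, 0, config$entrainment_kappa))
  phase <- (matrix(phi_star, config$n_trials, n, byrow = TRUE) + deltas) %% (2 * pi)
  lfp <- config$osc_amplitude * cos(phase)
  if (config$noise_amplitude > 0) {
    noise <- with_substream(config$seed, "lfp_noise", {
      t(vapply(seq_len(config$n_trials), function(i) pink_noise(n), numeric(n)))
    })
    lfp <- lfp + config$noise_amplitude * noise
  }
  list(lfp = lfp, phase = phase, phi_star = phi_star %% (2 * pi))
}

# dB of target relative to background -> background amplitude factor
# relative to the target profile ("-6" dB target = background twice as loud).
db_to_noise_factor <- function(level) {
  switch(level,
         "none" = 0,
         "+6" = 10^(-6 / 20),
         "0"  = 1,
         "-6" = 10^(6 / 20))
}

#' Latent firing-rate matrix of the generator
#'
#' `rate(t, trial) = baseline * [1 + d*s(t) + noise_trial(t)] *
#' [1 + c*cos(phase(t, trial) - phase_pref)]`, floored at zero, where `s(t)`
#' is the smooth zero-mean unit-variance stimulus profile shared across
#' trials, `d = rate_mod_depth`, `c = phase_coupling`, and `noise_trial` is a
#' trial-unique smooth profile whose r.m.s. relative to `d*s(t)` is set by
#' `noise_level_db`.
#'
#' @param config a [generator_config()].
#' @param phase latent per-trial phase matrix from [generate_lfp()].
#' @return list with `rate` (`n_trials` x `duration_ms` matrix, Hz) and
#'   `profile` (`s(t)`).
#' @keywords internal
generator_rate <- function(config, phase) {
  n <- config$duration_ms
  profile <- with_substream(config$seed, "profile",
                            smooth_profile(n, config$profile_timescale_ms))
  stim <- 1 + config$rate_mod_depth * profile
  stim <- matrix(stim, config$n_trials, n, byrow = TRUE)
  fac <- db_to_noise_factor(config$noise_level_db)
  if (fac > 0) {
    bg <- with_substream(config$seed, "noise", {
      t(vapply(seq_len(config$n_trials),
               function(i) smooth_profile(n, config$profile_timescale_ms),
               numeric(n)))
    })
    stim <- stim + config$rate_mod_depth * fac * bg
  }
  osc <- 1 + config$phase_coupling * cos(phase - config$phase_pref)
  rate <- pmax(config$baseline_rate_hz * stim * osc, 0)
  list(rate = rate, profile = profile)
}

#' Generate spike trains from the latent rate
#'
#' Spikes are drawn per trial from an inhomogeneous Poisson process by
#' thinning (Ogata/Lewis-Shedler): candidate events from a homogeneous
#' Poisson process at the trial's maximal rate are accepted with probability
#' `rate(t)/rate_max`, the rate being piecewise-constant at 1 ms resolution.
#' Counts in any window are therefore exactly Poisson with mean equal to the
#' integrated rate.
#'
#' @param config a [generator_config()].
#' @param phase latent per-trial phase matrix (radians), as produced by
#'   [generate_lfp()].
#' @return list with `spikes` (list of per-trial spike-time vectors, ms, in
#'   `[0, duration_ms)`), `rate`, and `profile`.
#' @export
generate_spikes <- function(config, phase) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.matrix(phase) || nrow(phase) != config$n_trials ||
      ncol(phase) != config$duration_ms) {
    stop("`phase` must be an n_trials x duration_ms matrix matching `config`")
  }
  lat <- generator_rate(config, phase)
  dur_s <- config$duration_ms / 1000
  spikes <- with_substream(config$seed, "spikes", {
    lapply(seq_len(config$n_trials), function(tr) {
      r <- lat$rate[tr, ]
      rmax <- max(r)
      if (rmax <= 0) return(numeric(0))
      n_cand <- stats::rpois(1, rmax * dur_s)
      if (n_cand == 0) return(numeric(0))
      tt <- sort(stats::runif(n_cand, 0, config$duration_ms))
      keep <- stats::runif(n_cand) < r[floor(tt) + 1] / rmax
      tt[keep]
    })
  })
  list(spikes = spikes, rate = lat$rate, profile = lat$profile)
}

#' Generate a full synthetic recording
#'
#' Composes [generate_lfp()] and [generate_spikes()] under independent named
#' RNG sub-streams of the config's master seed; the same seed always yields a
#' bit-identical recording.
#'
#' @param config a [generator_config()].
#' @param keep_ground_truth keep the latent rate, profile, and phase
#'   trajectories (used by tests and diagnostics)?
#' @return a `recording` object: `lfp` matrix, `spikes` per-trial list,
#'   `config`, and optionally `ground_truth`.
#' @export
generate_recording <- function(config, keep_ground_truth = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  field <- generate_lfp(config)
  sp <- generate_spikes(config, field$phase)
  gt <- if (keep_ground_truth) {
    list(phase = field$phase, phi_star = field$phi_star,
         rate = sp$rate, profile = sp$profile)
  }
  new_recording(field$lfp, sp$spikes, config, gt)
}

#' Standard synthetic study units
#'
#' `standard_unit_config()` is the package's reference condition for the
#' code-comparison, jitter, frequency and coherence experiments: a strongly
#' entrained 4 Hz oscillation (kappa = 8), strong phase coupling and rate
#' modulation, and a stimulus profile with structure at the 20 ms bin scale
#' so the time-partitioned code genuinely relies on fine stimulus-locked
#' timing. `noise_unit_config()` is the reference condition for the
#' background-noise experiment: a shorter 15 s stream and a higher firing
#' rate so that background noise rather than Poisson spike sampling limits
#' decoding. Rationale for both is laid out in the methods vignette.
#'
#' @param seed integer master seed (one seed = one synthetic unit).
#' @param duration_ms stream length (default 12000 for the standard unit).
#' @param n_trials stimulus repeats (default 30).
#' @param ... overrides passed to [generator_config()].
#' @return a `generator_config`.
#' @export
standard_unit_config <- function(seed, duration_ms = 12000, n_trials = 30,
                                 ...) {
  generator_config(duration_ms = duration_ms, n_trials = n_trials,
                   profile_timescale_ms = 20, seed = seed, ...)
}

#' @rdname standard_unit_config
#' @export
noise_unit_config <- function(seed, duration_ms = 15000, n_trials = 30,
                              ...) {
  generator_config(duration_ms = duration_ms, n_trials = n_trials,
                   profile_timescale_ms = 20, baseline_rate_hz = 30,
                   seed = seed, ...)
}

#' Construct a recording object
#'
#' Container for one unit/site: per-trial LFP rows sampled at 1 kHz and
#' per-trial spike-time lists. Use this to wrap imported data; synthetic data
#' comes from [generate_recording()].
#'
#' @param lfp numeric matrix, trials x time (1 ms samples).
#' @param spikes list of numeric vectors of spike times in ms, one per trial,
#'   each in `[0, duration_ms)`.
#' @param config a [generator_config()] or a plain metadata list.
#' @param ground_truth optional latent structure retained for testing.
#' @return an object of class `recording`.
#' @export
new_recording <- function(lfp, spikes, config = NULL, ground_truth = NULL) {
  stopifnot(is.matrix(lfp), is.list(spikes))
  if (nrow(lfp) != length(spikes)) {
    stop("LFP row count must equal the number of trials in `spikes`")
  }
  dur <- ncol(lfp)
  for (s in spikes) {
    if (length(s) && (min(s) < 0 || max(s) >= dur)) {
      stop("spike times must lie strictly inside [0, duration_ms)")
    }
  }
  structure(list(lfp = lfp, spikes = spikes, config = config,
                 ground_truth = ground_truth),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d trials x %d ms, %0.1f spikes/trial on average\n",
              nrow(x$lfp), ncol(x$lfp),
              mean(vapply(x$spikes, length, numeric(1)))))
  invisible(x)
}

#' Number of trials / duration of a recording
#' @param recording a `recording`.
#' @return integer.
#' @export
n_trials <- function(recording) nrow(recording$lfp)

#' @rdname n_trials
#' @export
duration_ms <- function(recording) ncol(recording$lfp)

#' Spikes of a recording as a tidy table
#'
#' @param recording a `recording`.
#' @return a tibble with columns `trial` and `spike_time_ms`.
#' @export
spike_table <- function(recording) {
  tibble::tibble(
    trial = rep(seq_along(recording$spikes),
                vapply(recording$spikes, length, integer(1))),
    spike_time_ms = unlist(recording$spikes, use.names = FALSE) %||% numeric(0)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
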