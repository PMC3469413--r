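#' Neural code specification
#'
#' Defines how the response within one window of length `T_ms` is turned
#' into a vector:
#' * `time` — counts in `N` equally spaced, stimulus-locked time bins;
#' * `phase` — counts in `N` equally spaced bins of the instantaneous
#'   oscillation phase at each spike time;
#' * `count_shuffled` — the time-partitioned vector with its bins randomly
#'   permuted per trial and window, which destroys the temporal pattern but
#'   keeps the total count and the dimensionality (decoding is averaged over
#'   `shuffle_repeats` independent shuffles);
#' * `count_scalar` — the total spike count as a 1-dimensional code;
#' * `dual` — the concatenated time- and phase-partitioned vectors (length
#'   `2N`), used to measure their redundancy.
#'
#' @param kind one of `"time"`, `"phase"`, `"count_shuffled"`,
#'   `"count_scalar"`, `"dual"`.
#' @param N number of bins (default 8).
#' @param T_ms window length in ms (default 160).
#' @param band a [filter_spec()] giving the oscillation band for
#'   phase-based kinds (default 2-6 Hz Butterworth).
#' @param shuffle_repeats shuffles averaged over for `count_shuffled`
#'   (default 20).
#' @param label label used in result tables (defaults to `kind`; set it when
#'   comparing several variants of the same kind, e.g. phase codes from
#'   different bands).
#' @return an object of class `code_spec`.
#' @export
code_spec <- function(kind = c("time", "phase", "count_shuffled",
                               "count_scalar", "dual"),
                      N = 8, T_ms = 160, band = NULL, shuffle_repeats = 20,
                      label = NULL) {
  kind <- match.arg(kind)
  if (N < 1 || N != round(N)) stop("`N` must be a positive integer")
  if (T_ms <= 0) stop("`T_ms` must be positive")
  if (shuffle_repeats < 1) stop("`shuffle_repeats` must be positive")
  if (kind %in% c("phase", "dual") && is.null(band)) band <- filter_spec()
  structure(list(kind = kind, N = as.integer(N), T_ms = T_ms, band = band,
                 shuffle_repeats = as.integer(shuffle_repeats),
                 label = label %||% kind),
            class = "code_spec")
}

#' @export
print.code_spec <- function(x, ...) {
  cat(sprintf("<code_spec> %s, N = %d, T = %g ms\n", x$kind, x$N, x$T_ms))
  invisible(x)
}

code_dimension <- function(spec) {
  switch(spec$kind,
         count_scalar = 1L,
         dual = 2L * spec$N,
         spec$N)
}

#' Time-partitioned response vector
#'
#' Splits the window `[window_start, window_start + T_ms)` into `N` equally
#' spaced time bins (half-open on the right) and counts spikes per bin.
#'
#' @param spike_times numeric vector of spike times in ms.
#' @param window_start window start, ms.
#' @param N number of bins.
#' @param T_ms window length, ms.
#' @return integer vector of length `N`.
#' @export
time_partitioned <- function(spike_times, window_start, N = 8, T_ms = 160) {
  s <- spike_times[spike_times >= window_start &
                     spike_times < window_start + T_ms]
  if (!length(s)) return(integer(N))
  bins <- floor((s - window_start) * N / T_ms)
  tabulate(bins + 1L, nbins = N)
}

#' Phase-partitioned response vector
#'
#' Each spike inside the window is assigned to one of `N` equally spaced
#' phase bins (`[i*2*pi/N, (i+1)*2*pi/N)`, half-open, phase exactly `2*pi`
#' wrapping to 0) according to the instantaneous oscillation phase at the
#' nearest 1-ms sample to its spike time.
#'
#' @param spike_times numeric vector of spike times in ms.
#' @param phase_row numeric vector of phase (radians) per 1-ms sample, for
#'   this trial.
#' @param window_start window start, ms.
#' @param N number of bins.
#' @param T_ms window length, ms.
#' @return integer vector of length `N`.
#' @export
phase_partitioned <- function(spike_times, phase_row, window_start,
                              N = 8, T_ms = 160) {
  if (length(phase_row) < window_start + T_ms) {
    stop("phase series shorter than the requested window")
  }
  s <- spike_times[spike_times >= window_start &
                     spike_times < window_start + T_ms]
  if (!length(s)) return(integer(N))
  idx <- pmin(pmax(round(s) + 1L, 1L), length(phase_row))
  ph <- phase_row[idx] %% (2 * pi)
  bins <- floor(ph * N / (2 * pi)) %% N
  tabulate(bins + 1L, nbins = N)
}

#' Bin-shuffled spike-count vector
#'
#' A random permutation (without replacement) of the bins of a
#' time-partitioned vector; preserves the total count and dimensionality
#' while destroying the temporal pattern.
#'
#' @param time_vector integer vector (a time-partitioned response).
#' @return integer vector, same multiset of entries.
#' @export
spike_count_shuffled <- function(time_vector) {
  n <- length(time_vector)
  if (n == 1L) return(time_vector)
  time_vector[sample.int(n)]
}

#' Scalar spike-count code
#'
#' @param spike_times numeric vector of spike times in ms.
#' @param window_start window start, ms.
#' @param T_ms window length, ms.
#' @return integer vector of length 1.
#' @export
spike_count_scalar <- function(spike_times, window_start, T_ms = 160) {
  sum(spike_times >= window_start & spike_times < window_start + T_ms)
}

#' Dual (joint time + phase) code
#'
#' Concatenates the time- and phase-partitioned vectors from the same window
#' and the same `N`.
#'
#' @param time_vector integer vector, length `N`.
#' @param phase_vector integer vector, length `N`.
#' @return integer vector of length `2N`.
#' @export
dual_code <- function(time_vector, phase_vector) {
  if (length(time_vector) != length(phase_vector)) {
    stop("time- and phase-partitioned vectors must share the same N")
  }
  if (sum(time_vector) != sum(phase_vector)) {
    stop("time- and phase-partitioned vectors must come from the same window",
         " (their totals differ)")
  }
  c(time_vector, phase_vector)
}

#' Build a response ensemble for decoding
#'
#' Treats each epoch as one stimulus class and each stimulus repeat as one
#' trial: for every (epoch, trial) pair the response vector under `code` is
#' computed, yielding the K-class ensemble the leave-one-out decoder
#' consumes.
#'
#' @param recording a `recording`.
#' @param epochs an `epoch_set` from [sample_epochs()], or a numeric vector
#'   of window starts (ms).
#' @param code a [code_spec()].
#' @param phase optional precomputed `phase_series` for phase-based codes
#'   (computed from `code$band` if missing).
#' @param starts_by_trial optional K x n_trials matrix of per-trial window
#'   starts (used to build time-jittered codebooks); defaults to the shared
#'   epoch starts.
#' @return a `response_ensemble`: list of K (trials x dimension) count
#'   matrices plus metadata.
#' @export
build_ensemble <- function(recording, epochs, code, phase = NULL,
                           starts_by_trial = NULL) {
  starts <- if (inherits(epochs, "epoch_set")) epochs$starts else epochs
  T_ms <- if (inherits(epochs, "epoch_set")) epochs$T_ms else code$T_ms
  K <- length(starts)
  nt <- n_trials(recording)
  if (is.null(starts_by_trial)) {
    starts_by_trial <- matrix(starts, K, nt)
  }
  stopifnot(nrow(starts_by_trial) == K, ncol(starts_by_trial) == nt)
  needs_phase <- code$kind %in% c("phase", "dual")
  if (needs_phase && is.null(phase)) {
    phase <- extract_phase(recording, code$band %||% filter_spec())
  }
  d <- code_dimension(code)
  responses <- lapply(seq_len(K), function(k) {
    m <- matrix(0L, nt, d)
    for (tr in seq_len(nt)) {
      st <- starts_by_trial[k, tr]
      sp <- recording$spikes[[tr]]
      m[tr, ] <- switch(
        code$kind,
        time = time_partitioned(sp, st, code$N, T_ms),
        count_shuffled = time_partitioned(sp, st, code$N, T_ms),
        phase = phase_partitioned(sp, phase$phase[tr, ], st, code$N, T_ms),
        count_scalar = spike_count_scalar(sp, st, T_ms),
        dual = c(time_partitioned(sp, st, code$N, T_ms),
                 phase_partitioned(sp, phase$phase[tr, ], st, code$N, T_ms)))
    }
    m
  })
  structure(list(responses = responses, K = K, dimension = d,
                 n_trials = nt, code = code, starts = starts, T_ms = T_ms),
            class = "response_ensemble")
}

#' @export
print.response_ensemble <- function(x, ...) {
  cat(sprintf("<response_ensemble> %d stimuli x %d trials, dimension %d (%s)\n",
              x$K, x$n_trials, x$dimension, x$code$kind))
  invisible(x)
}

#' Shuffle the bins of every response in an ensemble
#'
#' Applies an independent bin permutation to each (trial, window) response of
#' a time-partitioned ensemble, producing one realization of the bin-shuffled
#' spike-count code.
#'
#' @param ensemble a `response_ensemble` built with a `time` or
#'   `count_shuffled` code.
#' @return a `response_ensemble` of shuffled responses.
#' @export
shuffle_ensemble <- function(ensemble) {
  stopifnot(inherits(ensemble, "response_ensemble"))
  out <- ensemble
  out$responses <- lapply(ensemble$responses, function(m) {
    if (ncol(m) < 2) return(m)
    t(apply(m, 1, spike_count_shuffled))
  })
  out
}

#' Response ensemble as a tidy table
#'
#' @param x a `response_ensemble`.
#' @param ... unused.
#' @return a tibble with columns `stimulus`, `trial`, `bin_index`, `count`,
#'   `code`, `window_start`.
#' @export
tidy.response_ensemble <- function(x, ...) {
  purrr::map_dfr(seq_len(x$K), function(k) {
    m <- x$responses[[k]]
    tibble::tibble(
      stimulus = k,
      trial = rep(seq_len(nrow(m)), ncol(m)),
      bin_index = rep(seq_len(ncol(m)), each = nrow(m)),
      count = as.integer(m),
      code = x$code$kind,
      window_start = x$starts[k])
  })
}
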