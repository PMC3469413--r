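#' Band-pass filter specification
#'
#' Three families are supported, matching common practice for extracting a
#' slow oscillation from a field potential:
#' * `butterworth` — IIR Butterworth of the given `order` (default 3),
#'   applied forward-backward (zero phase);
#' * `kaiser_fir` — linear-phase FIR designed with a Kaiser window from the
#'   transition bandwidth, passband ripple and stopband attenuation, applied
#'   forward-backward;
#' * `morlet` — convolution with a complex Morlet wavelet of centre frequency
#'   `center_hz` and spectral s.d. `sigma_hz`; its complex output carries the
#'   phase directly.
#'
#' @param family one of `"butterworth"`, `"kaiser_fir"`, `"morlet"`.
#' @param low_hz,high_hz band edges in Hz (IIR/FIR families).
#' @param order Butterworth order (default 3).
#' @param transition_hz,ripple_db,attenuation_db Kaiser design parameters
#'   (defaults 1 Hz, 0.01 dB, 60 dB).
#' @param center_hz,sigma_hz Morlet centre frequency and spectral s.d.
#'   (defaults 4 Hz and 0.6/4 Hz).
#' @param fs_hz sampling rate, fixed at 1000 Hz in this package.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(family = c("butterworth", "kaiser_fir", "morlet"),
                        low_hz = 2, high_hz = 6, order = 3,
                        transition_hz = 1, ripple_db = 0.01,
                        attenuation_db = 60,
                        center_hz = 4, sigma_hz = 0.6 / 4, fs_hz = 1000) {
  family <- match.arg(family)
  nyq <- fs_hz / 2
  if (family == "morlet") {
    if (center_hz <= 0 || center_hz >= nyq) {
      stop("`center_hz` must lie in (0, Nyquist)")
    }
    if (sigma_hz <= 0) stop("`sigma_hz` must be positive")
  } else {
    if (!(0 < low_hz && low_hz < high_hz && high_hz < nyq)) {
      stop("band edges must satisfy 0 < low_hz < high_hz < Nyquist (",
           nyq, " Hz)")
    }
  }
  structure(list(family = family, low_hz = low_hz, high_hz = high_hz,
                 order = order, transition_hz = transition_hz,
                 ripple_db = ripple_db, attenuation_db = attenuation_db,
                 center_hz = center_hz, sigma_hz = sigma_hz, fs_hz = fs_hz),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  if (x$family == "morlet") {
    cat(sprintf("<filter_spec> morlet, fc = %g Hz, sigma_f = %g Hz\n",
                x$center_hz, x$sigma_hz))
  } else {
    cat(sprintf("<filter_spec> %s %g-%g Hz\n", x$family, x$low_hz, x$high_hz))
  }
  invisible(x)
}

#' Serialize / restore a filter specification
#' @param spec a `filter_spec`.
#' @param path file path for the JSON representation.
#' @return `read_filter_spec` returns a `filter_spec`.
#' @export
write_filter_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filter_spec
#' @export
read_filter_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(filter_spec, x)
}

# Edge margin (ms) within which zero-phase filtering is unreliable:
# two time constants of the slowest band edge.
edge_margin_ms <- function(spec) {
  if (spec$family == "kaiser_fir") {
    # half the Kaiser tap count (1 tap = 1 ms at 1 kHz)
    taps <- (spec$attenuation_db - 8) /
      (2.285 * 2 * pi * spec$transition_hz / spec$fs_hz)
    return(ceiling(taps / 2))
  }
  if (spec$family == "morlet") {
    # half the kernel support (4 temporal s.d.)
    return(ceiling(4 * spec$fs_hz / (2 * pi * spec$sigma_hz)))
  }
  ceiling(2 * 1000 / spec$low_hz)
}

# "Same"-length convolution of a real signal with a (possibly complex)
# symmetric kernel, via zero-padded FFT.
conv_same <- function(x, k) {
  n <- length(x)
  m <- length(k)
  half <- (m - 1L) %/% 2L
  nfft <- stats::nextn(n + m - 1L, 2)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  K <- stats::fft(c(k, rep(0, nfft - m)))
  full <- stats::fft(X * K, inverse = TRUE) / nfft
  full[(half + 1L):(half + n)]
}

morlet_kernel <- function(spec) {
  sigma_t <- 1 / (2 * pi * spec$sigma_hz) # seconds
  half <- ceiling(4 * sigma_t * spec$fs_hz)
  t <- (-half:half) / spec$fs_hz
  k <- exp(2i * pi * spec$center_hz * t) * exp(-t^2 / (2 * sigma_t^2))
  k / sum(Mod(k))
}

#' Band-pass filter an LFP matrix
#'
#' Rows are trials. IIR/FIR families are applied with zero-phase
#' forward-backward filtering (so the extracted phase is not lag-distorted
#' relative to the spikes); set `zero_phase = FALSE` for a causal single
#' pass. The Morlet family returns a complex matrix whose argument is the
#' instantaneous phase. The returned matrix carries an `edge_ms` attribute:
#' samples within that margin of either end are edge-contaminated, and epoch
#' sampling avoids them. If the recording is shorter than about three cycles
#' of the low band edge, a `short_data` attribute is set to `TRUE`.
#'
#' @param lfp numeric matrix (trials x ms) or a single numeric vector.
#' @param spec a [filter_spec()].
#' @param zero_phase logical, two-pass filtering (default `TRUE`).
#' @return filtered matrix, same shape, with attributes `edge_ms`,
#'   `short_data`, and `band` (the spec).
#' @export
bandpass <- function(lfp, spec = filter_spec(), zero_phase = TRUE) {
  stopifnot(inherits(spec, "filter_spec"))
  vec_in <- !is.matrix(lfp)
  if (vec_in) lfp <- matrix(lfp, nrow = 1)
  storage.mode(lfp) <- "double"
  if (anyNA(lfp)) stop("LFP contains NA values")
  n <- ncol(lfp)
  low_ref <- if (spec$family == "morlet") spec$center_hz else spec$low_hz
  short_data <- n < 3 * 1000 / low_ref
  if (short_data) {
    warning("recording shorter than ~3 cycles of the band; edge effects dominate")
  }
  out <- switch(
    spec$family,
    butterworth = {
      bf <- signal::butter(spec$order,
                           c(spec$low_hz, spec$high_hz) / (spec$fs_hz / 2),
                           type = "pass")
      t(apply(lfp, 1, function(r) {
        if (zero_phase) signal::filtfilt(bf, r) else
          as.numeric(signal::filter(bf, r))
      }))
    },
    kaiser_fir = {
      dev <- c(10^(-spec$attenuation_db / 20),
               10^(spec$ripple_db / 20) - 1,
               10^(-spec$attenuation_db / 20))
      ko <- signal::kaiserord(
        c(spec$low_hz - spec$transition_hz, spec$low_hz,
          spec$high_hz, spec$high_hz + spec$transition_hz),
        c(0, 1, 0), dev, spec$fs_hz)
      ntaps <- ko$n + (ko$n %% 2 == 1) # even order -> odd length, type-I FIR
      b <- signal::fir1(ntaps, ko$Wc, type = "pass",
                        window = signal::kaiser(ntaps + 1, ko$beta))
      # a symmetric (linear-phase) FIR applied as a centred convolution is
      # exactly zero-phase; a causal pass keeps the n/2-sample group delay
      out <- t(apply(lfp, 1, function(r) {
        if (zero_phase) Re(conv_same(r, as.numeric(b))) else
          as.numeric(signal::filter(b, 1, r))
      }))
      if (nrow(lfp) == 1) out <- matrix(out, nrow = 1)
      out
    },
    morlet = {
      k <- morlet_kernel(spec)
      out <- t(apply(lfp, 1, conv_same, k = k))
      if (nrow(lfp) == 1) out <- matrix(out, nrow = 1)
      out
    })
  if (vec_in) out <- out[1, , drop = TRUE]
  attr(out, "edge_ms") <- edge_margin_ms(spec)
  attr(out, "short_data") <- short_data
  attr(out, "band") <- spec
  out
}

# Analytic signal via FFT: positive frequencies doubled, negative zeroed.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a narrow-band signal
#'
#' For real input the analytic signal is formed with the Hilbert transform
#' and the phase is its argument mapped to `[0, 2*pi)`; a pure cosine has
#' phase 0 at its peaks. Complex input (Morlet output) is used directly.
#'
#' @param filtered matrix (trials x ms) from [bandpass()], or a vector.
#' @return a `phase_series`: list with `phase` (matrix in `[0, 2*pi)`),
#'   `amplitude` (envelope), `band` (the filter spec, if known), and
#'   `edge_ms`.
#' @export
instantaneous_phase <- function(filtered) {
  band <- attr(filtered, "band")
  edge <- attr(filtered, "edge_ms") %||% 0
  vec_in <- !is.matrix(filtered)
  if (vec_in) filtered <- matrix(filtered, nrow = 1)
  if (anyNA(filtered)) stop("filtered signal contains NA values")
  if (is.complex(filtered)) {
    z <- filtered
  } else {
    z <- t(apply(filtered, 1, analytic_signal))
    if (nrow(filtered) == 1) z <- matrix(z, nrow = 1)
  }
  structure(list(phase = Arg(z) %% (2 * pi),
                 amplitude = Mod(z),
                 band = band, edge_ms = edge),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> %d trials x %d ms (edge margin %d ms)\n",
              nrow(x$phase), ncol(x$phase), as.integer(x$edge_ms)))
  invisible(x)
}

#' Band-pass + phase extraction in one step
#'
#' @param recording a `recording`.
#' @param spec a [filter_spec()].
#' @param zero_phase two-pass filtering (default `TRUE`).
#' @return a `phase_series`.
#' @export
extract_phase <- function(recording, spec = filter_spec(), zero_phase = TRUE) {
  instantaneous_phase(bandpass(recording$lfp, spec, zero_phase = zero_phase))
}

#' Export / import a phase series matrix
#'
#' Writes the phase matrix in the same trials-by-ms CSV layout used for the
#' LFP by [write_recording()] (17 significant digits; round trip accurate to
#' better than 1e-9 relative).
#'
#' @param phase a `phase_series`.
#' @param path output file.
#' @return `read_phase_matrix` returns the numeric matrix.
#' @export
write_phase_series <- function(phase, path) {
  stopifnot(inherits(phase, "phase_series"))
  writeLines(apply(phase$phase, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ",")), path)
  invisible(path)
}

#' @rdname write_phase_series
#' @export
read_phase_matrix <- function(path) {
  do.call(rbind, lapply(strsplit(readLines(path), ","), as.numeric))
}

#' Inter-trial phase coherence
#'
#' The modulus of the trial-averaged unit phasor at each sample:
#' `ITC(t) = |mean_trials exp(i * phase(trial, t))|`, in `[0, 1]`; 1 means
#' perfectly aligned phases across trials, 0 uniform dispersion.
#'
#' @param phase a `phase_series` or a trials x ms phase matrix (radians).
#' @return numeric vector over time.
#' @export
intertrial_phase_coherence <- function(phase) {
  p <- if (inherits(phase, "phase_series")) phase$phase else phase
  stopifnot(is.matrix(p))
  if (nrow(p) < 2) {
    stop("inter-trial phase coherence is undefined for a single trial")
  }
  Mod(colMeans(exp(1i * p)))
}

#' Mean phase coherence within a decoding window
#'
#' Arithmetic mean of the inter-trial phase coherence over the samples of the
#' window `[window_start, window_start + T_ms)`.
#'
#' @param phase a `phase_series` or phase matrix.
#' @param window_start window start, ms from recording onset.
#' @param T_ms window length, ms.
#' @return scalar in `[0, 1]`.
#' @export
window_coherence <- function(phase, window_start, T_ms) {
  p <- if (inherits(phase, "phase_series")) phase$phase else phase
  i0 <- floor(window_start) + 1L
  i1 <- floor(window_start) + as.integer(round(T_ms))
  if (i0 < 1 || i1 > ncol(p)) stop("window out of range")
  mean(intertrial_phase_coherence(p[, i0:i1, drop = FALSE]))
}
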