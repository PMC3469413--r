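#' Sample a set of non-overlapping stimulus epochs
#'
#' Draws `K` non-overlapping windows of length `T_ms` uniformly at random
#' from `[range_start, range_end)`. Sampling uses the spacings construction
#' (sort K uniform draws on the available slack, then add the accumulated
#' window lengths), which is exactly the uniform distribution over ordered
#' non-overlapping placements and remains valid at zero slack, where the
#' only solution is the exact tiling. Starts are rounded to whole ms.
#'
#' @param range_start,range_end valid range in ms (epoch sampling should
#'   avoid filter edge margins and jitter margins).
#' @param K number of epochs (default 10).
#' @param T_ms window length in ms.
#' @return an `epoch_set`: list with `starts` (sorted, ms), `T_ms`, `K`.
#' @export
sample_epochs <- function(range_start, range_end, K = 10, T_ms = 160) {
  L <- range_end - range_start
  slack <- L - K * T_ms
  if (slack < 0) {
    stop(sprintf("cannot place %d non-overlapping windows of %g ms in %g ms",
                 K, T_ms, L))
  }
  u <- sort(round(stats::runif(K, 0, slack)))
  starts <- range_start + u + (seq_len(K) - 1) * T_ms
  structure(list(starts = starts, T_ms = T_ms, K = K), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs of %g ms: %s\n", x$K, x$T_ms,
              paste(x$starts, collapse = ", ")))
  invisible(x)
}

# Valid epoch range of a recording given a filter edge margin and jitter.
valid_epoch_range <- function(recording, edge_ms = 0, jitter_ms = 0) {
  margin <- edge_ms + ceiling(jitter_ms / 2)
  c(margin, duration_ms(recording) - margin)
}

decode_one <- function(ensemble, classifier, codebook = NULL, seed = NULL) {
  if (ensemble$code$kind == "count_shuffled") {
    shuffled_count_decode(ensemble, classifier, seed = seed %||% 1L)
  } else {
    loo_decode(ensemble, classifier, codebook = codebook, seed = seed)
  }
}

#' Compare neural codes on one recording
#'
#' The core comparison experiment: `K` non-overlapping epochs of length `T_ms`
#' are sampled from the stimulus stream and act as the stimulus classes
#' (trials are the stimulus repeats); for each code a response ensemble is
#' built over the same epochs and decoded with leave-one-out cross-
#' validation; everything is repeated over `n_sets` independent epoch sets
#' and averaged. With `jitter_ms > 0` the codebook for each trial is built
#' from windows shifted by i.i.d. uniform lags in `[-J/2, +J/2]` while the
#' test trial stays at the true position.
#'
#' @param recording a `recording`.
#' @param codes list of [code_spec()]s (or a single one).
#' @param classifier a [classifier_spec()] or name.
#' @param K epochs per set (default 10).
#' @param n_sets number of independent epoch sets (default 100).
#' @param T_ms window length (defaults to the first code's `T_ms`).
#' @param jitter_ms maximal temporal uncertainty J (default 0).
#' @param seed master seed; epoch sampling, shuffles, jitter lags and
#'   classifier jitter each use a named sub-stream of it.
#' @param keep_epochs keep per-epoch accuracies and coherence (needed by
#'   [coherence_performance()]).
#' @return an `experiment_result`: tibble of per-set results plus a summary.
#' @export
run_comparison <- function(recording, codes, classifier = "nearest_mean",
                           K = 10, n_sets = 100, T_ms = NULL,
                           jitter_ms = 0, seed = 1L, keep_epochs = FALSE) {
  if (inherits(codes, "code_spec")) codes <- list(codes)
  classifier <- as_classifier(classifier)
  T_ms <- T_ms %||% codes[[1]]$T_ms
  stopifnot(jitter_ms >= 0)

  # one phase series per distinct band among the requested codes
  phase_cache <- list()
  edge_needed <- 0
  for (cd in codes) {
    if (cd$kind %in% c("phase", "dual")) {
      key <- band_key(cd$band)
      if (is.null(phase_cache[[key]])) {
        filt <- bandpass(recording$lfp, cd$band)
        phase_cache[[key]] <- instantaneous_phase(filt)
        edge_needed <- max(edge_needed, attr(filt, "edge_ms"))
      }
    }
  }
  rng <- valid_epoch_range(recording, edge_needed, jitter_ms)
  nt <- n_trials(recording)

  epoch_seed <- substream_seed(seed, "epochs")
  jitter_seed <- substream_seed(seed, "jitter")
  shuffle_seed <- substream_seed(seed, "shuffles")
  cls_seed <- substream_seed(seed, "classifier")

  rows <- list()
  epoch_rows <- list()
  for (s in seq_len(n_sets)) {
    epochs <- withr::with_seed(c_seed(epoch_seed, s),
                               sample_epochs(rng[1], rng[2], K, T_ms))
    starts_tr <- NULL
    if (jitter_ms > 0) {
      lags <- withr::with_seed(
        c_seed(jitter_seed, s),
        matrix(stats::runif(K * nt, -jitter_ms / 2, jitter_ms / 2), K, nt))
      starts_tr <- matrix(epochs$starts, K, nt) + lags
    }
    for (ci in seq_along(codes)) {
      cd <- codes[[ci]]
      ph <- if (cd$kind %in% c("phase", "dual")) phase_cache[[band_key(cd$band)]]
      ens <- build_ensemble(recording, epochs, cd, phase = ph)
      cb <- if (!is.null(starts_tr)) {
        build_ensemble(recording, epochs, cd, phase = ph,
                       starts_by_trial = starts_tr)
      }
      res <- decode_one(ens, classifier, codebook = cb,
                        seed = if (cd$kind == "count_shuffled")
                          c_seed(shuffle_seed, s) else c_seed(cls_seed, s))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        set = s, code = code_label(cd), classifier = classifier$name,
        percent_correct = res$percent_correct)
      if (keep_epochs) {
        epoch_rows[[length(epoch_rows) + 1L]] <- tibble::tibble(
          set = s, code = code_label(cd), epoch = seq_len(K),
          window_start = epochs$starts,
          accuracy = res$per_stimulus_accuracy)
      }
    }
  }
  per_set <- dplyr::bind_rows(rows)
  new_experiment_result(per_set,
                        per_epoch = if (keep_epochs) dplyr::bind_rows(epoch_rows),
                        params = list(K = K, n_sets = n_sets, T_ms = T_ms,
                                      jitter_ms = jitter_ms, seed = seed,
                                      classifier = classifier$name))
}

band_key <- function(band) {
  band <- band %||% filter_spec()
  paste(band$family, band$low_hz, band$high_hz, band$center_hz, sep = "_")
}

code_label <- function(cd) cd$label %||% cd$kind

# Derive a bounded child seed from a stream seed and an index.
c_seed <- function(stream_seed, i) {
  as.integer((as.double(stream_seed) + 97561 * as.double(i)) %% 2147483647)
}

new_experiment_result <- function(per_set, per_epoch = NULL, params = list()) {
  summary <- per_set |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("code", "classifier", "T_ms", "N", "center_hz", "jitter_ms",
        "noise_level", "unit")))) |>
    dplyr::summarise(
      mean_pc = mean(.data$percent_correct),
      sem = stats::sd(.data$percent_correct) /
        sqrt(dplyr::n()),
      n_sets = dplyr::n(), .groups = "drop")
  structure(list(per_set = per_set, summary = summary,
                 per_epoch = per_epoch, params = params),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  print(x$summary, n = 20)
  invisible(x)
}

#' Tidy per-set results of an experiment
#' @param x an `experiment_result`.
#' @param ... unused.
#' @return a tibble, one row per (set, code, ...).
#' @export
tidy.experiment_result <- function(x, ...) x$per_set

#' One-row-per-condition summary of an experiment
#' @param x an `experiment_result`.
#' @param ... unused.
#' @return a tibble with `mean_pc`, `sem`, `n_sets` per condition.
#' @export
glance.experiment_result <- function(x, ...) x$summary

#' Decoding with a temporally jittered codebook
#'
#' Convenience wrapper around [run_comparison()] sweeping the maximal
#' temporal uncertainty `J`: for each J the per-trial codebook windows are
#' shifted by i.i.d. uniform lags in `[-J/2, +J/2]` (the test trial is
#' extracted at the true position), probing each code's robustness to
#' temporal uncertainty in the decoding process.
#'
#' @param recording a `recording`.
#' @param codes list of [code_spec()]s.
#' @param J_values jitter magnitudes in ms (default `c(0, 40, 80, 160)`).
#' @param ... passed to [run_comparison()].
#' @return an `experiment_result` whose tables carry a `jitter_ms` column.
#' @export
jitter_sweep <- function(recording, codes,
                         J_values = c(0, 40, 80, 160), ...) {
  runs <- lapply(J_values, function(J) {
    r <- run_comparison(recording, codes, jitter_ms = J, ...)
    dplyr::mutate(r$per_set, jitter_ms = J)
  })
  new_experiment_result(dplyr::bind_rows(runs),
                        params = list(J_values = J_values))
}

#' Decoding performance across LFP frequency bands
#'
#' Runs the phase-partitioned code with the oscillation phase extracted from
#' 4 Hz-wide bands at the given centre frequencies, together with the scalar
#' spike count, and reports the chance-subtracted phase/count performance
#' ratio per band.
#'
#' @param recording a `recording`.
#' @param centers centre frequencies in Hz (default `seq(4, 32, by = 4)`).
#' @param width band width in Hz (default 4).
#' @param N,T_ms code parameters.
#' @param ... passed to [run_comparison()].
#' @return an `experiment_result`; its `summary` has one row per centre
#'   frequency and code, and a `ratio` tibble with the chance-subtracted
#'   ratio per centre.
#' @export
frequency_sweep <- function(recording, centers = seq(4, 32, by = 4),
                            width = 4, N = 8, T_ms = 160, ...) {
  if (any(centers + width / 2 >= 500)) {
    stop("band extends beyond the Nyquist frequency (500 Hz)")
  }
  # one run with shared epoch sets: every band and the spike count are
  # evaluated on identical epochs, so the ratio denominator is common
  codes <- c(lapply(centers, function(fc) {
    band <- filter_spec("butterworth", fc - width / 2, fc + width / 2)
    code_spec("phase", N = N, T_ms = T_ms, band = band,
              label = sprintf("phase_%g", fc))
  }), list(code_spec("count_scalar", T_ms = T_ms)))
  r <- run_comparison(recording, codes, T_ms = T_ms, ...)
  per_set <- r$per_set |>
    dplyr::mutate(center_hz = suppressWarnings(
      as.numeric(sub("phase_", "", .data$code))))
  out <- new_experiment_result(per_set, params = list(centers = centers))
  chance <- 100 / (list(...)$K %||% 10)
  count_pc <- mean(per_set$percent_correct[per_set$code == "count_scalar"])
  out$ratio <- out$summary |>
    dplyr::filter(!is.na(.data$center_hz)) |>
    dplyr::transmute(.data$center_hz, phase_pc = .data$mean_pc,
                     count_pc = count_pc,
                     ratio = chance_subtracted_ratio(.data$mean_pc, count_pc,
                                                     chance))
  out
}

#' Window-length and bin-count sweeps
#'
#' Evaluates the codes along the two standard slices: varying the window
#' length `T` at fixed `N = 8`, and varying the number of bins `N` at fixed
#' `T = 160` ms.
#'
#' @param recording a `recording`.
#' @param kinds code kinds to evaluate (default time, phase, count_scalar).
#' @param T_values window lengths, ms (default `seq(80, 480, by = 80)`).
#' @param N_values bin counts (default `c(2, 4, 8, 16)`).
#' @param N_fixed,T_fixed the fixed parameter for each slice.
#' @param band oscillation band for the phase code.
#' @param ... passed to [run_comparison()].
#' @return an `experiment_result` with columns `T_ms` and `N` in its tables.
#' @export
parameter_sweep <- function(recording,
                            kinds = c("time", "phase", "count_scalar"),
                            T_values = seq(80, 480, by = 80),
                            N_values = c(2, 4, 8, 16),
                            N_fixed = 8, T_fixed = 160,
                            band = filter_spec(), ...) {
  grid <- dplyr::bind_rows(
    tibble::tibble(T_ms = T_values, N = N_fixed),
    tibble::tibble(T_ms = T_fixed, N = N_values))
  grid <- dplyr::distinct(grid)
  runs <- purrr::pmap(grid, function(T_ms, N) {
    codes <- lapply(kinds, function(k)
      code_spec(k, N = N, T_ms = T_ms, band = band))
    r <- run_comparison(recording, codes, T_ms = T_ms, ...)
    dplyr::mutate(r$per_set, T_ms = T_ms, N = N)
  })
  new_experiment_result(dplyr::bind_rows(runs),
                        params = list(T_values = T_values,
                                      N_values = N_values))
}

#' Correlation between phase coherence and decoding performance
#'
#' For each epoch set, the inter-trial phase coherence averaged within each
#' epoch window is correlated with the per-epoch decoding accuracy across
#' the epochs of the set, separately per code; per-set coefficients are then
#' averaged. Pearson and Spearman coefficients are both reported. Sets where
#' the coherence has zero variance are flagged and dropped from the average.
#'
#' @param recording a `recording`.
#' @param codes list of [code_spec()]s.
#' @param band band whose coherence is measured (default 2-6 Hz).
#' @param ... passed to [run_comparison()] (`keep_epochs` is forced on).
#' @return list with `correlations` (tibble: code, method, correlation,
#'   n_sets_used, n_flagged) and the underlying `experiment_result`.
#' @export
coherence_performance <- function(recording, codes, band = filter_spec(),
                                  ...) {
  res <- run_comparison(recording, codes, keep_epochs = TRUE, ...)
  ph <- extract_phase(recording, band)
  pe <- res$per_epoch
  pe$coherence <- vapply(seq_len(nrow(pe)), function(i)
    window_coherence(ph, pe$window_start[i], res$params$T_ms), numeric(1))
  per_set <- pe |>
    dplyr::group_by(.data$code, .data$set) |>
    dplyr::summarise(
      flagged = stats::sd(.data$coherence) == 0,
      pearson = if (flagged[1]) NA_real_ else
        stats::cor(.data$coherence, .data$accuracy),
      spearman = if (flagged[1]) NA_real_ else
        stats::cor(.data$coherence, .data$accuracy, method = "spearman"),
      .groups = "drop")
  correlations <- per_set |>
    tidyr::pivot_longer(c("pearson", "spearman"), names_to = "method",
                        values_to = "r") |>
    dplyr::group_by(.data$code, .data$method) |>
    dplyr::summarise(correlation = mean(.data$r, na.rm = TRUE),
                     n_sets_used = sum(!is.na(.data$r)),
                     n_flagged = sum(is.na(.data$r)), .groups = "drop")
  list(correlations = correlations, result = res, per_set = per_set)
}

#' Decoding under increasing sensory noise
#'
#' Re-generates the same synthetic unit (identical stimulus rate profile and
#' oscillation, via the shared master seed) at each background-noise level
#' and compares the codes. The levels follow the target-relative-to-
#' background dB convention: `none`, `+6` (low noise), `0` (medium), `-6`
#' (high noise; background r.m.s. twice the target's).
#'
#' @param config a [generator_config()] (its `noise_level_db` is overridden).
#' @param codes list of [code_spec()]s.
#' @param levels noise levels, in degradation order.
#' @param ... passed to [run_comparison()].
#' @return an `experiment_result` with a `noise_level` column.
#' @export
noise_level_experiment <- function(config, codes,
                                   levels = c("none", "+6", "0", "-6"),
                                   ...) {
  runs <- lapply(levels, function(lv) {
    cfg <- config
    cfg$noise_level_db <- lv
    rec <- generate_recording(cfg)
    r <- run_comparison(rec, codes, ...)
    dplyr::mutate(r$per_set, noise_level = lv)
  })
  per_set <- dplyr::bind_rows(runs) |>
    dplyr::mutate(noise_level = factor(.data$noise_level, levels = levels))
  new_experiment_result(per_set, params = list(levels = levels))
}
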