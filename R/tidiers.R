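#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a decoding result into its confusion table
#'
#' @param x a `decoding_result`.
#' @param ... unused.
#' @return a tibble with columns `true`, `decoded`, `n`.
#' @export
tidy.decoding_result <- function(x, ...) {
  K <- nrow(x$confusion)
  tibble::tibble(true = rep(seq_len(K), K),
                 decoded = rep(seq_len(K), each = K),
                 n = as.integer(x$confusion))
}

#' One-row summary of a decoding result
#'
#' @param x a `decoding_result`.
#' @param ... unused.
#' @return a tibble with `percent_correct`, `n_trials`, `n_stimuli`,
#'   `classifier`, `code`.
#' @export
glance.decoding_result <- function(x, ...) {
  tibble::tibble(percent_correct = x$percent_correct,
                 n_trials = x$n_trials,
                 n_stimuli = nrow(x$confusion),
                 classifier = x$classifier,
                 code = x$code)
}

#' Confusion-matrix heatmap for a decoding result
#'
#' @param object a `decoding_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.decoding_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$decoded, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(breaks = unique(df$true)) +
    ggplot2::scale_x_continuous(breaks = unique(df$decoded)) +
    ggplot2::labs(x = "decoded stimulus", y = "true stimulus",
                  fill = "trials",
                  title = sprintf("%s / %s: %.1f%% correct", object$code,
                                  object$classifier,
                                  object$percent_correct)) +
    ggplot2::theme_minimal()
}

#' Mean +/- s.e.m. plot of an experiment result
#'
#' Draws mean percent correct per code with s.e.m. error bars; if the
#' result carries a sweep variable (`jitter_ms`, `center_hz`, `T_ms`, `N`,
#' or `noise_level`), it is used as the x axis with one line per code.
#'
#' @param object an `experiment_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.experiment_result <- function(object, ...) {
  sm <- object$summary
  sweep_var <- intersect(c("jitter_ms", "center_hz", "T_ms", "N",
                           "noise_level"), names(sm))
  if (length(sweep_var)) {
    v <- sweep_var[1]
    ggplot2::ggplot(sm, ggplot2::aes(x = .data[[v]], y = .data$mean_pc,
                                     colour = .data$code,
                                     group = .data$code)) +
      ggplot2::geom_line() +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_pc - .data$sem,
                                            ymax = .data$mean_pc + .data$sem)) +
      ggplot2::labs(x = v, y = "percent correct") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(sm, ggplot2::aes(x = .data$code, y = .data$mean_pc)) +
      ggplot2::geom_col(fill = "grey70") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_pc - .data$sem,
                                          ymax = .data$mean_pc + .data$sem),
                             width = 0.2) +
      ggplot2::labs(x = NULL, y = "percent correct") +
      ggplot2::theme_minimal()
  }
}

#' Plot inter-trial phase coherence over time
#'
#' @param phase a `phase_series`.
#' @param downsample plot every `downsample`-th sample (default 10).
#' @return a ggplot.
#' @export
plot_coherence <- function(phase, downsample = 10) {
  itc <- intertrial_phase_coherence(phase)
  idx <- seq(1, length(itc), by = downsample)
  df <- tibble::tibble(time_ms = idx - 1, itc = itc[idx])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$itc)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (ms)", y = "inter-trial phase coherence") +
    ggplot2::theme_minimal()
}

#' Serialize a decoding result to JSON
#'
#' @param result a `decoding_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_decoding_result <- function(result, path) {
  jsonlite::write_json(
    list(percent_correct = result$percent_correct,
         confusion = result$confusion,
         per_stimulus_accuracy = result$per_stimulus_accuracy,
         classifier = result$classifier, code = result$code),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
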