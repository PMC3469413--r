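#' Chance decoding level
#' @param K number of stimulus classes.
#' @return percent correct expected from guessing.
#' @export
chance_level <- function(K) 100 / K

#' Excess performance of a partitioned code over the spike count
#'
#' The difference, in percentage points, between a partitioning scheme's
#' percent correct and the spike count's, on the same unit, classifier and
#' epochs. It isolates the performance the code carries above and beyond
#' the total spike count.
#'
#' @param code_pc percent correct of the partitioned code.
#' @param count_pc percent correct of the spike count.
#' @return percentage points (vectorized).
#' @export
excess_performance <- function(code_pc, count_pc) code_pc - count_pc

#' Relative excess of the phase-partitioned code
#'
#' Expresses the phase code's excess over the spike count as a percentage of
#' the time code's excess: `100 * (phase - count) / (time - count)`.
#' Computed per unit and then averaged across units when summarizing a
#' population (the population-mean version can be formed from the same
#' per-unit table).
#'
#' @param phase_pc,time_pc,count_pc percent correct of the three codes.
#' @return percent (vectorized); `NA` where the time code has no excess.
#' @export
relative_excess <- function(phase_pc, time_pc, count_pc) {
  den <- time_pc - count_pc
  ifelse(den <= 0, NA_real_, 100 * (phase_pc - count_pc) / den)
}

#' Chance-subtracted performance ratio
#'
#' `(code - chance) / (count - chance)`: the gain factor of a code over the
#' spike count once guessing performance is removed. Undefined (returned as
#' `NA` with a warning) when the count does not exceed chance.
#'
#' @param code_pc percent correct of the code (e.g. phase-partitioned).
#' @param count_pc percent correct of the spike count.
#' @param chance_pc chance level in percent (see [chance_level()]).
#' @return numeric ratio (vectorized).
#' @export
chance_subtracted_ratio <- function(code_pc, count_pc, chance_pc) {
  den <- count_pc - chance_pc
  bad <- den <= 0
  if (any(bad, na.rm = TRUE)) {
    warning("count performance at or below chance: ratio undefined, returning NA")
  }
  ifelse(bad, NA_real_, (code_pc - chance_pc) / den)
}

#' Gain of the dual code over the best individual code
#'
#' `100 * (dual - best) / (best - chance)`, in percent; small values mean
#' the time- and phase-partitioned codes are largely redundant. Negative
#' values (overfitting of the higher-dimensional dual code) are allowed and
#' reported.
#'
#' @param dual_pc percent correct of the dual code.
#' @param best_pc percent correct of the better individual code.
#' @param chance_pc chance level in percent.
#' @return percent (vectorized); `NA` when `best_pc` is at or below chance.
#' @export
dual_gain <- function(dual_pc, best_pc, chance_pc) {
  den <- best_pc - chance_pc
  bad <- den <= 0
  if (any(bad, na.rm = TRUE)) {
    warning("best individual code at or below chance: gain undefined, returning NA")
  }
  ifelse(bad, NA_real_, 100 * (dual_pc - best_pc) / den)
}

#' Population-level comparisons across units
#'
#' Takes a per-unit table of mean percent correct per code and reports:
#' paired t-tests between each pair of codes (uncorrected, matching the
#' small number of planned comparisons; Bonferroni-adjusted p-values are
#' included as a column), the Spearman rank correlation between the
#' per-unit excess of the time- and phase-partitioned codes over the count,
#' and mean +/- s.e.m. summaries per code (s.e.m. across units).
#'
#' @param units a data frame with one row per unit and columns `time`,
#'   `phase`, plus a count column (`count_scalar` or `count`).
#' @return list with `pairwise` (tibble of paired t-tests), `excess_cor`
#'   (Spearman between per-unit excesses), and `summary`.
#' @export
population_tests <- function(units) {
  units <- as.data.frame(units)
  count_col <- intersect(c("count_scalar", "count", "count_shuffled"),
                         names(units))[1]
  if (is.na(count_col)) stop("`units` needs a count column")
  if (!all(c("time", "phase") %in% names(units))) {
    stop("`units` needs `time` and `phase` columns")
  }
  if (nrow(units) < 3) stop("population tests need at least 3 units")
  codes <- c("time", "phase", count_col)
  pairs <- utils::combn(codes, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(p) {
    tt <- stats::t.test(units[[p[1]]], units[[p[2]]], paired = TRUE)
    tibble::tibble(code_a = p[1], code_b = p[2],
                   mean_diff = unname(tt$estimate),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p_value = tt$p.value)
  })
  pairwise$p_bonferroni <- pmin(pairwise$p_value * nrow(pairwise), 1)
  excess_time <- units$time - units[[count_col]]
  excess_phase <- units$phase - units[[count_col]]
  excess_cor <- stats::cor(excess_time, excess_phase, method = "spearman")
  summary <- purrr::map_dfr(codes, function(cd) {
    tibble::tibble(code = cd, mean_pc = mean(units[[cd]]),
                   sem = stats::sd(units[[cd]]) / sqrt(nrow(units)),
                   n_units = nrow(units))
  })
  list(pairwise = pairwise, excess_cor = excess_cor, summary = summary)
}

#' Per-unit summary of code performance and derived metrics
#'
#' Combines per-code percent correct into the derived quantities used for
#' population reporting: excess over the count, relative excess of phase
#' vs. time, chance-subtracted ratio, and the dual-code gain when a dual
#' column is present.
#'
#' @param units data frame, one row per unit, columns `time`, `phase`, a
#'   count column, optionally `dual`.
#' @param K number of stimulus classes used for decoding (default 10).
#' @return a tibble with the input columns plus the derived metrics.
#' @export
unit_summary <- function(units, K = 10) {
  units <- tibble::as_tibble(units)
  count_col <- intersect(c("count_scalar", "count", "count_shuffled"),
                         names(units))[1]
  if (is.na(count_col)) stop("`units` needs a count column")
  ch <- chance_level(K)
  cnt <- units[[count_col]]
  out <- units |>
    dplyr::mutate(
      excess_time = excess_performance(.data$time, cnt),
      excess_phase = excess_performance(.data$phase, cnt),
      relative_excess = relative_excess(.data$phase, .data$time, cnt),
      ratio_phase = chance_subtracted_ratio(.data$phase, cnt, ch))
  if ("dual" %in% names(units)) {
    out$dual_gain <- dual_gain(units$dual, pmax(units$time, units$phase), ch)
  }
  out
}
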