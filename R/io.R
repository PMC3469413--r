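#' Write a recording to a directory of plain-text files
#'
#' Spikes go to `spikes.csv` (columns `trial`, `spike_time_ms`), the LFP to
#' `lfp.csv` (one row per trial), and the configuration to `config.json`.
#' Numeric values are written with 17 significant digits so the round trip
#' through [read_recording()] is exact for spike times and accurate to better
#' than 1e-9 relative for the LFP.
#'
#' @param recording a `recording`.
#' @param dir directory to create/write into.
#' @return `dir`, invisibly.
#' @export
write_recording <- function(recording, dir) {
  stopifnot(inherits(recording, "recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  st <- spike_table(recording)
  st$spike_time_ms <- sprintf("%.17g", st$spike_time_ms)
  utils::write.csv(st, file.path(dir, "spikes.csv"), row.names = FALSE,
                   quote = FALSE)
  lfp_chr <- apply(recording$lfp, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lfp_chr, file.path(dir, "lfp.csv"))
  cfg <- recording$config
  if (inherits(cfg, "generator_config")) cfg <- unclass(cfg)
  meta <- list(n_trials = n_trials(recording),
               duration_ms = duration_ms(recording),
               config = cfg)
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a recording written by [write_recording()]
#'
#' @param dir directory containing `spikes.csv`, `lfp.csv`, `config.json`.
#' @return a `recording` (ground truth is not serialized and comes back
#'   `NULL`).
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  lfp_chr <- readLines(file.path(dir, "lfp.csv"))
  lfp <- do.call(rbind, lapply(strsplit(lfp_chr, ","), as.numeric))
  st <- utils::read.csv(file.path(dir, "spikes.csv"))
  spikes <- rep(list(numeric(0)), meta$n_trials)
  if (nrow(st)) {
    by_trial <- split(st$spike_time_ms, factor(st$trial,
                                               levels = seq_len(meta$n_trials)))
    spikes <- lapply(by_trial, as.numeric)
  }
  cfg <- meta$config
  if (!is.null(cfg$osc_freq_hz)) {
    cfg <- generator_config(
      duration_ms = cfg$duration_ms, n_trials = cfg$n_trials,
      osc_freq_hz = cfg$osc_freq_hz, entrainment_kappa = cfg$entrainment_kappa,
      osc_amplitude = cfg$osc_amplitude, noise_amplitude = cfg$noise_amplitude,
      freq_jitter_hz = cfg$freq_jitter_hz,
      baseline_rate_hz = cfg$baseline_rate_hz,
      rate_mod_depth = cfg$rate_mod_depth,
      phase_coupling = cfg$phase_coupling, phase_pref = cfg$phase_pref,
      profile_timescale_ms = cfg$profile_timescale_ms,
      noise_level_db = cfg$noise_level_db, seed = cfg$seed)
  }
  new_recording(lfp, unname(spikes), cfg, NULL)
}
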