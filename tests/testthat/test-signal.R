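t10 <- (0:9999) / 1000 # 10 s at 1 kHz

test_that("in-band tones pass and out-of-band tones are rejected", {
  sp <- filter_spec("butterworth", 2, 6)
  x4 <- cos(2 * pi * 4 * t10)
  y4 <- bandpass(x4, sp)
  core <- 600:9400
  expect_gt(cor(x4[core], y4[core]), 0.99)

  x30 <- cos(2 * pi * 30 * t10)
  y30 <- bandpass(x30, sp)
  # Oracle: squared magnitude of the 3rd-order band-pass response at 30 Hz,
  # evaluated from the designed filter (two-pass doubles the attenuation).
  bf <- signal::butter(3, c(2, 6) / 500, "pass")
  w <- 2 * pi * 30 / 1000
  z <- exp(-1i * w * (seq_along(bf$b) - 1))
  H30 <- Mod(sum(bf$b * z) / sum(bf$a * z))^2
  ratio <- sd(y30[core]) / sd(x30[core])
  expect_lt(ratio, 0.05)
  # two-pass attenuation agrees with the designed response up to the
  # numerical floor set by the forward-backward edge transients
  expect_lt(H30, 0.05)
  expect_lt(ratio, 10 * H30)

  expect_identical(sum(abs(bandpass(rep(0, 5000), sp))), 0)
  expect_error(filter_spec("butterworth", 2, 600), "Nyquist")
})

test_that("the phase convention puts cosine peaks at phase 0", {
  circ_dist <- function(a, b) abs((a - b + pi) %% (2 * pi) - pi)
  ph <- instantaneous_phase(matrix(cos(2 * pi * 4 * t10), 1))
  expect_lt(circ_dist(ph$phase[1, 1], 0), 1e-6)
  expect_lt(circ_dist(ph$phase[1, 251], 0), 0.01)
  # phase advances at 2*pi*4 rad/s
  core <- 1000:9000
  dphi <- diff(ph$phase[1, core]) %% (2 * pi)
  expect_equal(mean(dphi), 2 * pi * 4 / 1000, tolerance = 1e-3)

  phs <- instantaneous_phase(matrix(sin(2 * pi * 4 * t10), 1))
  expect_equal(phs$phase[1, 1], 3 * pi / 2, tolerance = 0.01)

  ph2 <- instantaneous_phase(matrix(7.3 * cos(2 * pi * 4 * t10), 1))
  expect_equal(ph2$phase, ph$phase, tolerance = 1e-9)
})

test_that("inter-trial phase coherence handles the analytic cases", {
  p <- matrix(runif(5 * 100, 0, 2 * pi), 5, 100)
  same <- matrix(rep(p[1, ], each = 4), 4)
  expect_equal(intertrial_phase_coherence(same), rep(1, 100))
  anti <- rbind(rep(0, 10), rep(pi, 10))
  expect_equal(intertrial_phase_coherence(anti), rep(0, 10))
  quad <- matrix(c(0, pi / 2, pi, 3 * pi / 2), 4, 10)
  expect_equal(intertrial_phase_coherence(quad), rep(0, 10))
  itc <- intertrial_phase_coherence(p)
  expect_true(all(itc >= 0 & itc <= 1))
  # invariant under a common phase offset at each time point
  shift <- matrix(runif(100), 5, 100, byrow = TRUE)
  expect_equal(intertrial_phase_coherence((p + shift) %% (2 * pi)), itc)
  expect_error(intertrial_phase_coherence(p[1, , drop = FALSE]), "single trial")
})

test_that("window coherence averages the per-sample resultants", {
  # hand-built 3-trial phase array over a 4-sample window
  p <- rbind(c(0.0, 1.0, 2.0, 3.0),
             c(0.5, 1.5, 1.0, 0.0),
             c(6.0, 0.2, 2.5, 3.1))
  by_hand <- mean(sapply(1:4, function(t) Mod(mean(exp(1i * p[, t])))))
  expect_equal(window_coherence(p, 0, 4), by_hand)
  const <- matrix(1.3, 3, 50)
  expect_equal(window_coherence(const, 10, 20), 1.0)
  expect_error(window_coherence(p, 2, 4), "out of range")
})

test_that("phase-partitioned decoding is robust to the filter family", {
  rec <- generate_recording(standard_unit_config(31))
  variants <- list(
    filter_spec("butterworth", 2, 6),
    filter_spec("butterworth", 2, 10),
    filter_spec("kaiser_fir", 2, 6, transition_hz = 1,
                ripple_db = 0.01, attenuation_db = 60),
    filter_spec("kaiser_fir", 2, 8, transition_hz = 2,
                ripple_db = 0.01, attenuation_db = 30),
    filter_spec("morlet", center_hz = 4, sigma_hz = 0.6 / 4))
  codes <- lapply(seq_along(variants), function(i)
    code_spec("phase", band = variants[[i]], label = paste0("phase_", i)))
  r <- run_comparison(rec, codes, n_sets = 6, seed = 5)
  overall <- glance(r)
  expect_lt((max(overall$mean_pc) - min(overall$mean_pc)) /
              mean(overall$mean_pc), 0.10)
})

test_that("filter specs serialize losslessly and flag short data", {
  sp <- filter_spec("kaiser_fir", 2, 8, transition_hz = 2, attenuation_db = 30)
  f <- tempfile(fileext = ".json")
  write_filter_spec(sp, f)
  expect_equal(read_filter_spec(f), sp)
  expect_warning(bandpass(rnorm(500), filter_spec("butterworth", 2, 6)),
                 "edge effects")
})

test_that("phase matrices export to the shared matrix container", {
  rec <- quick_recording(seed = 33, duration_ms = 2000, n_trials = 4)
  ph <- extract_phase(rec)
  f <- tempfile(fileext = ".csv")
  write_phase_series(ph, f)
  back <- read_phase_matrix(f)
  expect_equal(dim(back), dim(ph$phase))
  expect_lt(max(abs(back - ph$phase)), 1e-9)
  unlink(f)
})
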