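test_that("the generator is bit-deterministic in its master seed", {
  r1 <- quick_recording(seed = 11)
  r2 <- quick_recording(seed = 11)
  r3 <- quick_recording(seed = 12)
  expect_identical(r1$lfp, r2$lfp)
  expect_identical(r1$spikes, r2$spikes)
  expect_false(identical(r1$spikes, r3$spikes))
  expect_false(identical(r1$lfp, r3$lfp))
})

test_that("recording dimensions and spike-time bounds honour the config", {
  cfg <- generator_config(duration_ms = 52000, n_trials = 50, seed = 2)
  rec <- generate_recording(cfg, keep_ground_truth = FALSE)
  expect_equal(dim(rec$lfp), c(50, 52000))
  expect_length(rec$spikes, 50)
  st <- spike_table(rec)
  expect_true(all(st$spike_time_ms >= 0 & st$spike_time_ms < 52000))
  expect_error(generator_config(duration_ms = -5), "duration")
  expect_error(generator_config(n_trials = 0), "n_trials")
  expect_error(generator_config(rate_mod_depth = 1.5), "rate_mod_depth")
})

test_that("perfect entrainment without noise gives identical trials and unit ITC", {
  rec <- quick_recording(seed = 3, entrainment_kappa = Inf, noise_amplitude = 0)
  expect_true(all(abs(sweep(rec$lfp, 2, rec$lfp[1, ])) < 1e-12))
  itc <- intertrial_phase_coherence(extract_phase(rec))
  expect_true(all(itc > 1 - 1e-6))
})

test_that("zero entrainment ITC matches the uniform-phase resultant expectation", {
  # Oracle: Monte-Carlo distribution of the resultant length of n uniform
  # phases, frozen via its analytic mean ~ sqrt(pi)/(2 sqrt(n)).
  n <- 200
  set.seed(99)
  oracle <- mean(replicate(400, Mod(mean(exp(1i * runif(n, 0, 2 * pi))))))
  itcs <- sapply(1:8, function(s) {
    cfg <- generator_config(duration_ms = 3000, n_trials = n,
                            entrainment_kappa = 0, noise_amplitude = 0,
                            seed = 100 + s)
    f <- generate_lfp(cfg)
    mean(intertrial_phase_coherence(f$phase[, 500:2500]))
  })
  expect_equal(mean(itcs), oracle, tolerance = 0.15)
  expect_lt(mean(itcs), 0.12) # far from any locking
})

test_that("without an oscillation the LFP is uncorrelated with the latent cosine", {
  cfg <- quick_config(seed = 5, osc_amplitude = 0, noise_amplitude = 1)
  f <- generate_lfp(cfg)
  cors <- sapply(seq_len(cfg$n_trials), function(i)
    cor(f$lfp[i, ], cos(f$phi_star)))
  expect_true(all(abs(cors) < 0.15))
})

test_that("window-averaged ITC is non-decreasing in entrainment strength", {
  kappas <- c(0, 0.5, 2, 8, 32)
  mean_itc <- sapply(kappas, function(k) {
    mean(sapply(1:20, function(s) {
      cfg <- generator_config(duration_ms = 2000, n_trials = 25,
                              entrainment_kappa = k, noise_amplitude = 0,
                              seed = 1000 * s + 7)
      f <- generate_lfp(cfg)
      mean(intertrial_phase_coherence(f$phase[, 200:1800]))
    }))
  })
  expect_true(all(diff(mean_itc) > 0))
})

test_that("homogeneous firing matches the Poisson count distribution", {
  cfg <- generator_config(duration_ms = 52000, n_trials = 40,
                          rate_mod_depth = 0, phase_coupling = 0,
                          baseline_rate_hz = 10, seed = 8)
  f <- generate_lfp(cfg)
  sp <- generate_spikes(cfg, f$phase)
  T_ms <- 160
  edges <- seq(0, 51840, by = T_ms)
  counts <- unlist(lapply(sp$spikes, function(s)
    tabulate(findInterval(s, edges), nbins = length(edges))))
  expect_gte(length(counts), 1e4)
  expect_equal(mean(counts), 1.6, tolerance = 0.03)
  lambda <- 10 * T_ms / 1000
  kmax <- max(counts)
  probs <- dpois(0:kmax, lambda)
  probs[kmax + 1] <- probs[kmax + 1] + ppois(kmax, lambda, lower.tail = FALSE)
  ct <- suppressWarnings(chisq.test(tabulate(counts + 1, kmax + 1), p = probs))
  expect_gt(ct$p.value, 0.01)
})

test_that("phase coupling concentrates spike phases at the preferred phase", {
  cfg <- generator_config(duration_ms = 20000, n_trials = 30,
                          rate_mod_depth = 0, phase_coupling = 1,
                          phase_pref = 0, entrainment_kappa = 0,
                          noise_amplitude = 0, seed = 9)
  f <- generate_lfp(cfg)
  sp <- generate_spikes(cfg, f$phase)
  N <- 8
  hist_counts <- integer(N)
  for (tr in seq_len(cfg$n_trials)) {
    v <- phase_partitioned(sp$spikes[[tr]], f$phase[tr, ], 0, N,
                           cfg$duration_ms)
    hist_counts <- hist_counts + v
  }
  # Oracle: integral of 1 + cos(phi) over each phase bin, normalized.
  edges <- seq(0, 2 * pi, length.out = N + 1)
  expected <- diff(edges + sin(edges)) / (2 * pi)
  observed <- hist_counts / sum(hist_counts)
  peak_bins <- c(1, N) # bins containing phase 0 (wrapping)
  expect_true(which.max(hist_counts) %in% peak_bins)
  expect_equal(observed, expected, tolerance = 0.05)
})

test_that("background-noise r.m.s. follows the dB mapping (high noise = 2x target)", {
  for (lv in c("+6", "0", "-6")) {
    # small modulation depth keeps the rate away from the zero floor so the
    # noise component can be recovered exactly from the rate decomposition
    cfg <- quick_config(seed = 10, noise_level_db = lv, rate_mod_depth = 0.1)
    f <- generate_lfp(cfg)
    lat <- phasecode:::generator_rate(cfg, f$phase)
    target <- cfg$rate_mod_depth * lat$profile
    # recover one trial's noise component from the rate decomposition
    osc <- 1 + cfg$phase_coupling * cos(f$phase[1, ] - cfg$phase_pref)
    bracket <- lat$rate[1, ] / (cfg$baseline_rate_hz * osc)
    noise <- bracket - 1 - target
    expected_factor <- c("+6" = 0.5, "0" = 1, "-6" = 2)[[lv]]
    expect_equal(sqrt(mean(noise^2)) / sqrt(mean(target^2)),
                 expected_factor, tolerance = 0.05)
  }
})

test_that("extracted Hilbert phase recovers the latent phase of a clean LFP", {
  cfg <- quick_config(seed = 12, duration_ms = 8000, noise_amplitude = 0)
  rec <- generate_recording(cfg)
  ph <- extract_phase(rec)
  core <- 1500:6500
  d <- (ph$phase[, core] - rec$ground_truth$phase[, core] + pi) %% (2 * pi) - pi
  expect_lt(sqrt(mean(d^2)), 0.1)
  # circular correlation between extracted and latent phase
  a <- as.numeric(ph$phase[, core]); b <- as.numeric(rec$ground_truth$phase[, core])
  ccor <- min(cor(sin(a), sin(b)), cor(cos(a), cos(b)))
  expect_gt(ccor, 0.95)
})

test_that("von Mises sampler hits its analytic mean resultant length", {
  set.seed(42)
  for (k in c(0.5, 4)) {
    th <- rvonmises(4000, mu = 1, kappa = k)
    r_hat <- Mod(mean(exp(1i * th)))
    r_expected <- besselI(k, 1) / besselI(k, 0)
    expect_equal(r_hat, r_expected, tolerance = 0.05)
    expect_equal(Arg(mean(exp(1i * th))), 1, tolerance = 0.1)
  }
  expect_identical(rvonmises(3, 0.5, Inf), rep(0.5, 3))
})
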