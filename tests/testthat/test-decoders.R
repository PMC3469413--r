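test_that("perfectly separated ensembles decode at 100 percent", {
  ens <- toy_ensemble(lapply(1:3, function(i) matrix(i, 4, 2)))
  res <- loo_decode(ens, "nearest_mean")
  expect_equal(res$percent_correct, 100)
  expect_equal(res$confusion, diag(4L, 3))
})

test_that("fully degenerate ensembles tie-break to stimulus 1", {
  ens <- toy_ensemble(lapply(1:5, function(i) matrix(2, 3, 2)))
  res <- loo_decode(ens, "nearest_mean")
  expect_equal(res$percent_correct, 100 / 5)
  expect_true(all(res$confusion[, 1] == 3))
})

test_that("nearest-mean matches brute-force template matching on random ensembles", {
  set.seed(101)
  for (i in 1:60) {
    K <- sample(2:3, 1)
    nt <- sample(2:4, 1)
    d <- sample(1:3, 1)
    ens <- random_toy_ensemble(K, nt, d)
    res <- loo_decode(ens, "nearest_mean")
    oracle <- brute_nearest_mean(ens$responses)
    if (oracle$margin > 1e-9) {
      expect_identical(res$confusion,
                       confusion_from_decoded(oracle$decoded, K))
    }
  }
})

test_that("naive Bayes decoders match brute-force likelihood argmax", {
  set.seed(202)
  for (i in 1:40) {
    K <- sample(2:3, 1)
    nt <- sample(3:4, 1)
    d <- sample(1:3, 1)
    ens <- random_toy_ensemble(K, nt, d)
    op <- brute_nb(ens$responses, "poisson")
    if (op$margin > 1e-9) {
      expect_identical(loo_decode(ens, "poisson_nb")$confusion,
                       confusion_from_decoded(op$decoded, K))
    }
    om <- brute_nb(ens$responses, "multinomial")
    if (om$margin > 1e-9) {
      expect_identical(loo_decode(ens, "multinomial_nb")$confusion,
                       confusion_from_decoded(om$decoded, K))
    }
  }
})

test_that("a hand-built 2-stimulus ensemble reproduces exhaustive LOO distances", {
  r1 <- rbind(c(1L, 2L), c(2L, 1L), c(1L, 1L))
  r2 <- rbind(c(4L, 5L), c(5L, 4L), c(4L, 4L))
  ens <- toy_ensemble(list(r1, r2))
  res <- loo_decode(ens, "nearest_mean")
  expect_identical(res$confusion,
                   confusion_from_decoded(brute_nearest_mean(list(r1, r2))$decoded, 2L))
  expect_equal(res$percent_correct, 100)
})

test_that("Poisson likelihood arithmetic matches the closed form", {
  m <- list(means = 2, n_train = 10)
  expect_equal(nb_loglik(2L, m, "poisson"), log(2^2 * exp(-2) / 2))
  # zero training mean is floored, not -Inf
  m0 <- list(means = 0, n_train = 10)
  expect_equal(nb_loglik(1L, m0, "poisson"),
               dpois(1, 1 / 20, log = TRUE))
  # multinomial smoothing never yields -Inf
  freq <- matrix(0L, 2, 4) # two bins, counts 0..3 never observed
  expect_true(is.finite(nb_loglik(c(3L, 3L),
                                  list(freq = freq, n_train = 5),
                                  "multinomial")))
})

test_that("an identity-covariance linear classifier reduces to nearest mean", {
  set.seed(303)
  for (i in 1:10) {
    ens <- random_toy_ensemble(3, 4, 2)
    nm <- loo_decode(ens, "nearest_mean")
    lin <- loo_decode(ens, classifier_spec("linear", regularization_sd = 0,
                                           cov = "identity"))
    expect_identical(lin$confusion, nm$confusion)
  }
})

test_that("permuting stimulus labels permutes the confusion matrix", {
  set.seed(404)
  resp <- lapply(1:4, function(i) matrix(rpois(6 * 2, i), 6, 2))
  perm <- c(3, 1, 4, 2)
  res <- loo_decode(toy_ensemble(resp), "poisson_nb")
  res_p <- loo_decode(toy_ensemble(resp[perm]), "poisson_nb")
  expect_identical(res_p$confusion, res$confusion[perm, perm])
})

test_that("knn votes among nearest neighbours with deterministic ties", {
  # stimulus 1 trials cluster at 0, stimulus 2 at 10
  r1 <- matrix(c(0L, 0L, 1L, 0L, 0L, 1L), 3, 2)
  r2 <- r1 + 10L
  res <- loo_decode(toy_ensemble(list(r1, r2)),
                    classifier_spec("knn", k = 2))
  expect_equal(res$percent_correct, 100)
  # all points identical: every vote ties, lowest stimulus index wins
  same <- toy_ensemble(lapply(1:2, function(i) matrix(1L, 3, 2)))
  res2 <- loo_decode(same, classifier_spec("knn", k = 3))
  expect_true(all(res2$confusion[, 1] == 3))
})

test_that("gaussian discriminants with regularization decode separable data", {
  set.seed(505)
  resp <- lapply(1:3, function(i) matrix(rpois(20 * 3, 3 * i), 20, 3))
  for (cl in c("linear", "quadratic")) {
    res <- loo_decode(toy_ensemble(resp), cl, seed = 9)
    expect_gt(res$percent_correct, 70)
    # deterministic under the same classifier seed
    res2 <- loo_decode(toy_ensemble(resp), cl, seed = 9)
    expect_identical(res$confusion, res2$confusion)
  }
})

test_that("decoding errors on degenerate ensembles are informative", {
  one_trial <- toy_ensemble(list(matrix(1L, 1, 2), matrix(2L, 3, 2)))
  expect_error(loo_decode(one_trial, "nearest_mean"), "at least 2 trials")
})

test_that("shuffled-count decoding averages over repeats and matches scalar count", {
  # property: bin-shuffled and scalar spike-count codes carry the same
  # information; their decoding performance agrees across many units
  pcs <- sapply(1:40, function(u) {
    rec <- quick_recording(seed = 600 + u, duration_ms = 4000, n_trials = 8)
    eps <- withr::with_seed(u, sample_epochs(500, 3500, 6, 160))
    te <- build_ensemble(rec, eps, code_spec("time"))
    sh <- shuffled_count_decode(te, "nearest_mean", repeats = 10, seed = u)
    sc <- loo_decode(build_ensemble(rec, eps, code_spec("count_scalar")),
                     "nearest_mean")
    c(sh$percent_correct, sc$percent_correct)
  })
  tt <- t.test(pcs[1, ], pcs[2, ], paired = TRUE)
  expect_gt(tt$p.value, 0.01)
  expect_lt(abs(mean(pcs[1, ] - pcs[2, ])), 3)
})
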