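# Small fixture builders shared across test files.

quick_config <- function(seed = 1, ...) {
  args <- list(duration_ms = 6000, n_trials = 10, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(generator_config, args)
}

quick_recording <- function(seed = 1, ...) {
  generate_recording(quick_config(seed, ...))
}

# Hand-rollable ensemble from a list of per-stimulus response matrices.
toy_ensemble <- function(responses, kind = "time") {
  d <- ncol(responses[[1]])
  structure(list(responses = lapply(responses, function(m) {
    storage.mode(m) <- "integer"; m
  }),
  K = length(responses), dimension = d,
  n_trials = nrow(responses[[1]]),
  code = code_spec(kind, N = max(d, 1L), T_ms = 160),
  starts = seq_len(length(responses)), T_ms = 160),
  class = "response_ensemble")
}

# Brute-force leave-one-out nearest-mean decoding, written directly from the
# template-matching definition, kept independent of the package internals.
brute_nearest_mean <- function(responses) {
  K <- length(responses)
  decoded <- list()
  margin <- Inf
  for (i in seq_len(K)) {
    ni <- nrow(responses[[i]])
    decoded[[i]] <- integer(ni)
    for (j in seq_len(ni)) {
      test <- responses[[i]][j, ]
      dists <- sapply(seq_len(K), function(g) {
        rows <- responses[[g]]
        if (g == i) rows <- rows[-j, , drop = FALSE]
        mu <- colMeans(rows)
        sum((test - mu)^2)
      })
      decoded[[i]][j] <- which.min(dists)
      srt <- sort(dists)
      margin <- min(margin, srt[2] - srt[1])
    }
  }
  list(decoded = decoded, margin = margin)
}

# Brute-force naive-Bayes LOO decoding (Poisson or multinomial), directly
# from the log-likelihood definitions.
brute_nb <- function(responses, type = "poisson", max_count = NULL) {
  K <- length(responses)
  d <- ncol(responses[[1]])
  if (is.null(max_count)) max_count <- max(sapply(responses, max))
  decoded <- list()
  margin <- Inf
  for (i in seq_len(K)) {
    ni <- nrow(responses[[i]])
    decoded[[i]] <- integer(ni)
    for (j in seq_len(ni)) {
      test <- responses[[i]][j, ]
      ll <- sapply(seq_len(K), function(g) {
        rows <- responses[[g]]
        if (g == i) rows <- rows[-j, , drop = FALSE]
        n_tr <- nrow(rows)
        if (type == "poisson") {
          lambda <- pmax(colMeans(rows), 1 / (2 * n_tr))
          sum(dpois(test, lambda, log = TRUE))
        } else {
          n_levels <- max_count + 1
          sum(sapply(seq_len(d), function(b) {
            f <- sum(rows[, b] == test[b])
            log((f + 1) / (n_tr + n_levels))
          }))
        }
      })
      decoded[[i]][j] <- which.max(ll)
      srt <- sort(ll, decreasing = TRUE)
      margin <- min(margin, srt[1] - srt[2])
    }
  }
  list(decoded = decoded, margin = margin)
}

# Flatten a decoding_result confusion into per-class decoded lists is not
# needed; compare decisions through the confusion matrix instead.
confusion_from_decoded <- function(decoded, K) {
  cm <- matrix(0L, K, K)
  for (i in seq_along(decoded)) {
    for (g in decoded[[i]]) cm[i, g] <- cm[i, g] + 1L
  }
  cm
}

# Random small count ensemble for oracle comparisons.
random_toy_ensemble <- function(K, n_trials, d, lambda = 2) {
  toy_ensemble(lapply(seq_len(K), function(i) {
    matrix(rpois(n_trials * d, lambda + i - 1), n_trials, d)
  }))
}
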