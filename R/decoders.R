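#' Classifier specification for single-trial decoding
#'
#' Six classifiers, all run under the same leave-one-out cross-validation:
#' * `nearest_mean` — Euclidean template matching against per-stimulus mean
#'   responses (the codebook); Bayes-optimal for independent equal-variance
#'   Gaussian response distributions;
#' * `linear` — Gaussian discriminant with a covariance matrix pooled across
#'   stimuli;
#' * `quadratic` — Gaussian discriminant with a full covariance matrix per
#'   stimulus;
#' * `poisson_nb` — naive Bayes assuming independent Poisson counts per bin;
#' * `multinomial_nb` — naive Bayes sampling the discrete per-bin count
#'   distributions with add-one smoothing;
#' * `knn` — majority vote among the `k` Euclidean-nearest training trials.
#'
#' For `linear`/`quadratic`, i.i.d. Gaussian jitter of s.d.
#' `regularization_sd` (default 0.001) is added to the discrete counts,
#' redrawn in every leave-one-out fold, to avoid ill-conditioned covariance
#' estimates. `cov = "identity"` forces the pooled covariance of the linear
#' classifier to the identity (a diagnostic that reduces it to
#' `nearest_mean`).
#'
#' @param name classifier name (see above).
#' @param k neighbours for `knn` (default 5).
#' @param regularization_sd jitter s.d. for the Gaussian discriminants.
#' @param cov `"estimate"` (default) or `"identity"` (linear only).
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("nearest_mean", "linear", "quadratic",
                                     "poisson_nb", "multinomial_nb", "knn"),
                            k = 5, regularization_sd = 0.001,
                            cov = c("estimate", "identity")) {
  name <- match.arg(name)
  cov <- match.arg(cov)
  if (k < 1 || k != round(k)) stop("`k` must be a positive integer")
  if (regularization_sd < 0) stop("`regularization_sd` must be non-negative")
  structure(list(name = name, k = as.integer(k),
                 regularization_sd = regularization_sd, cov = cov),
            class = "classifier_spec")
}

as_classifier <- function(x) {
  if (inherits(x, "classifier_spec")) x else classifier_spec(x)
}

# Flatten an ensemble into X (rows ordered by stimulus then trial), labels y.
ensemble_matrix <- function(ensemble) {
  X <- do.call(rbind, ensemble$responses)
  y <- rep(seq_len(ensemble$K),
           vapply(ensemble$responses, nrow, integer(1)))
  list(X = X, y = y)
}

#' Leave-one-out single-trial decoding
#'
#' For every trial of every stimulus: the trial is removed, per-stimulus mean
#' responses (the codebook) are computed from the remaining trials (the test
#' trial is excluded only from its own stimulus' mean), the trial is
#' classified according to `classifier`, and the confusion matrix is
#' accumulated. Ties are broken deterministically towards the lowest stimulus
#' index.
#'
#' When `codebook` is supplied (an ensemble over the same stimuli/trials,
#' e.g. one built from time-jittered windows), training responses are taken
#' from it while test responses come from `ensemble`; the row of `codebook`
#' belonging to the test trial is still left out.
#'
#' @param ensemble a `response_ensemble`.
#' @param classifier a [classifier_spec()] or classifier name.
#' @param codebook optional `response_ensemble` used for training responses.
#' @param seed optional integer seed for the classifier's own randomness
#'   (the per-fold regularization jitter).
#' @return a `decoding_result`: `percent_correct`, `confusion` (K x K, rows
#'   = true stimulus), `per_stimulus_accuracy`, and metadata.
#' @export
loo_decode <- function(ensemble, classifier = classifier_spec(),
                       codebook = NULL, seed = NULL) {
  stopifnot(inherits(ensemble, "response_ensemble"))
  classifier <- as_classifier(classifier)
  trials <- vapply(ensemble$responses, nrow, integer(1))
  if (any(trials < 2)) {
    stop("every stimulus needs at least 2 trials for leave-one-out decoding")
  }
  te <- ensemble_matrix(ensemble)
  tr <- if (is.null(codebook)) te else {
    stopifnot(inherits(codebook, "response_ensemble"),
              codebook$K == ensemble$K,
              codebook$n_trials == ensemble$n_trials)
    ensemble_matrix(codebook)
  }
  decoded <- if (is.null(seed)) {
    decode_all(te$X, tr$X, te$y, ensemble$K, classifier)
  } else {
    withr::with_seed(as.integer(seed),
                     decode_all(te$X, tr$X, te$y, ensemble$K, classifier))
  }
  confusion <- matrix(0L, ensemble$K, ensemble$K)
  for (i in seq_along(decoded)) {
    confusion[te$y[i], decoded[i]] <- confusion[te$y[i], decoded[i]] + 1L
  }
  new_decoding_result(confusion, classifier, ensemble$code)
}

new_decoding_result <- function(confusion, classifier, code) {
  total <- sum(confusion)
  structure(list(
    percent_correct = 100 * sum(diag(confusion)) / total,
    confusion = confusion,
    per_stimulus_accuracy = diag(confusion) / rowSums(confusion),
    n_trials = total,
    classifier = classifier$name,
    code = if (!is.null(code)) code$kind else NA_character_),
    class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s / %s: %.2f%% correct (%d trials, %d stimuli)\n",
              x$code, x$classifier, x$percent_correct, x$n_trials,
              nrow(x$confusion)))
  invisible(x)
}

decode_all <- function(Xte, Xtr, y, K, classifier) {
  switch(classifier$name,
         nearest_mean = decode_nearest_mean(Xte, Xtr, y, K),
         linear = decode_gaussian(Xte, Xtr, y, K, classifier, pooled = TRUE),
         quadratic = decode_gaussian(Xte, Xtr, y, K, classifier,
                                     pooled = FALSE),
         poisson_nb = decode_poisson_nb(Xte, Xtr, y, K),
         multinomial_nb = decode_multinomial_nb(Xte, Xtr, y, K),
         knn = decode_knn(Xte, Xtr, y, K, classifier$k))
}

# Vectorized nearest-mean: distances of every test row to every class mean,
# with the test trial's own class mean recomputed without it.
decode_nearest_mean <- function(Xte, Xtr, y, K) {
  n <- nrow(Xte)
  sums <- rowsum(Xtr, y)                 # K x d
  counts <- as.numeric(table(factor(y, levels = seq_len(K))))
  M <- sums / counts
  D <- outer(rowSums(Xte^2), rep(1, K)) +
    outer(rep(1, n), rowSums(M^2)) - 2 * Xte %*% t(M)
  # own-class column: mean without the test trial's codebook row
  own <- (sums[y, , drop = FALSE] - Xtr) / (counts[y] - 1)
  d_own <- rowSums((Xte - own)^2)
  D[cbind(seq_len(n), y)] <- d_own
  max.col(-D, ties.method = "first")
}

decode_gaussian <- function(Xte, Xtr, y, K, classifier, pooled) {
  n <- nrow(Xte)
  d <- ncol(Xte)
  out <- integer(n)
  identity_cov <- classifier$cov == "identity"
  for (m in seq_len(n)) {
    jit_sd <- classifier$regularization_sd
    Xtr_j <- Xtr + if (jit_sd > 0) {
      matrix(stats::rnorm(length(Xtr), sd = jit_sd), nrow(Xtr))
    } else 0
    xte <- Xte[m, ] + if (jit_sd > 0) stats::rnorm(d, sd = jit_sd) else 0
    train <- setdiff(seq_len(n), m)
    ytr <- y[train]
    Xt <- Xtr_j[train, , drop = FALSE]
    means <- rowsum(Xt, ytr) /
      as.numeric(table(factor(ytr, levels = seq_len(K))))
    scores <- numeric(K)
    if (pooled) {
      centred <- Xt - means[ytr, , drop = FALSE]
      S <- if (identity_cov) diag(d) else
        crossprod(centred) / (nrow(Xt) - K)
      Sinv <- tryCatch(solve(S), error = function(e)
        stop("pooled covariance is singular even after regularization"))
      for (i in seq_len(K)) {
        v <- xte - means[i, ]
        scores[i] <- -0.5 * drop(t(v) %*% Sinv %*% v)
      }
    } else {
      for (i in seq_len(K)) {
        Xi <- Xt[ytr == i, , drop = FALSE]
        Si <- stats::cov(Xi)
        ld <- determinant(Si, logarithm = TRUE)
        Sinv <- tryCatch(solve(Si), error = function(e)
          stop(sprintf("covariance for stimulus %d is singular even after regularization", i)))
        v <- xte - means[i, ]
        scores[i] <- -0.5 * as.numeric(ld$modulus) -
          0.5 * drop(t(v) %*% Sinv %*% v)
      }
    }
    out[m] <- which.max(scores)
  }
  out
}

decode_poisson_nb <- function(Xte, Xtr, y, K) {
  n <- nrow(Xte)
  sums <- rowsum(Xtr, y)
  counts <- as.numeric(table(factor(y, levels = seq_len(K))))
  out <- integer(n)
  for (m in seq_len(n)) {
    s <- sums
    cnt <- counts
    s[y[m], ] <- s[y[m], ] - Xtr[m, ]
    cnt[y[m]] <- cnt[y[m]] - 1
    ll <- vapply(seq_len(K), function(i) {
      lambda <- pmax(s[i, ] / cnt[i], 1 / (2 * cnt[i]))
      sum(stats::dpois(Xte[m, ], lambda, log = TRUE))
    }, numeric(1))
    out[m] <- which.max(ll)
  }
  out
}

decode_multinomial_nb <- function(Xte, Xtr, y, K) {
  n <- nrow(Xte)
  d <- ncol(Xte)
  max_count <- max(Xtr, Xte)
  n_levels <- max_count + 1L
  # freq[i, bin, value+1]: training histogram of counts per class and bin
  freq <- array(0L, c(K, d, n_levels))
  for (m in seq_len(n)) {
    for (b in seq_len(d)) {
      v <- Xtr[m, b] + 1L
      freq[y[m], b, v] <- freq[y[m], b, v] + 1L
    }
  }
  counts <- as.numeric(table(factor(y, levels = seq_len(K))))
  out <- integer(n)
  for (m in seq_len(n)) {
    cls <- y[m]
    ll <- vapply(seq_len(K), function(i) {
      ni <- counts[i] - (i == cls)
      tot <- ni + n_levels # add-one smoothing denominator
      s <- 0
      for (b in seq_len(d)) {
        v <- Xte[m, b] + 1L
        # remove the test trial's own codebook row from its class histogram
        f <- freq[i, b, v] - (i == cls && Xtr[m, b] == Xte[m, b])
        s <- s + log((f + 1) / tot)
      }
      s
    }, numeric(1))
    out[m] <- which.max(ll)
  }
  out
}

decode_knn <- function(Xte, Xtr, y, K, k) {
  n <- nrow(Xte)
  out <- integer(n)
  D <- outer(rowSums(Xte^2), rep(1, n)) +
    outer(rep(1, n), rowSums(Xtr^2)) - 2 * Xte %*% t(Xtr)
  for (m in seq_len(n)) {
    dd <- D[m, ]
    dd[m] <- Inf # the test trial's own codebook row is left out
    nb <- order(dd)[seq_len(min(k, n - 1L))]
    votes <- tabulate(y[nb], nbins = K)
    out[m] <- which.max(votes)
  }
  out
}

#' Naive Bayes log-likelihood of a count vector
#'
#' Sum over bins of the log probability mass of the observed count under the
#' per-bin model: independent Poisson means (`type = "poisson"`, means
#' floored at `1/(2 * n_train)`) or smoothed discrete count distributions
#' (`type = "multinomial"`, add-one smoothing over `0..max_count`).
#'
#' @param counts observed non-negative integer vector.
#' @param model for `"poisson"`: list with `means` (per-bin) and `n_train`;
#'   for `"multinomial"`: list with `freq` (bins x (max_count+1) histogram
#'   matrix of training counts) and `n_train`.
#' @param type `"poisson"` or `"multinomial"`.
#' @return log-likelihood (finite by construction).
#' @export
nb_loglik <- function(counts, model, type = c("poisson", "multinomial")) {
  type <- match.arg(type)
  if (type == "poisson") {
    lambda <- pmax(model$means, 1 / (2 * model$n_train))
    sum(stats::dpois(counts, lambda, log = TRUE))
  } else {
    freq <- model$freq
    n_levels <- ncol(freq)
    tot <- model$n_train + n_levels
    v <- counts + 1L
    if (any(v > n_levels)) stop("observed count outside the modelled range")
    sum(log((freq[cbind(seq_along(counts), v)] + 1) / tot))
  }
}

#' Decode with averaging over bin shuffles
#'
#' Runs [loo_decode()] `shuffle_repeats` times on freshly bin-shuffled
#' copies of a time-partitioned ensemble and averages the percent correct,
#' which is how the bin-shuffled spike-count code is scored.
#'
#' @param ensemble a time-partitioned `response_ensemble`.
#' @param classifier a [classifier_spec()] or name.
#' @param repeats number of shuffles (defaults to the code's
#'   `shuffle_repeats`).
#' @param seed integer seed for the shuffle stream.
#' @return a `decoding_result` whose confusion matrix is the sum over
#'   repeats and whose `percent_correct` is the average.
#' @export
shuffled_count_decode <- function(ensemble, classifier = classifier_spec(),
                                  repeats = NULL, seed = 1L) {
  classifier <- as_classifier(classifier)
  repeats <- repeats %||% ensemble$code$shuffle_repeats %||% 20L
  runs <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(repeats), function(r) {
      sh <- shuffle_ensemble(ensemble)
      cls_seed <- sample.int(.Machine$integer.max, 1)
      loo_decode(sh, classifier, seed = cls_seed)
    })
  })
  confusion <- Reduce(`+`, lapply(runs, `[[`, "confusion"))
  res <- new_decoding_result(confusion, classifier, ensemble$code)
  res$percent_correct <- mean(vapply(runs, `[[`, numeric(1), "percent_correct"))
  res$code <- "count_shuffled"
  res
}
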