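#' Named RNG sub-streams
#'
#' One master seed spawns named, mutually independent-looking sub-seeds so
#' each generator component (LFP, stimulus profile, spikes, background noise,
#' bin shuffles, epoch sampling, jitter lags, classifier jitter) is
#' reproducible on its own. The derivation is a small deterministic string
#' hash folded into the 31-bit seed range R accepts.
#'
#' @param seed integer master seed.
#' @param name character stream name.
#' @return an integer seed in [0, 2^31 - 2].
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (code in utf8ToInt(name)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

#' Evaluate an expression under a named sub-stream of a master seed
#'
#' Global RNG state is restored afterwards.
#' @keywords internal
with_substream <- function(seed, name, expr) {
  withr::with_seed(substream_seed(seed, name), expr)
}

#' Draw from a von Mises distribution
#'
#' Best & Fisher (1979) wrapped-Cauchy envelope rejection sampler. Used for
#' the per-trial phase offsets of the oscillation around the stimulus-locked
#' trajectory; `kappa = 0` is the uniform circle, `kappa = Inf` collapses to
#' the mean direction.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa non-negative concentration.
#' @return numeric vector of angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  if (is.infinite(kappa)) return(rep(mu %% (2 * pi), n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1))) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}
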