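#' @keywords internal
"_PACKAGE"

expit <- function(eta) stats::plogis(eta)

logit <- function(p) stats::qlogis(p)

# Numerically stable log(1 + exp(eta)).
log1pexp <- function(eta) {
  out <- eta
  small <- eta <= 18
  out[small] <- log1p(exp(eta[small]))
  big <- eta > 18 & eta <= 33.3
  out[big] <- eta[big] + exp(-eta[big])
  out
}

# Weighted Bernoulli log-likelihood on the linear-predictor scale.
bernoulli_loglik <- function(eta, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  sum(w * (y * eta - log1pexp(eta)))
}

# Clamp probabilities away from 0/1 so that deviance terms stay finite.
clamp_prob <- function(p, eps = 1e-15) {
  pmin(pmax(p, eps), 1 - eps)
}

#' Deterministic child seed
#'
#' Derives a reproducible 32-bit child seed from a root seed and up to two
#' indices (for example scenario and replicate number), so that any single
#' replicate of an experiment can be regenerated in isolation.
#'
#' @param root integer root seed.
#' @param i,j nonnegative integer indices.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(root, i = 0L, j = 0L) {
  m <- 2147483647
  x <- (as.numeric(root) %% m) * 48271 %% m
  x <- (x + as.numeric(i) * 99991 + as.numeric(j) * 1009 + 12345) %% m
  as.integer(x) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
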