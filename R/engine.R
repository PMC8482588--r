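# Core Newton-Raphson engines for (penalized) logistic regression.
#
# Both engines operate on a design matrix that already contains the intercept
# column.  `newton_logistic` maximizes
#     l(beta) - 0.5 * sum(penalty * beta^2)
# for a per-column penalty vector (zeros leave a column unpenalized), with
# case weights, optional warm start and step-halving.  `newton_firth`
# maximizes Firth's penalized likelihood l(beta) + 0.5 * log|I(beta)| via the
# modified score with hat-diagonal adjustment.

newton_logistic <- function(X, y, w = NULL, penalty = NULL, init = NULL,
                            max_iter = 100L, tol = 1e-8, cap = 50) {
  p <- ncol(X)
  n <- nrow(X)
  if (is.null(w)) w <- rep(1, n)
  if (is.null(penalty)) penalty <- rep(0, p)
  stopifnot(length(penalty) == p, length(w) == n, length(y) == n)
  beta <- if (is.null(init)) rep(0, p) else as.numeric(init)

  pen_obj <- function(b, eta) {
    bernoulli_loglik(eta, y, w) - 0.5 * sum(penalty * b^2)
  }

  eta <- drop(X %*% beta)
  obj <- pen_obj(beta, eta)
  converged <- FALSE
  capped <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    pi_hat <- expit(eta)
    score <- drop(crossprod(X, w * (y - pi_hat))) - penalty * beta
    W <- w * pi_hat * (1 - pi_hat)
    H <- crossprod(X, X * W)
    diag(H) <- diag(H) + penalty
    step <- tryCatch(solve(H, score), error = function(e) {
      # Near-singular curvature (flat separated likelihood): damp and retry.
      solve(H + diag(1e-10, p), score)
    })
    # step-halving on the penalized objective
    fac <- 1
    for (h in seq_len(25)) {
      beta_new <- beta + fac * step
      eta_new <- drop(X %*% beta_new)
      obj_new <- pen_obj(beta_new, eta_new)
      if (is.finite(obj_new) && obj_new >= obj - 1e-12) break
      fac <- fac / 2
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    eta <- eta_new
    obj <- obj_new
    if (max(abs(beta)) > cap) {
      # divergence under separation: freeze at capped values
      beta <- pmin(pmax(beta, -cap), cap)
      eta <- drop(X %*% beta)
      capped <- TRUE
      break
    }
    pi_hat <- expit(eta)
    score <- drop(crossprod(X, w * (y - pi_hat))) - penalty * beta
    if (max(abs(score)) < tol && delta < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  list(coefficients = beta,
       fitted = expit(eta),
       log_likelihood = bernoulli_loglik(eta, y, w),
       converged = converged && !capped,
       capped = capped,
       iterations = iter,
       max_score = max(abs(drop(crossprod(X, w * (expit(eta) - y))) +
                             penalty * beta)))
}

newton_firth <- function(X, y, w = NULL, init = NULL, max_iter = 100L,
                         tol = 1e-8) {
  p <- ncol(X)
  n <- nrow(X)
  if (is.null(w)) w <- rep(1, n)
  beta <- if (is.null(init)) rep(0, p) else as.numeric(init)

  firth_obj <- function(eta) {
    pi_hat <- expit(eta)
    W <- w * pi_hat * (1 - pi_hat)
    info <- crossprod(X, X * W)
    ld <- determinant(info, logarithm = TRUE)
    if (ld$sign <= 0) return(-Inf)
    bernoulli_loglik(eta, y, w) + 0.5 * as.numeric(ld$modulus)
  }

  eta <- drop(X %*% beta)
  obj <- firth_obj(eta)
  converged <- FALSE
  trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    pi_hat <- expit(eta)
    W <- w * pi_hat * (1 - pi_hat)
    XW <- X * sqrt(W)
    info <- crossprod(XW)
    info_inv <- solve(info)
    h <- rowSums((XW %*% info_inv) * XW)
    score <- drop(crossprod(X, w * (y - pi_hat) + h * (0.5 - pi_hat)))
    step <- drop(info_inv %*% score)
    fac <- 1
    for (k in seq_len(25)) {
      beta_new <- beta + fac * step
      eta_new <- drop(X %*% beta_new)
      obj_new <- firth_obj(eta_new)
      if (is.finite(obj_new) && obj_new >= obj - 1e-12) break
      fac <- fac / 2
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    eta <- eta_new
    obj <- obj_new
    trace <- c(trace, obj)
    if (max(abs(score)) < tol && delta < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) {
      cond <- simpleError(sprintf(
        "Firth fit did not converge in %d iterations (last max |score| = %.3g)",
        max_iter, max(abs(score))))
      attr(cond, "trace") <- trace
      stop(cond)
    }
  }
  pi_hat <- expit(eta)
  list(coefficients = beta,
       fitted = pi_hat,
       log_likelihood = bernoulli_loglik(eta, y, w),
       penalized_log_likelihood = obj,
       converged = converged,
       iterations = iter)
}
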