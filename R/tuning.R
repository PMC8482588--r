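# Tuning of the ridge complexity parameter: leave-one-out criteria (deviance,
# GCV, classification error), AIC with effective degrees of freedom, repeated
# 10-fold cross-validation, fixed penalties from prior odds-ratio intervals,
# and the two oracle benchmarks.
#
# Leave-one-out refits reuse the full-data standardization: covariates are
# standardized once per dataset, and rows with identical covariate pattern
# and outcome are collapsed into weighted fits, which leaves every criterion
# unchanged but makes LOOCV cost proportional to the number of distinct
# patterns rather than N.

collapse_patterns <- function(data) {
  key <- apply(cbind(data$x, data$y), 1, paste, collapse = "\r")
  idx <- match(key, unique(key))
  first <- match(unique(key), key)
  list(x = data$x[first, , drop = FALSE],
       y = data$y[first],
       m = as.numeric(tabulate(idx, nbins = length(first))),
       row_pattern = idx)
}

# Ridge fits over an ascending lambda grid with warm starts.
# Returns coefficient matrix ((K+1) x L), log-likelihoods and effective df.
ridge_path_engine <- function(Xint, y, w, grid, need_df = FALSE,
                              allow_cap = FALSE) {
  p <- ncol(Xint)
  L <- length(grid)
  coefs <- matrix(NA_real_, p, L)
  ll <- numeric(L)
  df <- rep(NA_real_, L)
  init <- rep(0, p)
  for (l in seq_len(L)) {
    pen <- c(0, rep(grid[l], p - 1))
    res <- newton_logistic(Xint, y, w = w, penalty = pen, init = init)
    if (!res$converged && !allow_cap) {
      stop(sprintf("ridge fit did not converge at lambda = %g", grid[l]))
    }
    coefs[, l] <- res$coefficients
    ll[l] <- res$log_likelihood
    init <- res$coefficients
    if (need_df) {
      pi_hat <- res$fitted
      W <- (w %||% rep(1, length(y))) * pi_hat * (1 - pi_hat)
      A <- crossprod(Xint, Xint * W)
      Ap <- A
      diag(Ap) <- diag(Ap) + pen
      df[l] <- tryCatch(sum(diag(solve(Ap, A))), error = function(e) {
        stop("penalized Hessian is singular at lambda = ", grid[l])
      })
    }
  }
  list(coef = coefs, log_likelihood = ll, df = df)
}

# Leave-one-out predictions over the grid for collapsed covariate-outcome
# patterns.  Returns a J x L matrix of out-of-sample probabilities.
loo_path_engine <- function(Xint, y, m, grid, decrement = TRUE) {
  J <- nrow(Xint)
  L <- length(grid)
  P <- matrix(NA_real_, J, L)
  p <- ncol(Xint)
  for (j in seq_len(J)) {
    w <- m
    w[j] <- if (decrement) m[j] - 1 else 0
    init <- rep(0, p)
    for (l in seq_len(L)) {
      pen <- c(0, rep(grid[l], p - 1))
      res <- tryCatch(
        newton_logistic(Xint, y, w = w, penalty = pen, init = init),
        error = function(e) {
          stop(sprintf("leave-one-out fit failed for pattern %d at lambda = %g: %s",
                       j, grid[l], conditionMessage(e)))
        })
      init <- res$coefficients
      P[j, l] <- expit(sum(Xint[j, ] * res$coefficients))
    }
  }
  P
}

tuning_paths <- function(data, grid, need_loo = TRUE, need_full = TRUE,
                         collapse = TRUE) {
  stopifnot(inherits(data, "lr_dataset"))
  design <- standardize(data$x)
  Xint <- cbind(1, design$matrix)
  out <- list(design = design, grid = grid, n = length(data$y))
  if (need_full) {
    out$full <- ridge_path_engine(Xint, data$y, data$w, grid, need_df = TRUE)
  }
  if (need_loo) {
    if (collapse && all(data$w == 1)) {
      cp <- collapse_patterns(data)
      Xu <- cbind(1, apply_standardization(design, cp$x))
      out$loo <- list(P = loo_path_engine(Xu, cp$y, cp$m, grid),
                      y = cp$y, m = cp$m)
    } else {
      out$loo <- list(P = loo_path_engine(Xint, data$y, data$w, grid,
                                          decrement = FALSE),
                      y = data$y, m = data$w)
    }
  }
  out
}

deviance_from_loo <- function(loo) {
  P <- clamp_prob(loo$P)
  drop(-2 * crossprod(loo$m, loo$y * log(P) + (1 - loo$y) * log(1 - P)))
}

ce_from_loo <- function(loo, cutoff, n) {
  P <- loo$P
  err <- loo$y * (P < cutoff - 1e-12) + (1 - loo$y) * (P > cutoff + 1e-12) +
    0.5 * (abs(P - cutoff) <= 1e-12)
  drop(crossprod(loo$m, err)) / n
}

#' Leave-one-out cross-validated deviance
#'
#' `D = -2 * sum(y_i log p_(-i) + (1 - y_i) log(1 - p_(-i)))` where
#' `p_(-i)` is the ridge prediction for observation i from the model fitted
#' without it (standardization fixed from the full data).
#'
#' @param data an [lr_dataset()].
#' @param lambda nonnegative penalty (scalar or vector of grid values).
#' @param collapse collapse identical covariate-outcome patterns into
#'   weighted fits (identical result, much faster on discrete covariates).
#' @return Deviance value(s), one per `lambda`.
#' @export
loocv_deviance <- function(data, lambda, collapse = TRUE) {
  paths <- tuning_paths(data, sort(lambda), need_full = FALSE,
                        collapse = collapse)
  d <- deviance_from_loo(paths$loo)
  d[match(lambda, sort(lambda))]
}

#' Effective degrees of freedom of a ridge fit
#'
#' `df_e = trace(A %*% solve(A + P))` with `A` the unpenalized Fisher
#' information at the penalized estimate and `P` the penalty matrix
#' (zero entry for the intercept).  Equals K+1 at `lambda = 0` and
#' decreases towards 1 (the unpenalized intercept) as `lambda` grows.
#'
#' @inheritParams loocv_deviance
#' @export
effective_df <- function(data, lambda) {
  paths <- tuning_paths(data, sort(lambda), need_loo = FALSE)
  paths$full$df[match(lambda, sort(lambda))]
}

#' Generalized cross-validation criterion
#'
#' `GCV = N * D / (N - df_e)^2` with `D` the leave-one-out deviance and
#' `df_e` the effective degrees of freedom at `lambda`.
#'
#' @inheritParams loocv_deviance
#' @export
gcv <- function(data, lambda, collapse = TRUE) {
  paths <- tuning_paths(data, sort(lambda), collapse = collapse)
  n <- paths$n
  df <- paths$full$df
  if (any(df >= n)) stop("effective degrees of freedom reach N")
  out <- n * deviance_from_loo(paths$loo) / (n - df)^2
  out[match(lambda, sort(lambda))]
}

#' Leave-one-out classification error
#'
#' Misclassification rate of the leave-one-out predictions at cut-off `c`,
#' with ties (prediction equal to the cut-off) counted one half.  For
#' unbalanced outcomes the cut-off defaults to the marginal event rate
#' rather than one half.
#'
#' @inheritParams loocv_deviance
#' @param cutoff classification cut-off in (0, 1); default observed event
#'   rate.
#' @export
classification_error <- function(data, lambda, cutoff = NULL,
                                 collapse = TRUE) {
  cutoff <- cutoff %||% mean(data$y)
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  paths <- tuning_paths(data, sort(lambda), need_full = FALSE,
                        collapse = collapse)
  out <- ce_from_loo(paths$loo, cutoff, paths$n)
  out[match(lambda, sort(lambda))]
}

#' AIC of a ridge fit
#'
#' `AIC = -2 * l(beta_hat) + 2 * df_e`, with the unpenalized log-likelihood
#' evaluated at the penalized estimate and the effective degrees of freedom
#' as complexity measure.
#'
#' @inheritParams loocv_deviance
#' @export
ridge_aic <- function(data, lambda) {
  paths <- tuning_paths(data, sort(lambda), need_loo = FALSE)
  out <- -2 * paths$full$log_likelihood + 2 * paths$full$df
  out[match(lambda, sort(lambda))]
}

new_tuning_result <- function(lambda_star, criterion, grid, trace = NULL,
                              theta = NULL, seed = NULL, extra = list()) {
  res <- c(list(lambda_star = lambda_star,
                criterion = criterion,
                trace = trace,
                at_boundary = grid_boundary(lambda_star, grid),
                theta = theta,
                seed = seed),
           extra)
  class(res) <- "tuning_result"
  res
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result %s>  lambda* = %g  (boundary: %s)\n",
              x$criterion, x$lambda_star, x$at_boundary))
  invisible(x)
}

#' Tune the complexity parameter over a grid
#'
#' Evaluates one tuning criterion at every grid value and returns the
#' minimizer together with the full criterion trace.  Ties are broken
#' towards the smaller lambda for D, GCV and AIC; for the classification
#' error, which is discrete and has no unique optimum, the largest lambda
#' minimizing CE is chosen.
#'
#' @param data an [lr_dataset()].
#' @param grid increasing vector of candidate lambdas, see [make_grid()].
#' @param criterion one of `"D"`, `"GCV"`, `"CE"`, `"AIC"`.
#' @param cutoff cut-off for `criterion = "CE"` (default: event rate).
#' @param collapse collapse duplicate covariate-outcome patterns in the
#'   leave-one-out computations.
#' @return A `tuning_result` with elements `lambda_star`, `criterion`,
#'   `trace` (data frame of lambda and criterion values), `at_boundary`.
#' @examples
#' d <- illustration_dataset(2)
#' tune_lambda(d, make_grid(40), "D")$at_boundary  # "upper"
#' @export
tune_lambda <- function(data, grid = make_grid(),
                        criterion = c("D", "GCV", "CE", "AIC"),
                        cutoff = NULL, collapse = TRUE) {
  criterion <- match.arg(criterion)
  ord <- order(grid)
  grid <- grid[ord]
  need_loo <- criterion %in% c("D", "GCV", "CE")
  need_full <- criterion %in% c("GCV", "AIC")
  paths <- tuning_paths(data, grid, need_loo = need_loo,
                        need_full = need_full, collapse = collapse)
  n <- paths$n
  values <- switch(criterion,
    D = deviance_from_loo(paths$loo),
    GCV = {
      if (any(paths$full$df >= n)) stop("effective degrees of freedom reach N")
      n * deviance_from_loo(paths$loo) / (n - paths$full$df)^2
    },
    CE = ce_from_loo(paths$loo, cutoff %||% mean(data$y), n),
    AIC = -2 * paths$full$log_likelihood + 2 * paths$full$df)
  idx <- if (criterion == "CE") {
    max(which(values <= min(values) + 1e-12))
  } else {
    which.min(values)
  }
  new_tuning_result(grid[idx], criterion, grid,
                    trace = data.frame(lambda = grid, value = values))
}

#' Repeated 10-fold cross-validation
#'
#' Repeats K-fold cross-validated deviance minimization several times with
#' different random fold assignments and aggregates the per-repetition
#' minimizers by a quantile `theta`, snapped back to the nearest grid value
#' on the log scale.  `theta = 0.5` and `theta = 0.95` give the RCV50 and
#' RCV95 tuning rules.  Folds are drawn without outcome stratification; a
#' repetition whose folds leave some training set with a single outcome
#' class is redrawn (counted in `n_redraws`).
#'
#' @inheritParams tune_lambda
#' @param folds number of folds.
#' @param reps number of repetitions.
#' @param theta quantile in (0, 1) applied to the per-repetition minimizers.
#' @param seed integer seed; repetition r uses the deterministic child seed
#'   `child_seed(seed, r)`.
#' @return A `tuning_result` with criterion `"RCV50"`, `"RCV95"` or
#'   `"RCV"`, the per-repetition minimizers in `rep_lambda_star`.
#' @export
repeated_cv <- function(data, grid = make_grid(), folds = 10L, reps = 50L,
                        theta = 0.5, seed = 1L) {
  stopifnot(theta > 0, theta < 1)
  ord <- order(grid)
  grid <- grid[ord]
  design <- standardize(data$x)
  Xint <- cbind(1, design$matrix)
  n <- length(data$y)
  L <- length(grid)
  lam_star <- numeric(reps)
  n_redraws <- 0L
  for (r in seq_len(reps)) {
    for (attempt in seq_len(50L)) {
      set.seed(child_seed(seed, r, attempt))
      fold <- sample(rep(seq_len(folds), length.out = n))
      ok <- all(vapply(seq_len(folds), function(f) {
        ytr <- data$y[fold != f]
        length(unique(ytr)) == 2
      }, logical(1)))
      if (ok) break
      n_redraws <- n_redraws + 1L
    }
    if (!ok) stop("could not draw folds with both outcome classes")
    dev <- numeric(L)
    for (f in seq_len(folds)) {
      w <- as.numeric(fold != f) * data$w
      hold <- fold == f
      init <- rep(0, ncol(Xint))
      for (l in seq_len(L)) {
        pen <- c(0, rep(grid[l], ncol(Xint) - 1))
        res <- newton_logistic(Xint, data$y, w = w, penalty = pen,
                               init = init)
        init <- res$coefficients
        p <- clamp_prob(expit(drop(Xint[hold, , drop = FALSE] %*%
                                     res$coefficients)))
        dev[l] <- dev[l] - 2 * sum(data$w[hold] *
          (data$y[hold] * log(p) + (1 - data$y[hold]) * log(1 - p)))
      }
    }
    lam_star[r] <- grid[which.min(dev)]
  }
  q <- stats::quantile(lam_star, probs = theta, type = 7, names = FALSE)
  snapped <- grid[which.min(abs(log10(grid) - log10(q)))]
  crit <- if (theta == 0.5) "RCV50" else if (theta == 0.95) "RCV95" else "RCV"
  new_tuning_result(snapped, crit, grid, theta = theta, seed = seed,
                    extra = list(rep_lambda_star = lam_star,
                                 n_redraws = n_redraws))
}

#' Convert a prior odds-ratio interval into a fixed ridge penalty
#'
#' Interprets ridge regression as Bayesian estimation with zero-centered
#' normal priors on the standardized coefficients.  A symmetric
#' `level`-probability prior interval `(1/or_upper, or_upper)` for the odds
#' ratio of a standardized covariate gives prior variance
#' `v_prior = (log(or_upper)/z)^2` with `z` the corresponding standard
#' normal quantile, and penalty `lambda = 1/v_prior`.  Following the
#' convention of reporting round prior variances, `v_prior` is rounded to
#' two significant digits before inversion: `or_upper = 4` gives
#' `v_prior = 1/2`, `lambda = 2` (informative prior, IP) and
#' `or_upper = 16` gives `lambda = 1/2` (weakly informative prior, WP).
#'
#' @param or_upper upper limit (> 1) of the prior odds-ratio interval.
#' @param level prior interval probability, default 0.95.
#' @return An object of class `prior_spec` with `or_upper`, `level`,
#'   `v_prior_raw`, `v_prior` and `lambda`.
#' @examples
#' prior_to_lambda(4)$lambda    # 2
#' prior_to_lambda(16)$lambda   # 0.5
#' @export
prior_to_lambda <- function(or_upper, level = 0.95) {
  if (!(or_upper > 1)) stop("or_upper must exceed 1")
  z <- stats::qnorm(1 - (1 - level) / 2)
  v_raw <- (log(or_upper) / z)^2
  v <- signif(v_raw, 2)
  structure(list(or_upper = or_upper, level = level,
                 v_prior_raw = v_raw, v_prior = v, lambda = 1 / v),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf(
    "<prior_spec>  %.0f%% OR interval (%.4g, %.4g): v_prior = %g, lambda = %g\n",
    100 * x$level, 1 / x$or_upper, x$or_upper, x$v_prior, x$lambda))
  invisible(x)
}

#' Oracle choice of the complexity parameter
#'
#' Benchmarks that use the unknown truth: the explanation oracle (OEX)
#' scans the grid for the lambda minimizing `(beta1_hat - beta1)^2` with
#' `beta1` the true first coefficient on the standardized scale; the
#' prediction oracle (OP) minimizes the summed squared difference between
#' fitted and true event probabilities.
#'
#' @inheritParams tune_lambda
#' @param truth for `mode = "explanation"`, the true standardized first
#'   coefficient; for `mode = "prediction"`, a vector of true event
#'   probabilities (defaults to `data$true_probs`).
#' @param mode `"explanation"` or `"prediction"`.
#' @return A `tuning_result` (criterion `"OEX"` or `"OP"`) with the loss
#'   trace.
#' @export
oracle_lambda <- function(data, grid = make_grid(), truth = NULL,
                          mode = c("explanation", "prediction")) {
  mode <- match.arg(mode)
  ord <- order(grid)
  grid <- grid[ord]
  paths <- tuning_paths(data, grid, need_loo = FALSE)
  Xint <- cbind(1, paths$design$matrix)
  if (mode == "explanation") {
    if (is.null(truth)) stop("explanation oracle needs the true standardized beta1")
    loss <- (paths$full$coef[2, ] - truth)^2
    crit <- "OEX"
  } else {
    truth <- truth %||% data$true_probs
    if (is.null(truth)) stop("prediction oracle needs true event probabilities")
    P <- expit(Xint %*% paths$full$coef)
    loss <- colSums((P - truth)^2)
    crit <- "OP"
  }
  new_tuning_result(grid[which.min(loss)], crit, grid,
                    trace = data.frame(lambda = grid, value = loss))
}
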