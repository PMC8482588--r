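new_fit <- function(method, intercept, coefficients, scale, log_likelihood,
                    converged, iterations, lambda = NA_real_,
                    center = NULL, scale_sd = NULL, s = NULL) {
  fit <- list(method = method,
              intercept = unname(intercept),
              coefficients = coefficients,
              scale = scale,
              lambda = lambda,
              log_likelihood = log_likelihood,
              converged = converged,
              iterations = iterations)
  if (identical(scale, "standardized")) {
    stopifnot(!is.null(center), !is.null(scale_sd))
    fit$center <- center
    fit$scale_sd <- scale_sd
    fit$coefficients_original <- coefficients / scale_sd
    fit$intercept_original <-
      unname(intercept) - sum(coefficients * center / scale_sd)
  } else {
    fit$coefficients_original <- coefficients
    fit$intercept_original <- unname(intercept)
  }
  if (!is.null(s)) fit$s <- s
  class(fit) <- "ridgetune_fit"
  fit
}

#' @export
print.ridgetune_fit <- function(x, ...) {
  cat(sprintf("<%s fit>%s  converged: %s (%d iterations)\n", x$method,
              if (!is.na(x$lambda)) sprintf("  lambda = %g", x$lambda) else "",
              x$converged, x$iterations))
  cat(sprintf("  scale: %s, log-likelihood: %.4f\n", x$scale,
              x$log_likelihood))
  print(c(`(Intercept)` = x$intercept, x$coefficients))
  invisible(x)
}

#' Extract coefficients from a fit
#'
#' @param object a `ridgetune_fit`.
#' @param scale `"fitted"` for the scale the model was estimated on,
#'   `"original"` for the back-transformed original covariate scale.
#' @param ... unused.
#' @export
coef.ridgetune_fit <- function(object, scale = c("fitted", "original"), ...) {
  scale <- match.arg(scale)
  if (scale == "original") {
    c(`(Intercept)` = object$intercept_original, object$coefficients_original)
  } else {
    c(`(Intercept)` = object$intercept, object$coefficients)
  }
}

#' Maximum likelihood logistic regression
#'
#' Newton-Raphson maximization of the binomial log-likelihood with
#' step-halving.  Under separation the likelihood has no finite maximizer;
#' the estimate is then returned with coefficients capped at `cap` in
#' absolute value and `converged = FALSE` rather than raising an error.
#'
#' @param data an [lr_dataset()].
#' @param cap absolute bound on coefficients under divergence.
#' @param max_iter,tol Newton control (convergence when both the maximal
#'   absolute score and coefficient change fall below `tol`).
#' @return A `ridgetune_fit` on the original covariate scale.
#' @examples
#' d <- illustration_dataset(2)
#' coef(fit_ml(d))  # slope = log((9*19)/(1*71))
#' @export
fit_ml <- function(data, cap = 50, max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(data, "lr_dataset"))
  rate <- stats::weighted.mean(data$y, data$w)
  if (ncol(data$x) == 0 && (rate <= 0 || rate >= 1)) {
    stop("intercept-only model undefined for event rate 0 or 1")
  }
  X <- cbind(`(Intercept)` = 1, data$x)
  res <- newton_logistic(X, data$y, w = data$w, max_iter = max_iter,
                         tol = tol, cap = cap)
  cf <- res$coefficients[-1]
  names(cf) <- colnames(data$x)
  new_fit("ML", res$coefficients[1], cf, "original", res$log_likelihood,
          res$converged, res$iterations)
}

#' Firth's bias-corrected logistic regression
#'
#' Maximizes the likelihood penalized by Jeffreys' invariant prior,
#' `l(beta) + 0.5 * log|I(beta)|`, via Newton iterations on the modified
#' score (hat-diagonal adjustment).  The estimate exists and is finite even
#' under separation; the intercept is part of the penalty, so the average
#' predicted probability is pulled towards one half — see [flic_adjust()]
#' for the intercept-corrected variant used for prediction.
#'
#' @inheritParams fit_ml
#' @return A `ridgetune_fit` (method `"Firth"`) on the original scale.
#' @examples
#' coef(fit_firth(illustration_dataset(1)))  # finite despite separation
#' @export
fit_firth <- function(data, max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(data, "lr_dataset"))
  X <- cbind(`(Intercept)` = 1, data$x)
  res <- newton_firth(X, data$y, w = data$w, max_iter = max_iter, tol = tol)
  cf <- res$coefficients[-1]
  names(cf) <- colnames(data$x)
  new_fit("Firth", res$coefficients[1], cf, "original", res$log_likelihood,
          res$converged, res$iterations)
}

#' Firth's logistic regression with intercept correction (FLIC)
#'
#' Keeps the Firth slopes fixed and re-estimates the intercept by
#' one-dimensional maximum likelihood with the Firth linear predictor as an
#' offset.  The intercept score equation forces the mean predicted
#' probability to equal the observed event rate exactly, correcting the
#' towards-one-half bias that the Jeffreys penalty puts on predictions.
#'
#' @param firth_fit a fit produced by [fit_firth()] on `data`.
#' @inheritParams fit_ml
#' @return A `ridgetune_fit` with method `"FLIC"`.
#' @examples
#' d <- illustration_dataset(1)
#' f <- flic_adjust(fit_firth(d), d)
#' mean(predict_probs(f, d$x)) - mean(d$y)  # 0
#' @export
flic_adjust <- function(firth_fit, data, max_iter = 100L, tol = 1e-10) {
  stopifnot(inherits(firth_fit, "ridgetune_fit"),
            firth_fit$method == "Firth",
            inherits(data, "lr_dataset"))
  rate <- stats::weighted.mean(data$y, data$w)
  if (rate <= 0 || rate >= 1) {
    stop("intercept correction undefined for event rate 0 or 1")
  }
  offset <- drop(data$x %*% firth_fit$coefficients)
  b0 <- firth_fit$intercept
  for (iter in seq_len(max_iter)) {
    p <- expit(b0 + offset)
    score <- sum(data$w * (data$y - p))
    info <- sum(data$w * p * (1 - p))
    step <- score / info
    b0 <- b0 + step
    if (abs(score) < tol && abs(step) < tol) break
  }
  ll <- bernoulli_loglik(b0 + offset, data$y, data$w)
  new_fit("FLIC", b0, firth_fit$coefficients, "original", ll,
          TRUE, iter)
}

#' Ridge logistic regression by direct penalized optimization
#'
#' Exact maximizer of the strictly concave penalized log-likelihood
#' `l(beta) - (lambda/2) * sum(beta_k^2)`; the intercept is excluded from
#' the penalty, so the mean predicted probability equals the observed event
#' rate.  Covariates must be standardized (see [standardize()]); the fit
#' stores both the standardized-scale coefficients and the back-transformed
#' original-scale view.
#'
#' @param design a `std_design` from [standardize()].
#' @param outcome 0/1 outcome vector.
#' @param lambda nonnegative complexity parameter.
#' @param weights optional nonnegative case weights.
#' @param init optional warm start, `c(intercept, slopes)` on the
#'   standardized scale.
#' @inheritParams fit_ml
#' @return A `ridgetune_fit` with method `"ridge_direct"` and scale tag
#'   `"standardized"`.
#' @examples
#' d <- illustration_dataset(2)
#' f <- fit_ridge_direct(standardize(d$x), d$y, lambda = 2)
#' coef(f, "original")
#' @export
fit_ridge_direct <- function(design, outcome, lambda, weights = NULL,
                             init = NULL, max_iter = 100L, tol = 1e-8,
                             cap = 50) {
  stopifnot(inherits(design, "std_design"))
  if (length(lambda) != 1 || is.na(lambda) || lambda < 0) {
    stop("lambda must be a single nonnegative number")
  }
  K <- ncol(design$matrix)
  X <- cbind(`(Intercept)` = 1, design$matrix)
  res <- newton_logistic(X, outcome, w = weights,
                         penalty = c(0, rep(lambda, K)), init = init,
                         max_iter = max_iter, tol = tol, cap = cap)
  if (!res$converged && lambda > 0) {
    stop(sprintf("ridge fit did not converge at lambda = %g (max |score| %.3g)",
                 lambda, res$max_score))
  }
  cf <- res$coefficients[-1]
  names(cf) <- colnames(design$matrix)
  new_fit("ridge_direct", res$coefficients[1], cf, "standardized",
          res$log_likelihood, res$converged, res$iterations, lambda = lambda,
          center = design$center, scale_sd = design$scale)
}

#' Ridge logistic regression by data augmentation
#'
#' Approximates the ridge penalty by weighted maximum likelihood on an
#' augmented dataset: for each covariate two artificial records are added,
#' with value `1/s` in that covariate, zero in all others, no intercept
#' contribution, one with outcome 1 and one with outcome 0, each carrying
#' weight `2 * s^2 * lambda`.  For `s = 10` (default) the augmented-data
#' estimate agrees with [fit_ridge_direct()] to about two decimals, and the
#' agreement tightens as `s` grows.
#'
#' @inheritParams fit_ridge_direct
#' @param s positive rescaling factor of the pseudo-records.
#' @return A `ridgetune_fit` with method `"ridge_aug"`.
#' @export
fit_ridge_augmented <- function(design, outcome, lambda, s = 10,
                                weights = NULL, max_iter = 100L, tol = 1e-8,
                                cap = 50) {
  stopifnot(inherits(design, "std_design"))
  if (length(lambda) != 1 || is.na(lambda) || lambda < 0) {
    stop("lambda must be a single nonnegative number")
  }
  if (s <= 0) stop("s must be positive")
  K <- ncol(design$matrix)
  n <- nrow(design$matrix)
  if (is.null(weights)) weights <- rep(1, n)
  aug <- augmentation_scheme(K, lambda, s)
  X <- rbind(cbind(1, design$matrix), aug$design)
  colnames(X) <- c("(Intercept)", colnames(design$matrix))
  y <- c(outcome, aug$outcome)
  w <- c(weights, aug$weight)
  res <- newton_logistic(X, y, w = w, max_iter = max_iter, tol = tol,
                         cap = cap)
  if (!res$converged && lambda > 0) {
    stop(sprintf(
      "augmented ridge fit did not converge at lambda = %g (max |score| %.3g)",
      lambda, res$max_score))
  }
  cf <- res$coefficients[-1]
  names(cf) <- colnames(design$matrix)
  fit <- new_fit("ridge_aug", res$coefficients[1], cf, "standardized",
                 bernoulli_loglik(drop(cbind(1, design$matrix) %*%
                                         res$coefficients), outcome, weights),
                 res$converged, res$iterations, lambda = lambda,
                 center = design$center, scale_sd = design$scale, s = s)
  fit
}

#' Pseudo-record scheme for the augmentation prior
#'
#' Builds the 2K artificial records implementing a zero-centered normal
#' prior of precision `lambda` on each (standardized) coefficient: covariate
#' value `1/s` in one column, zero elsewhere, no intercept contribution, one
#' event and one non-event per covariate, each with weight `2 * s^2 * lambda`.
#'
#' @param k number of covariates.
#' @param lambda nonnegative penalty.
#' @param s positive rescaling factor.
#' @return List with `design` (2K x (K+1) matrix including the zeroed
#'   intercept column), `outcome` and `weight`.
#' @export
augmentation_scheme <- function(k, lambda, s = 10) {
  pseudo <- matrix(0, 2 * k, k + 1)
  for (j in seq_len(k)) {
    pseudo[2 * j - 1, j + 1] <- 1 / s
    pseudo[2 * j, j + 1] <- 1 / s
  }
  list(design = pseudo,
       outcome = rep(c(1, 0), k),
       weight = rep(2 * s^2 * lambda, 2 * k))
}

#' Predicted event probabilities
#'
#' Applies a fit to raw covariates.  Standardized-scale fits standardize the
#' input with the means and sds stored at fitting time, so raw covariates
#' can be supplied for every method.
#'
#' @param fit a `ridgetune_fit`.
#' @param covariates numeric matrix on the original (raw) scale.
#' @return Vector of probabilities strictly inside (0, 1).
#' @export
predict_probs <- function(fit, covariates) {
  stopifnot(inherits(fit, "ridgetune_fit"))
  x <- as.matrix(covariates)
  if (ncol(x) != length(fit$coefficients)) {
    stop("covariate dimension does not match the fit")
  }
  eta <- if (identical(fit$scale, "standardized")) {
    xs <- sweep(sweep(x, 2, fit$center), 2, fit$scale_sd, "/")
    fit$intercept + drop(xs %*% fit$coefficients)
  } else {
    fit$intercept + drop(x %*% fit$coefficients)
  }
  clamp_prob(expit(eta))
}

# Linear predictor on raw covariates (used for calibration slopes).
linear_predictor <- function(fit, covariates) {
  x <- as.matrix(covariates)
  if (ncol(x) != length(fit$coefficients)) {
    stop("covariate dimension does not match the fit")
  }
  fit$intercept_original + drop(x %*% fit$coefficients_original)
}

#' Serialize a fit to JSON
#'
#' @param fit a `ridgetune_fit`.
#' @param path optional file; when omitted the JSON string is returned.
#' @export
write_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "ridgetune_fit"))
  obj <- list(method = fit$method,
              scale = fit$scale,
              lambda = if (is.na(fit$lambda)) NULL else fit$lambda,
              intercept = fit$intercept,
              coefficients = as.list(fit$coefficients),
              intercept_original = fit$intercept_original,
              coefficients_original = as.list(fit$coefficients_original),
              log_likelihood = fit$log_likelihood,
              converged = fit$converged,
              iterations = fit$iterations)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
  }
}
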