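# Performance measures for the simulation study: RMSE of coefficients and
# predictions, calibration slope on a large validation set, RMSD/MAD of log
# calibration slopes, concordance index and the slope-lambda rank
# correlation.

#' RMSE of a coefficient over replicates
#'
#' @param estimates vector of per-replicate estimates.
#' @param true_value the true coefficient.
#' @return `sqrt(mean((estimates - true_value)^2))`.
#' @export
rmse_coefficient <- function(estimates, true_value) {
  if (!length(estimates)) stop("no estimates supplied")
  sqrt(mean((estimates - true_value)^2))
}

#' Pooled RMSE of predicted probabilities
#'
#' Square root of the mean squared difference between predicted and true
#' event probabilities, pooled over replicates and observations.
#'
#' @param predicted,true matrices (observations x replicates), vectors, or
#'   lists of per-replicate vectors of matching lengths.
#' @export
rmse_predictions <- function(predicted, true) {
  if (is.list(predicted)) predicted <- unlist(predicted)
  if (is.list(true)) true <- unlist(true)
  predicted <- as.numeric(predicted)
  true <- as.numeric(true)
  if (length(predicted) != length(true)) {
    stop("predicted and true probabilities differ in length")
  }
  sqrt(mean((predicted - true)^2))
}

#' Calibration slope on a validation set
#'
#' The coefficient from an unpenalized maximum likelihood logistic
#' regression of validation outcomes on the model's linear predictor
#' (intercept free).  A slope of 1 is ideal; below 1 indicates overfitting
#' of the development model, above 1 underfitting.  A degenerate linear
#' predictor (zero variance) yields slope 0 with attribute
#' `degenerate = TRUE` rather than an error.
#'
#' @param fit a `ridgetune_fit`.
#' @param validation an [lr_dataset()] of new observations from the same
#'   population.
#' @export
calibration_slope <- function(fit, validation) {
  stopifnot(inherits(validation, "lr_dataset"))
  lp <- linear_predictor(fit, validation$x)
  if (stats::sd(lp) < 1e-8) {
    return(structure(0, degenerate = TRUE))
  }
  g <- stats::glm(validation$y ~ lp, family = stats::binomial())
  sl <- unname(stats::coef(g)[2])
  if (is.na(sl)) {
    return(structure(0, degenerate = TRUE))
  }
  if (!g$converged) {
    stop("calibration regression did not converge (slope ", format(sl), ")")
  }
  sl
}

#' RMSD of log calibration slopes
#'
#' Root mean squared distance of the log slopes from the ideal
#' `log(1) = 0`, combining bias and variability of calibration.  Slopes are
#' winsorized at `floor` (default 0.01) before taking logs, so rare
#' nonpositive slopes do not produce infinities.
#'
#' @param slopes vector of calibration slopes.
#' @param floor winsorization floor.
#' @export
rmsd_log_slopes <- function(slopes, floor = 0.01) {
  if (!length(slopes)) stop("no slopes supplied")
  sqrt(mean(log(pmax(slopes, floor))^2))
}

#' MAD of log calibration slopes
#'
#' Median absolute deviation (about the median) of the log slopes, a robust
#' measure of calibration-slope variability.  Uses the conventional normal
#' consistency factor 1.4826 by default; pass `constant = 1` for the raw
#' MAD.  Rare nonpositive slopes are floored at `floor` before the log, as
#' in [rmsd_log_slopes()] (the log is undefined otherwise; being far in the
#' tail they barely move a median-based measure).
#'
#' @inheritParams rmsd_log_slopes
#' @param constant scale factor passed to [stats::mad()].
#' @export
mad_log_slopes <- function(slopes, constant = 1.4826, floor = 0.01) {
  if (!length(slopes)) stop("no slopes supplied")
  stats::mad(log(pmax(slopes, floor)), constant = constant)
}

#' Concordance index (c-statistic)
#'
#' Probability that a randomly chosen event observation receives a higher
#' prediction than a randomly chosen non-event observation, ties counted
#' one half.  Computed by the rank method (O(n log n)), which is exactly
#' the all-pairs count.
#'
#' @param fit a `ridgetune_fit`, or a numeric vector of predictions.
#' @param validation an [lr_dataset()], or a 0/1 outcome vector when `fit`
#'   is a prediction vector.
#' @export
c_index <- function(fit, validation) {
  if (inherits(fit, "ridgetune_fit")) {
    stopifnot(inherits(validation, "lr_dataset"))
    pred <- linear_predictor(fit, validation$x)
    y <- validation$y
  } else {
    pred <- as.numeric(fit)
    y <- if (inherits(validation, "lr_dataset")) validation$y
         else as.numeric(validation)
  }
  stopifnot(length(pred) == length(y))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("c-index undefined: only one outcome class")
  r <- rank(pred, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Spearman correlation between slopes and tuned lambdas
#'
#' Rank correlation (average ranks for ties) between per-replicate
#' calibration slopes and the tuned complexity parameters, quantifying how
#' strongly under-shrinkage translates into overfitting.
#'
#' @param slopes,lambda_stars equal-length vectors (length >= 3).
#' @return Correlation in `[-1, 1]`; `NA` with a warning when either vector
#'   is constant.
#' @export
spearman_slope_lambda <- function(slopes, lambda_stars) {
  if (length(slopes) != length(lambda_stars) || length(slopes) < 3) {
    stop("need equal-length vectors of at least 3 values")
  }
  if (stats::sd(slopes) < 1e-15 || stats::sd(lambda_stars) < 1e-15) {
    warning("rank correlation undefined for a constant vector")
    return(NA_real_)
  }
  stats::cor(slopes, lambda_stars, method = "spearman")
}
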