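#' Binary-outcome dataset
#'
#' Container for a logistic-regression dataset: a numeric covariate matrix
#' (without intercept column), a 0/1 outcome vector, optional nonnegative
#' case weights and optional true event probabilities (known for simulated
#' data, used by the prediction oracle and the evaluation measures).
#'
#' @param covariates numeric matrix (N x K) or data frame of covariates.
#' @param outcome binary vector of length N with values 0/1.
#' @param case_weights optional nonnegative weights, default all 1.
#' @param true_probs optional vector of true event probabilities in (0, 1).
#' @return An object of class `lr_dataset`: a list with elements `x`, `y`,
#'   `w` and (possibly `NULL`) `true_probs`.
#' @examples
#' d <- lr_dataset(matrix(rnorm(20), 10, 2), rbinom(10, 1, 0.5))
#' @export
lr_dataset <- function(covariates, outcome, case_weights = NULL,
                       true_probs = NULL) {
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  y <- as.numeric(outcome)
  n <- length(y)
  if (n < 2) stop("a dataset needs at least 2 observations")
  if (nrow(x) != n) stop("covariates and outcome differ in length")
  if (anyNA(x)) stop("covariates contain missing values")
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("outcome must be coded 0/1")
  if (is.null(case_weights)) case_weights <- rep(1, n)
  if (length(case_weights) != n || any(case_weights < 0)) {
    stop("case_weights must be nonnegative and of length N")
  }
  if (!is.null(true_probs)) {
    true_probs <- as.numeric(true_probs)
    if (length(true_probs) != n) stop("true_probs must have length N")
    if (any(true_probs <= 0 | true_probs >= 1)) {
      stop("true_probs must lie strictly in (0, 1)")
    }
  }
  if (ncol(x) > 0 && is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  structure(list(x = x, y = y, w = as.numeric(case_weights),
                 true_probs = true_probs),
            class = "lr_dataset")
}

#' @export
print.lr_dataset <- function(x, ...) {
  cat(sprintf("<lr_dataset>  N = %d, K = %d, events = %d (rate %.3f)%s\n",
              nrow(x$x), ncol(x$x), sum(x$y), mean(x$y),
              if (!is.null(x$true_probs)) ", true probabilities attached"
              else ""))
  invisible(x)
}

#' Read / write a dataset as delimited text
#'
#' The on-disk format is a plain CSV with a header: one column named `y`
#' holding the 0/1 outcome, an optional column `true_prob`, and all other
#' columns treated as covariates.
#'
#' @param path file path.
#' @return `read_dataset` returns an [lr_dataset()].
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"y" %in% names(df)) stop("no outcome column named 'y' in ", path)
  tp <- if ("true_prob" %in% names(df)) df[["true_prob"]] else NULL
  covars <- df[, setdiff(names(df), c("y", "true_prob")), drop = FALSE]
  lr_dataset(as.matrix(covars), df[["y"]], true_probs = tp)
}

#' @param data an [lr_dataset()].
#' @rdname read_dataset
#' @export
write_dataset <- function(data, path) {
  df <- as.data.frame(data$x)
  df$y <- data$y
  if (!is.null(data$true_probs)) df$true_prob <- data$true_probs
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
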