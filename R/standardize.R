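#' Standardize a covariate matrix
#'
#' Centers every column to mean zero and scales to unit sample standard
#' deviation (denominator N - 1).  Ridge regression is not invariant to the
#' scaling of the design matrix, so covariates are standardized before
#' penalization; the stored means and sds allow back-transformation of
#' coefficients and prediction from raw covariates.
#'
#' @param covariates numeric matrix (no intercept column).
#' @return An object of class `std_design`: list with `matrix` (standardized
#'   N x K matrix), `center` (column means) and `scale` (column sds).
#' @examples
#' sd1 <- standardize(cbind(a = rnorm(10), b = runif(10)))
#' colMeans(sd1$matrix)  # ~0
#' @export
standardize <- function(covariates) {
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  bad <- which(sds < 1e-12 | !is.finite(sds))
  if (length(bad)) {
    nm <- colnames(x)[bad] %||% as.character(bad)
    stop("constant column(s) cannot be standardized: ",
         paste(nm, collapse = ", "))
  }
  structure(list(matrix = sweep(sweep(x, 2, ctr), 2, sds, "/"),
                 center = ctr, scale = sds),
            class = "std_design")
}

# Apply a stored standardization to new raw covariates.
apply_standardization <- function(design, covariates) {
  x <- as.matrix(covariates)
  if (ncol(x) != length(design$center)) {
    stop("covariate dimension does not match the standardized design")
  }
  sweep(sweep(x, 2, design$center), 2, design$scale, "/")
}
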