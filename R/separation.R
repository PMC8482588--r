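#' Detect (quasi-)separation
#'
#' Decides by a linear-programming feasibility check whether a separating
#' hyperplane exists, i.e. whether some coefficient vector `b` (including an
#' intercept) satisfies `(2 y_i - 1) * x_i' b >= 0` for every observation
#' with strict inequality for at least one — the condition under which
#' maximum likelihood estimates are infinite.  The LP maximizes the sum of
#' signed margins subject to nonnegative margins and a unit box on `b`; the
#' data are separated (completely or quasi-completely) if and only if the
#' optimum is positive.
#'
#' @param data an [lr_dataset()].
#' @param tol positivity tolerance for the LP optimum.
#' @return `TRUE` if a separating hyperplane exists.
#' @examples
#' detect_separation(illustration_dataset(1))  # TRUE
#' detect_separation(illustration_dataset(2))  # FALSE
#' @export
detect_separation <- function(data, tol = 1e-7) {
  stopifnot(inherits(data, "lr_dataset"))
  Xt <- cbind(1, data$x)
  M <- unique(Xt * (2 * data$y - 1))   # signed design, margins are M %*% b
  p <- ncol(M)
  # variables: b = u - v with 0 <= u, v <= 1; all constraints written as <=
  # so the all-slack basis at b = 0 is feasible and phase 1 is skipped
  a <- c(colSums(M), -colSums(M))
  A1 <- rbind(diag(2 * p), cbind(-M, M))
  b1 <- c(rep(1, 2 * p), rep(0, nrow(M)))
  res <- boot::simplex(a = a, A1 = A1, b1 = b1, maxi = TRUE,
                       n.iter = 500 + 4 * (nrow(M) + 2 * p))
  isTRUE(res$value > tol)
}
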