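#' Log-linear grid of complexity parameters
#'
#' The candidate set over which the ridge complexity parameter is tuned:
#' `n` log-linearly equidistant values, by default 200 values from 1e-6 to
#' 100 (the consecutive ratio is constant).
#'
#' @param n number of grid points (>= 2).
#' @param lo,hi positive grid limits, `lo < hi`.
#' @return Increasing numeric vector of length `n`.
#' @examples
#' g <- make_grid()
#' c(g[1], g[200])  # 1e-6, 100
#' @export
make_grid <- function(n = 200L, lo = 1e-6, hi = 100) {
  if (n < 2) stop("n must be at least 2")
  if (!(lo > 0 && hi > lo)) stop("grid limits must satisfy 0 < lo < hi")
  10^seq(log10(lo), log10(hi), length.out = n)
}

grid_boundary <- function(lambda_star, grid) {
  if (lambda_star == grid[1]) "lower"
  else if (lambda_star == grid[length(grid)]) "upper"
  else "none"
}
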