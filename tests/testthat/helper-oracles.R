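# Independent brute-force oracles used across the test files.

# All-pairs concordance count: probability that an event observation
# outranks a non-event observation, ties counted one half.
brute_c_index <- function(pred, y) {
  i1 <- which(y == 1)
  i0 <- which(y == 0)
  s <- 0
  for (a in i1) for (b in i0) {
    s <- s + if (pred[a] > pred[b]) 1 else if (pred[a] == pred[b]) 0.5 else 0
  }
  s / (length(i1) * length(i0))
}

# Exhaustive 2-covariate separation oracle.  A separating direction of the
# cone {d : d'(x_i - x_j) >= 0 for all event/non-event pairs} can be taken
# along a boundary ray, which is orthogonal to one of the pair differences;
# checking all pair differences and their rotations is therefore exhaustive
# in two dimensions.  Works exactly on small-integer covariates.
brute_separation <- function(x, y, tol = 1e-9) {
  i1 <- which(y == 1)
  i0 <- which(y == 0)
  if (!length(i1) || !length(i0)) return(TRUE)   # one-class data
  diffs <- do.call(rbind, lapply(i1, function(a) {
    t(vapply(i0, function(b) x[a, ] - x[b, ], numeric(2)))
  }))
  cands <- rbind(diffs, -diffs,
                 cbind(-diffs[, 2], diffs[, 1]),
                 cbind(diffs[, 2], -diffs[, 1]))
  cands <- cands[rowSums(abs(cands)) > tol, , drop = FALSE]
  for (r in seq_len(nrow(cands))) {
    pr <- drop(diffs %*% cands[r, ])
    if (all(pr >= -tol) && any(pr > tol)) return(TRUE)
  }
  FALSE
}

# Small random non-degenerate dataset for property checks.
random_dataset <- function(n = 80, k = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    x <- matrix(rnorm(n * k), n, k)
    y <- rbinom(n, 1, plogis(0.3 * x[, 1] - 0.2))
    if (sum(y) >= 3 && sum(1 - y) >= 3) return(lr_dataset(x, y))
  }
}

# Central-difference Hessian of a scalar function.
num_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    e_i <- e_j <- rep(0, p)
    e_i[i] <- h
    e_j[j] <- h
    H[i, j] <- (f(x + e_i + e_j) - f(x + e_i - e_j) -
                  f(x - e_i + e_j) + f(x - e_i - e_j)) / (4 * h^2)
  }
  (H + t(H)) / 2
}
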