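d1 <- illustration_dataset(1)
d2 <- illustration_dataset(2)

test_that("the lambda grid is log-linearly equidistant", {
  g <- make_grid()
  expect_length(g, 200)
  expect_equal(g[1], 1e-6)
  expect_equal(g[200], 100)
  expect_equal(g[2], 10^(-6 + 8 / 199), tolerance = 1e-12)
  ratios <- g[-1] / g[-length(g)]
  expect_lt(diff(range(ratios)), 1e-12)
  expect_equal(make_grid(2, 0.1, 10), c(0.1, 10))
  expect_error(make_grid(1), "at least 2")
  expect_error(make_grid(10, 1, 0.5), "lo < hi")
})

test_that("LOOCV deviance is unchanged by covariate-pattern collapsing", {
  for (d in list(d2, d1)) {
    for (lam in c(0.01, 1, 50)) {
      expect_equal(loocv_deviance(d, lam, collapse = TRUE),
                   loocv_deviance(d, lam, collapse = FALSE),
                   tolerance = 1e-8)
    }
  }
})

test_that("deviance tuning hits the documented grid boundaries", {
  g <- make_grid(80)
  t1 <- tune_lambda(d1, g, "D")
  expect_identical(t1$at_boundary, "lower")
  expect_equal(t1$lambda_star, 1e-6)
  t2 <- tune_lambda(d2, g, "D")
  expect_identical(t2$at_boundary, "upper")
  expect_equal(t2$lambda_star, 100)
  expect_true(all(is.finite(t1$trace$value)))
  expect_true(all(is.finite(t2$trace$value)))
})

test_that("tuning is invariant to grid ordering", {
  g <- make_grid(30)
  set.seed(8)
  gs <- sample(g)
  for (cr in c("D", "CE", "AIC")) {
    expect_equal(tune_lambda(d2, gs, cr)$lambda_star,
                 tune_lambda(d2, g, cr)$lambda_star)
  }
})

test_that("effective degrees of freedom span [1, K+1]", {
  set.seed(21)
  d <- random_dataset(60, 3)
  expect_equal(effective_df(d, 0), 4, tolerance = 1e-8)
  expect_equal(effective_df(d, 1e8), 1, tolerance = 1e-4)
  df_path <- effective_df(d, c(0.01, 1, 10))
  expect_true(all(diff(df_path) < 0))
})

test_that("effective df matches a finite-difference Hessian computation", {
  set.seed(31)
  d <- random_dataset(40, 1)
  lam <- 1
  fit <- fit_ridge_direct(standardize(d$x), d$y, lam)
  Xint <- cbind(1, standardize(d$x)$matrix)
  beta_hat <- c(fit$intercept, unname(fit$coefficients))
  ll <- function(b) sum(d$y * (Xint %*% b) - log1p(exp(Xint %*% b)))
  pll <- function(b) ll(b) - lam / 2 * b[2]^2
  H1 <- num_hessian(ll, beta_hat)
  H2 <- num_hessian(pll, beta_hat)
  expect_equal(effective_df(d, lam), sum(diag(H1 %*% solve(H2))),
               tolerance = 1e-4)
})

test_that("GCV and AIC recompose from their ingredients", {
  lam <- c(0.05, 2)
  n <- 100
  D <- loocv_deviance(d2, lam)
  dfe <- effective_df(d2, lam)
  expect_equal(gcv(d2, lam), n * D / (n - dfe)^2, tolerance = 1e-10)

  s2 <- standardize(d2$x)
  ll <- vapply(lam, function(l) fit_ridge_direct(s2, d2$y, l)$log_likelihood,
               numeric(1))
  expect_equal(ridge_aic(d2, lam), -2 * ll + 2 * dfe, tolerance = 1e-8)
  # AIC differences are -2*dLL + 2*d(df)
  a <- ridge_aic(d2, lam)
  expect_equal(a[2] - a[1], -2 * (ll[2] - ll[1]) + 2 * (dfe[2] - dfe[1]),
               tolerance = 1e-8)
  # at lambda = 0 AIC is the standard K+1-parameter AIC
  expect_equal(ridge_aic(d2, 0),
               -2 * fit_ml(d2)$log_likelihood + 2 * 2, tolerance = 1e-6)
})

test_that("classification error matches the pattern-enumeration oracle", {
  lam <- 0.5
  cutoff <- mean(d2$y)
  # brute force: refit without each distinct (x, y) pattern occurrence
  pats <- unique(cbind(d2$x, d2$y))
  s <- standardize(d2$x)
  err <- 0
  for (p in seq_len(nrow(pats))) {
    sel <- which(d2$x[, 1] == pats[p, 1] & d2$y == pats[p, 2])
    i <- sel[1]
    dminus <- lr_dataset(d2$x[-i, , drop = FALSE], d2$y[-i])
    # keep the full-data standardization
    sd_i <- list(matrix = apply_standardization(s, dminus$x),
                 center = s$center, scale = s$scale)
    class(sd_i) <- "std_design"
    fit <- fit_ridge_direct(sd_i, dminus$y, lam)
    pr <- predict_probs(fit, d2$x[i, , drop = FALSE])
    err <- err + length(sel) *
      (pats[p, 2] * (pr < cutoff) + (1 - pats[p, 2]) * (pr > cutoff) +
         0.5 * (pr == cutoff))
  }
  expect_equal(classification_error(d2, lam), unname(err) / 100,
               tolerance = 1e-6)
  expect_error(classification_error(d2, lam, cutoff = 1), "cutoff")
})

test_that("CE ties break towards the largest lambda", {
  tr <- tune_lambda(d2, make_grid(40), "CE")
  vals <- tr$trace$value
  expect_equal(tr$lambda_star,
               max(tr$trace$lambda[vals <= min(vals) + 1e-12]))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("repeated CV is deterministic and respects its contract", {
  g <- make_grid(25)
  r1 <- repeated_cv(d2, g, reps = 5, theta = 0.5, seed = 42)
  r2 <- repeated_cv(d2, g, reps = 5, theta = 0.5, seed = 42)
  expect_identical(r1$lambda_star, r2$lambda_star)
  expect_identical(r1$rep_lambda_star, r2$rep_lambda_star)
  expect_true(r1$lambda_star %in% g)

  # a single repetition returns that repetition's minimizer
  r3 <- repeated_cv(d2, g, reps = 1, theta = 0.9, seed = 7)
  expect_equal(r3$lambda_star, r3$rep_lambda_star)

  # identical per-repetition choices are returned for any theta
  expect_equal(repeated_cv(d2, g, reps = 4, theta = 0.95, seed = 42,
                           folds = 5)$criterion, "RCV95")
  expect_error(repeated_cv(d2, g, reps = 2, theta = 1.2), "theta")
})

test_that("prior odds-ratio intervals convert to the printed penalties", {
  ip <- prior_to_lambda(4)
  expect_equal(ip$v_prior_raw, (log(4) / qnorm(0.975))^2, tolerance = 1e-12)
  expect_equal(ip$v_prior, 0.5)
  expect_equal(ip$lambda, 2)
  wp <- prior_to_lambda(16)
  expect_equal(wp$lambda, 0.5)
  # z cancellation: or_upper = exp(z) gives v_prior exactly 1
  expect_equal(prior_to_lambda(exp(qnorm(0.975)))$lambda, 1)
  expect_error(prior_to_lambda(0.8), "exceed 1")
})

test_that("oracles minimize their loss exhaustively over the grid", {
  set.seed(77)
  cfg <- calibrate_intercept(scenario_config(250, 5, 1, 0.25), n_ref = 5e4)
  d <- generate_dataset(cfg)
  truth_std <- scenario_coefficients(5, 1)$beta_std[1]
  g <- make_grid(40)

  oex <- oracle_lambda(d, g, truth = truth_std, mode = "explanation")
  expect_equal(oex$criterion, "OEX")
  expect_equal(oex$lambda_star, g[which.min(oex$trace$value)])
  # exhaustive re-scan: loss at lambda* is minimal everywhere
  s <- standardize(d$x)
  for (l in g[seq(1, 40, by = 6)]) {
    loss_l <- (unname(fit_ridge_direct(s, d$y, l)$coefficients[1]) -
                 truth_std)^2
    expect_gte(loss_l + 1e-10, min(oex$trace$value))
  }

  op <- oracle_lambda(d, g, mode = "prediction")
  expect_equal(op$criterion, "OP")
  expect_equal(op$lambda_star, g[which.min(op$trace$value)])
  # a fit that attains zero loss would be selected: truth equal to a fit
  fitg <- fit_ridge_direct(s, d$y, g[17])
  d_fake <- d
  d_fake$true_probs <- predict_probs(fitg, d$x)
  op2 <- oracle_lambda(d_fake, g, mode = "prediction")
  expect_equal(op2$lambda_star, g[17])

  expect_error(oracle_lambda(d, g, mode = "explanation"), "beta1")
})
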