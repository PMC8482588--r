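d1 <- illustration_dataset(1)
d2 <- illustration_dataset(2)

test_that("maximum likelihood reproduces closed forms", {
  # intercept-only: 25 events of 100
  d0 <- lr_dataset(matrix(nrow = 100, ncol = 0),
                   rep(c(1, 0), c(25, 75)))
  expect_equal(fit_ml(d0)$intercept, qlogis(0.25), tolerance = 1e-7)

  # 2x2 closed-form odds ratio on dataset 2
  fit <- fit_ml(d2)
  expect_equal(unname(coef(fit)["x"]), log(9 * 19 / (1 * 71)),
               tolerance = 1e-6)
  expect_true(fit$converged)
  expect_lte(fit$log_likelihood, 0)

  # leave one event out of dataset 1: fitted probability at x=1 is 8/79
  dl <- lr_dataset(d1$x[-100, , drop = FALSE], d1$y[-100])
  expect_equal(predict_probs(fit_ml(dl), matrix(1)), 8 / 79,
               tolerance = 1e-6)
})

test_that("ML under separation returns capped estimates, not an error", {
  fit <- fit_ml(d1)
  expect_false(fit$converged)
  expect_lte(max(abs(c(fit$intercept, fit$coefficients))), 50)
})

test_that("intercept-only degenerate outcomes are rejected", {
  expect_error(fit_ml(lr_dataset(matrix(nrow = 10, ncol = 0), rep(0, 10))),
               "event rate")
})

test_that("Firth matches the Jeffreys posterior mode for binomial data", {
  # intercept-only: Jeffreys prior is Beta(1/2, 1/2), mode (k+1/2)/(N+1)
  for (k in c(3, 10, 25)) {
    d0i <- lr_dataset(matrix(nrow = 40, ncol = 0), rep(c(1, 0), c(k, 40 - k)))
    expect_equal(plogis(fit_firth(d0i)$intercept), (k + 0.5) / 41,
                 tolerance = 1e-7)
  }
})

test_that("Firth shrinks the 2x2 estimates and stays finite under separation", {
  f2 <- fit_firth(d2)
  m2 <- fit_ml(d2)
  expect_equal(unname(coef(f2)["x"]), 0.55, tolerance = 0.01)
  expect_lt(abs(coef(f2)["x"]), abs(coef(m2)["x"]))

  f1 <- fit_firth(d1)
  expect_true(f1$converged)
  expect_true(all(is.finite(coef(f1))))
  expect_equal(unname(coef(f1)["x"]), 1.71, tolerance = 0.02)
})

test_that("FLIC restores calibration-in-the-large exactly", {
  for (d in list(d1, d2)) {
    fl <- flic_adjust(fit_firth(d), d)
    expect_equal(mean(predict_probs(fl, d$x)), mean(d$y), tolerance = 1e-8)
    # slopes untouched
    expect_equal(fl$coefficients, fit_firth(d)$coefficients)
  }
  # printed predictions for dataset 1
  fl1 <- flic_adjust(fit_firth(d1), d1)
  expect_lt(abs(predict_probs(fl1, matrix(0)) - 0.02), 0.005)
  expect_lt(abs(predict_probs(fl1, matrix(1)) - 0.11), 0.005)
})

test_that("FLIC is a fixed point when the mean prediction already matches", {
  # re-adjusting an already calibrated intercept leaves it unchanged
  fl <- flic_adjust(fit_firth(d2), d2)
  fl$method <- "Firth"
  fl2 <- flic_adjust(fl, d2)
  expect_equal(fl2$intercept, fl$intercept, tolerance = 1e-8)
})

test_that("direct ridge spans the ML and fully-shrunk limits", {
  s2 <- standardize(d2$x)
  # lambda = 0 equals maximum likelihood
  r0 <- fit_ridge_direct(s2, d2$y, 0)
  m <- fit_ml(d2)
  expect_equal(unname(r0$coefficients_original), unname(m$coefficients),
               tolerance = 1e-6)
  # penalty-dominated limit: slopes vanish, intercept -> logit(event rate)
  rbig <- fit_ridge_direct(s2, d2$y, 1e8)
  expect_lt(max(abs(rbig$coefficients)), 1e-3)
  expect_equal(rbig$intercept, qlogis(mean(d2$y)), tolerance = 1e-3)
  # mean predicted probability equals the event rate (unpenalized intercept)
  r <- fit_ridge_direct(s2, d2$y, 2)
  expect_equal(mean(predict_probs(r, d2$x)), mean(d2$y), tolerance = 1e-8)
})

test_that("near-unpenalized ridge on separated data matches the printed value", {
  f <- fit_ridge_direct(standardize(d1$x), d1$y, 1e-6)
  expect_equal(unname(coef(f, "original")["x"]), 13.94, tolerance = 0.05)
})

test_that("ridge objective is strictly concave: optimizer starts agree", {
  set.seed(7)
  for (i in 1:5) {
    d <- random_dataset(60, 2)
    s <- standardize(d$x)
    a <- fit_ridge_direct(s, d$y, 0.5)
    warm <- c(fit_ml(d)$intercept, fit_ml(d)$coefficients * s$scale)
    b <- fit_ridge_direct(s, d$y, 0.5, init = warm)
    expect_lt(max(abs(coef(a) - coef(b))), 1e-6)
  }
})

test_that("slope norm of direct ridge is non-increasing in lambda", {
  set.seed(11)
  d <- random_dataset(70, 3)
  s <- standardize(d$x)
  norms <- vapply(make_grid(25), function(l) {
    sqrt(sum(fit_ridge_direct(s, d$y, l)$coefficients^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("data augmentation approximates the direct optimizer", {
  s2 <- standardize(d2$x)
  # lambda = 0: no pseudo-weight, equals ML
  a0 <- fit_ridge_augmented(s2, d2$y, 0)
  expect_equal(unname(a0$coefficients_original),
               unname(fit_ml(d2)$coefficients), tolerance = 1e-6)
  # lambda = 2: two-decimal agreement with the exact optimizer
  a2 <- fit_ridge_augmented(s2, d2$y, 2)
  r2 <- fit_ridge_direct(s2, d2$y, 2)
  expect_lt(max(abs(coef(a2) - coef(r2))), 1e-2)
  # heavy shrinkage reproduces the printed coefficient
  a100 <- fit_ridge_augmented(s2, d2$y, 100)
  expect_lt(abs(unname(coef(a100, "original")["x"]) - 0.06), 0.01)
  expect_error(fit_ridge_augmented(s2, d2$y, -1), "nonnegative")
})

test_that("pseudo-records implement the stated augmentation scheme", {
  aug <- augmentation_scheme(3, 0.7, s = 10)
  expect_equal(nrow(aug$design), 6)
  expect_equal(aug$weight, rep(2 * 100 * 0.7, 6))
  expect_equal(aug$design[, 1], rep(0, 6))          # no intercept share
  expect_equal(colSums(aug$design[, -1] != 0), rep(2, 3))
  expect_equal(unique(aug$design[aug$design != 0]), 0.1)
  expect_equal(aug$outcome, rep(c(1, 0), 3))
})

test_that("predictions are proper probabilities on either scale", {
  # zero coefficients, zero intercept: everything 0.5
  s2 <- standardize(d2$x)
  f <- fit_ridge_direct(s2, d2$y, 1e8)
  f$intercept <- 0
  f$coefficients[] <- 0
  expect_equal(predict_probs(f, d2$x), rep(0.5, 100))

  # standardized-scale fit and its original-scale view agree on raw data
  set.seed(3)
  d <- random_dataset(50, 3)
  r <- fit_ridge_direct(standardize(d$x), d$y, 1)
  p_std <- predict_probs(r, d$x)
  p_orig <- plogis(r$intercept_original +
                     drop(d$x %*% r$coefficients_original))
  expect_lt(max(abs(p_std - p_orig)), 1e-10)

  expect_error(predict_probs(r, d$x[, 1:2]), "dimension")
  expect_true(all(p_std > 0 & p_std < 1))
})
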