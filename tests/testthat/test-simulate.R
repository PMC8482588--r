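test_that("the latent correlation matrix matches its specification", {
  raw <- correlation_matrix(adjusted = FALSE)
  expect_equal(raw["Z1", "Z2"], 0.5)
  expect_equal(raw["Z2", "Z14"], 0.3)
  expect_equal(raw["Z3", "Z4"], -0.5)
  expect_true(isSymmetric(raw))
  expect_equal(unname(diag(raw)), rep(1, 15))
  expect_equal(sum(raw != 0) - 15, 2 * 24)   # 24 declared pairs

  adj <- correlation_matrix()
  expect_gt(min(eigen(adj, symmetric = TRUE, only.values = TRUE)$values), 0)
  # the projection moves entries only slightly
  expect_lt(max(abs(adj - raw)), 0.03)
})

test_that("sampled covariates reproduce the schema's moments", {
  set.seed(915)
  X <- sample_covariates(1e5)
  sch <- covariate_schema()
  # binary/ordinal ranges
  expect_true(all(X[, 1:4] %in% c(0, 1)))
  expect_true(all(X[, 5:6] %in% c(0, 2, 1)))
  # E(X1) = pnorm(0.84) ~ 0.80, E(X5) from the two normal tails
  expect_equal(mean(X[, 1]), pnorm(0.84), tolerance = 0.01)
  expect_equal(mean(X[, 5]), pnorm(1.2) + pnorm(-0.75), tolerance = 0.01)
  # all expected values within 2% relative error of the schema
  rel <- abs(colMeans(X) - sch$expected_value) /
    pmax(abs(sch$expected_value), 0.5)
  expect_true(all(rel < 0.02))
  # truncation thresholds are never exceeded
  thr <- simulation_reference()$thresholds
  for (nm in names(thr)) expect_lte(max(X[, nm]), thr[[nm]])
})

test_that("latent pairwise correlations match the sampled matrix", {
  set.seed(331)
  sigma <- correlation_matrix()
  Z <- matrix(rnorm(1e5 * 15), ncol = 15) %*% chol(sigma)
  expect_lt(max(abs(cor(Z) - sigma)), 0.015)
})

test_that("scenario coefficients reproduce the standardized views", {
  sc <- scenario_coefficients(10, 1)
  printed <- c(0.83, 0.67, 0.35, 0.35, 0.2, 0.21, 0.37, 0.67, 0.66, 0.36)
  # X7's printed value is inconsistent with X10's (identical marginals);
  # allow 0.015 there, 0.01 everywhere else
  tol <- c(rep(0.01, 6), 0.015, 0.01, 0.01, 0.01)
  expect_true(all(abs(sc$beta_std - printed) <= tol))
  expect_equal(unname(sc$beta[1:6]), c(2.08, 1.39, 0.69, 0.69, 0.35, 0.35))
  expect_lt(abs(unname(sc$beta[7]) - 0.036), 0.001)
  expect_lt(abs(unname(sc$beta[8]) - 0.003), 0.0005)

  half <- scenario_coefficients(2, 0.5)
  expect_equal(unname(half$beta), c(1.04, 0.695))
  expect_lt(max(abs(unname(half$beta_std) - c(0.42, 0.33))), 0.01)
  expect_error(scenario_coefficients(7), "K must be")
})

test_that("intercept calibration hits the target event rate", {
  cfg <- scenario_config(100, 2, 1, 0.25)
  # closed form when all coefficients are zero
  cfg0 <- cfg
  cfg0$beta[] <- 0
  set.seed(4)
  cfg0 <- calibrate_intercept(cfg0, n_ref = 1000)
  expect_equal(cfg0$beta0, qlogis(0.25), tolerance = 1e-5)

  # out-of-sample recalculation for the real coefficients
  set.seed(5)
  cfg <- calibrate_intercept(cfg, n_ref = 2e5)
  set.seed(6)
  X <- sample_covariates(2e5)
  pr <- plogis(cfg$beta0 + drop(X[, 1:2] %*% cfg$beta))
  expect_equal(mean(pr), 0.25, tolerance = 0.005)

  # monotonicity in the target rate
  cfg10 <- scenario_config(100, 2, 1, 0.1)
  set.seed(5)
  cfg10 <- calibrate_intercept(cfg10, n_ref = 5e4)
  expect_lt(cfg10$beta0, cfg$beta0)
})

test_that("generated datasets carry coherent truth", {
  set.seed(7)
  cfg <- calibrate_intercept(scenario_config(200, 5, 0.5, 0.25),
                             n_ref = 5e4)
  d <- generate_dataset(cfg)
  expect_equal(nrow(d$x), 200)
  expect_equal(ncol(d$x), 5)
  expect_true(all(d$true_probs > 0 & d$true_probs < 1))
  expect_identical(attr(d, "scenario_id"), cfg$scenario_id)

  dn <- cfg
  dn$noise <- TRUE
  expect_equal(colnames(generate_dataset(dn)$x),
               c(paste0("X", 1:5), paste0("X", 11:15)))
  expect_error(generate_dataset(scenario_config(100, 2, 1, 0.1)),
               "not calibrated")
})

test_that("sparse strong-effect scenarios frequently separate", {
  set.seed(8)
  cfg <- calibrate_intercept(scenario_config(100, 5, 1, 0.1), n_ref = 1e5)
  sep <- vapply(1:100, function(i) detect_separation(generate_dataset(cfg)),
                logical(1))
  expect_gt(mean(sep), 0.3)   # tens of percent, up to 85% reported
  expect_lt(mean(sep), 0.95)
})

test_that("the illustration fixtures match their printed tables", {
  d1 <- illustration_dataset(1)
  expect_equal(nrow(d1$x), 100)
  expect_equal(sum(d1$y), 9)
  expect_equal(sum(d1$y[d1$x == 0]), 0)
  d2 <- illustration_dataset(2)
  expect_equal(sum(d2$y[d2$x == 0]), 1)
  expect_equal(sum(d2$y), 10)
  expect_equal(sum(d2$x == 0), 20)
  expect_error(illustration_dataset(3), "1 or 2")
})

test_that("the illustration sampler implements its generating process", {
  set.seed(9)
  d <- illustration_sampler(1e5)
  expect_equal(unique(d$true_probs[d$x == 0]), plogis(-3.05))
  expect_equal(unique(d$true_probs[d$x == 1]), plogis(-2.05))
  expect_equal(mean(d$x), 0.8, tolerance = 0.005)
  # marginal event rate ~ 0.2 * 0.045 + 0.8 * 0.114 ~ 0.10
  expect_lt(abs(mean(d$y) -
                  (0.2 * plogis(-3.05) + 0.8 * plogis(-2.05))), 0.005)
})
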