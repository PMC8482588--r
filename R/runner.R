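# Orchestration: the factorial scenario grid, per-scenario simulation with
# per-replicate child seeds (any replicate is reproducible in isolation),
# the illustration mini-study, aggregation into per-scenario performance
# tables, and a checkpointed experiment driver.

ridge_method_ids <- c("D", "GCV", "CE", "RCV50", "RCV95", "AIC", "IP", "WP",
                      "OEX", "OP")
all_method_ids <- c(ridge_method_ids, "FLIC")

# Evaluate several tuning criteria from one set of shared fit paths.
tune_all <- function(data, grid, criteria, cutoff = NULL, truth_std = NULL,
                     true_probs = NULL) {
  need_loo <- any(criteria %in% c("D", "GCV", "CE"))
  need_full <- any(criteria %in% c("GCV", "AIC", "OEX", "OP"))
  paths <- tuning_paths(data, grid, need_loo = need_loo,
                        need_full = need_full)
  n <- paths$n
  out <- list()
  for (cr in criteria) {
    if (cr %in% c("OEX", "OP")) {
      Xint <- cbind(1, paths$design$matrix)
      loss <- if (cr == "OEX") {
        (paths$full$coef[2, ] - truth_std)^2
      } else {
        colSums((expit(Xint %*% paths$full$coef) - true_probs)^2)
      }
      out[[cr]] <- new_tuning_result(grid[which.min(loss)], cr, grid,
                                     trace = data.frame(lambda = grid,
                                                        value = loss))
      next
    }
    values <- switch(cr,
      D = deviance_from_loo(paths$loo),
      GCV = n * deviance_from_loo(paths$loo) / (n - paths$full$df)^2,
      CE = ce_from_loo(paths$loo, cutoff %||% mean(data$y), n),
      AIC = -2 * paths$full$log_likelihood + 2 * paths$full$df)
    idx <- if (cr == "CE") max(which(values <= min(values) + 1e-12))
           else which.min(values)
    out[[cr]] <- new_tuning_result(grid[idx], cr, grid,
                                   trace = data.frame(lambda = grid,
                                                      value = values))
  }
  out
}

#' Factorial scenario grid
#'
#' The base full factorial design N in 100/250/500 x K in 2/5/10 x effect
#' multiplier a in 0.5/1 x event rate 0.1/0.25 x noise absent/present (72
#' scenarios); the extension adds N = 1000 crossed with K in 5/10, a, event
#' rate and noise (16 more, 88 in total).
#'
#' @param include_extension include the N = 1000 scenarios.
#' @return List of uncalibrated [scenario_config()] objects.
#' @export
scenario_grid <- function(include_extension = FALSE) {
  base <- expand.grid(N = c(100, 250, 500), K = c(2, 5, 10), a = c(0.5, 1),
                      rate = c(0.1, 0.25), noise = c(FALSE, TRUE))
  if (include_extension) {
    ext <- expand.grid(N = 1000, K = c(5, 10), a = c(0.5, 1),
                       rate = c(0.1, 0.25), noise = c(FALSE, TRUE))
    base <- rbind(base, ext)
  }
  lapply(seq_len(nrow(base)), function(i) {
    scenario_config(base$N[i], base$K[i], base$a[i], base$rate[i],
                    base$noise[i])
  })
}

method_record <- function(scenario_id, replicate, method, separated, n_train,
                          true_beta1) {
  data.frame(scenario_id = scenario_id, replicate = replicate,
             method = method, separated = separated, n_train = n_train,
             beta1_true = true_beta1, lambda_star = NA_real_,
             at_boundary = NA_character_, beta1_std = NA_real_,
             beta1_orig = NA_real_, slope = NA_real_,
             slope_degenerate = FALSE, c_index = NA_real_,
             pred_sse = NA_real_, failed = FALSE, message = "",
             stringsAsFactors = FALSE)
}

evaluate_fit <- function(rec, fit, data, validation) {
  rec$beta1_std <- if (identical(fit$scale, "standardized"))
    unname(fit$coefficients[1]) else NA_real_
  rec$beta1_orig <- unname(fit$coefficients_original[1])
  sl <- calibration_slope(fit, validation)
  rec$slope <- as.numeric(sl)
  rec$slope_degenerate <- isTRUE(attr(sl, "degenerate"))
  rec$c_index <- c_index(fit, validation)
  if (!is.null(data$true_probs)) {
    rec$pred_sse <- sum((predict_probs(fit, data$x) - data$true_probs)^2)
  }
  rec
}

#' Run one simulation scenario
#'
#' Generates a fixed validation set (default 10,000 observations, outcomes
#' drawn once), then for each replicate generates a training dataset, flags
#' separation, fits every requested method and evaluates it on the
#' validation set.  Replicate r is seeded by `child_seed(seed, 1, r)`, so
#' any replicate can be re-run in isolation.  Method-level failures are
#' recorded per replicate, not fatal.
#'
#' @param config a [scenario_config()]; calibrated here if needed.
#' @param methods subset of D, GCV, CE, RCV50, RCV95, AIC, IP, WP, OEX, OP,
#'   FLIC.
#' @param replicates number of simulated datasets.
#' @param seed root seed for this scenario.
#' @param grid candidate lambdas for the tuned methods.
#' @param n_validation validation sample size.
#' @param ref optional covariate reference sample for intercept calibration
#'   (sampled with `n_ref` rows if needed and missing).
#' @param n_ref calibration reference size.
#' @param rcv_reps,rcv_folds repeated-CV settings for RCV50/RCV95.
#' @return List with `records` (one row per replicate x method) and
#'   `config` (calibrated).
#' @export
run_scenario <- function(config, methods = c("D", "AIC", "IP", "WP", "FLIC"),
                         replicates = 100, seed = 1, grid = make_grid(),
                         n_validation = 1e4, ref = NULL, n_ref = 1e6,
                         rcv_reps = 50L, rcv_folds = 10L) {
  stopifnot(inherits(config, "scenario_config"),
            all(methods %in% all_method_ids), replicates >= 1)
  if (is.na(config$beta0)) {
    if (is.null(ref)) {
      set.seed(child_seed(seed, 0, 1))
      ref <- sample_covariates(n_ref)
    }
    config <- calibrate_intercept(config, ref = ref)
  }
  sc <- scenario_coefficients(config$K, config$a)
  beta1_true_orig <- unname(sc$beta[1])
  beta1_true_std <- unname(sc$beta_std[1])

  val_config <- config
  val_config$N <- n_validation
  set.seed(child_seed(seed, 0, 0))
  validation <- generate_dataset(val_config)

  criteria <- intersect(methods, c("D", "GCV", "CE", "AIC", "OEX", "OP"))
  fixed <- intersect(methods, c("IP", "WP"))
  fixed_lambda <- c(IP = prior_to_lambda(4)$lambda,
                    WP = prior_to_lambda(16)$lambda)
  rcv <- intersect(methods, c("RCV50", "RCV95"))

  rows <- vector("list", replicates * length(methods))
  ri <- 0L
  for (r in seq_len(replicates)) {
    set.seed(child_seed(seed, 1, r))
    d <- generate_dataset(config)
    sep <- detect_separation(d)
    design <- try(standardize(d$x), silent = TRUE)
    tuned <- NULL
    if (length(criteria) && !inherits(design, "try-error")) {
      tuned <- tryCatch(
        tune_all(d, grid, criteria, truth_std = beta1_true_std,
                 true_probs = d$true_probs),
        error = function(e) e)
    }
    for (m in methods) {
      ri <- ri + 1L
      rec <- method_record(config$scenario_id, r, m, sep, config$N,
                           beta1_true_orig)
      rec <- tryCatch({
        if (m == "FLIC") {
          fit <- flic_adjust(fit_firth(d), d)
          evaluate_fit(rec, fit, d, validation)
        } else {
          if (inherits(design, "try-error")) {
            stop(attr(design, "condition")$message)
          }
          lam <- if (m %in% names(fixed_lambda)) {
            unname(fixed_lambda[m])
          } else if (m %in% rcv) {
            theta <- if (m == "RCV50") 0.5 else 0.95
            tr <- repeated_cv(d, grid, folds = rcv_folds, reps = rcv_reps,
                              theta = theta, seed = child_seed(seed, 3, r))
            rec$lambda_star <- tr$lambda_star
            rec$at_boundary <- tr$at_boundary
            tr$lambda_star
          } else {
            if (inherits(tuned, "error")) stop(conditionMessage(tuned))
            tr <- tuned[[m]]
            rec$lambda_star <- tr$lambda_star
            rec$at_boundary <- tr$at_boundary
            tr$lambda_star
          }
          if (m %in% names(fixed_lambda)) rec$lambda_star <- lam
          fit <- fit_ridge_direct(design, d$y, lam)
          evaluate_fit(rec, fit, d, validation)
        }
      }, error = function(e) {
        rec$failed <- TRUE
        rec$message <- conditionMessage(e)
        rec
      })
      rows[[ri]] <- rec
    }
  }
  list(records = do.call(rbind, rows), config = config)
}

#' Aggregate replicate records into performance tables
#'
#' One row per scenario and method: RMSE of the first coefficient (original
#' scale), pooled RMSE of predictions, calibration-slope median and
#' quartiles, RMSD and MAD (scaled and raw) of log slopes, mean c-index,
#' variability of tuned lambdas (MAD of log10 lambda*), the Spearman
#' correlation between slopes and lambdas, separation prevalence, and the
#' number of failed fits (excluded pairwise).
#'
#' @param records record table(s) from [run_scenario()] /
#'   [run_illustration()], row-bound.
#' @return A data frame, one row per scenario x method.
#' @export
summarize_records <- function(records) {
  if (is.null(records) || !nrow(records)) stop("no records supplied")
  split_on <- interaction(records$scenario_id, records$method, drop = TRUE)
  out <- lapply(split(records, split_on), function(g) {
    ok <- g[!g$failed, , drop = FALSE]
    sl <- ok$slope[!is.na(ok$slope)]
    lam <- ok$lambda_star[!is.na(ok$lambda_star)]
    data.frame(
      scenario_id = g$scenario_id[1],
      method = g$method[1],
      n_replicates = nrow(g),
      n_failed = sum(g$failed),
      separation_rate = mean(g$separated),
      rmse_beta1 = if (nrow(ok)) rmse_coefficient(ok$beta1_orig,
                                                  ok$beta1_true[1])
                   else NA_real_,
      rmse_pred = if (any(!is.na(ok$pred_sse)))
        sqrt(sum(ok$pred_sse, na.rm = TRUE) /
               (sum(!is.na(ok$pred_sse)) * g$n_train[1])) else NA_real_,
      slope_median = if (length(sl)) stats::median(sl) else NA_real_,
      slope_q25 = if (length(sl)) unname(stats::quantile(sl, 0.25))
                  else NA_real_,
      slope_q75 = if (length(sl)) unname(stats::quantile(sl, 0.75))
                  else NA_real_,
      rmsd_log_slope = if (length(sl)) rmsd_log_slopes(sl) else NA_real_,
      mad_log_slope = if (length(sl)) mad_log_slopes(sl) else NA_real_,
      mad_log_slope_raw = if (length(sl)) mad_log_slopes(sl, constant = 1)
                          else NA_real_,
      c_index_mean = mean(ok$c_index, na.rm = TRUE),
      lambda_star_mad_log10 = if (length(lam)) stats::mad(log10(lam))
                              else NA_real_,
      spearman_slope_lambda = if (length(lam) >= 3 &&
                                  stats::sd(lam) > 1e-15 &&
                                  stats::sd(sl) > 1e-15)
        spearman_slope_lambda(ok$slope, ok$lambda_star) else NA_real_,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$scenario_id, res$method), , drop = FALSE]
}

#' The illustration mini-study
#'
#' Repeats the illustration generating process (binary covariate with mean
#' 0.8, event probability `expit(-3.05 + x)`, n = 100): per replicate the
#' covariate is standardized, lambda is tuned by leave-one-out deviance
#' over the grid, and ridge (at lambda*), FLIC and ridge with the
#' informative prior (lambda = 2) are fitted and evaluated against a fixed
#' 10,000-observation validation set.
#'
#' @param replicates number of simulated datasets (500 in the study).
#' @param seed root seed.
#' @param grid candidate lambdas.
#' @param n_validation validation sample size.
#' @return List of class `illustration_summary`: `records`, the boundary
#'   selection fractions of the deviance-tuned lambda, and per-method bias,
#'   MSE of the slope coefficient (original scale, truth 1) and calibration
#'   slope quartiles.
#' @export
run_illustration <- function(replicates = 500, seed = 1, grid = make_grid(),
                             n_validation = 1e4) {
  set.seed(child_seed(seed, 0, 0))
  validation <- illustration_sampler(n_validation)
  lambda_ip <- prior_to_lambda(4)$lambda
  rows <- vector("list", 3L * replicates)
  ri <- 0L
  for (r in seq_len(replicates)) {
    set.seed(child_seed(seed, 1, r))
    d <- illustration_sampler(100)
    sep <- detect_separation(d)
    for (m in c("D", "IP", "FLIC")) {
      ri <- ri + 1L
      rec <- method_record("illustration", r, m, sep, 100, 1)
      rec <- tryCatch({
        if (m == "FLIC") {
          fit <- flic_adjust(fit_firth(d), d)
        } else {
          design <- standardize(d$x)
          lam <- if (m == "IP") lambda_ip else {
            tr <- tune_lambda(d, grid, "D")
            rec$lambda_star <- tr$lambda_star
            rec$at_boundary <- tr$at_boundary
            tr$lambda_star
          }
          if (m == "IP") rec$lambda_star <- lam
          fit <- fit_ridge_direct(design, d$y, lam)
        }
        evaluate_fit(rec, fit, d, validation)
      }, error = function(e) {
        rec$failed <- TRUE
        rec$message <- conditionMessage(e)
        rec
      })
      rows[[ri]] <- rec
    }
  }
  records <- do.call(rbind, rows)
  tuned <- records[records$method == "D" & !records$failed, ]
  per_method <- lapply(split(records[!records$failed, ],
                             records$method[!records$failed]), function(g) {
    sl <- g$slope[!is.na(g$slope)]
    list(bias_beta1 = mean(g$beta1_orig) - 1,
         mse_beta1 = mean((g$beta1_orig - 1)^2),
         slope_median = stats::median(sl),
         slope_q25 = unname(stats::quantile(sl, 0.25)),
         slope_q75 = unname(stats::quantile(sl, 0.75)))
  })
  structure(list(records = records,
                 replicates = replicates,
                 boundary_lower_frac = mean(tuned$at_boundary == "lower"),
                 boundary_upper_frac = mean(tuned$at_boundary == "upper"),
                 methods = per_method),
            class = "illustration_summary")
}

#' @export
print.illustration_summary <- function(x, ...) {
  cat(sprintf("<illustration mini-study>  %d replicates\n", x$replicates))
  cat(sprintf("  deviance-tuned lambda* at lower/upper grid boundary: %.0f%% / %.0f%%\n",
              100 * x$boundary_lower_frac, 100 * x$boundary_upper_frac))
  for (m in names(x$methods)) {
    s <- x$methods[[m]]
    cat(sprintf("  %-4s bias %.2f, MSE %.2f, slope median %.2f (%.2f, %.2f)\n",
                m, s$bias_beta1, s$mse_beta1, s$slope_median, s$slope_q25,
                s$slope_q75))
  }
  invisible(x)
}

#' Experiment plan
#'
#' @param scenarios list of [scenario_config()]s (ids must be unique).
#' @param methods methods to run in every scenario.
#' @param replicates simulated datasets per scenario.
#' @param seed root seed of the experiment.
#' @param grid candidate lambdas.
#' @param n_validation,n_ref validation and calibration-reference sizes.
#' @return An `experiment_plan`.
#' @export
make_plan <- function(scenarios, methods = c("D", "AIC", "IP", "WP", "FLIC"),
                      replicates = 1000, seed = 1, grid = make_grid(),
                      n_validation = 1e4, n_ref = 1e6) {
  ids <- vapply(scenarios, `[[`, "", "scenario_id")
  if (anyDuplicated(ids)) stop("scenario ids must be unique")
  stopifnot(replicates >= 1, all(methods %in% all_method_ids))
  structure(list(scenarios = scenarios, methods = methods,
                 replicates = replicates, seed = seed, grid = grid,
                 n_validation = n_validation, n_ref = n_ref),
            class = "experiment_plan")
}

#' Run (or resume) a planned experiment
#'
#' Executes every scenario of the plan, writing one records CSV per
#' scenario plus a pooled `records.csv`, `summary.csv` and
#' `plan.resolved.json` into `out_dir`.  Scenario i is seeded by
#' `child_seed(seed, 2000 + i)` and the calibration reference sample by
#' `child_seed(seed, 0, 999)`, independent of execution order, so an
#' interrupted run resumed with `resume = TRUE` (completed scenario files
#' are kept) produces byte-identical outputs.
#'
#' @param plan an [make_plan()] object.
#' @param out_dir output directory, created if needed.
#' @param resume skip scenarios whose records file already exists.
#' @return Invisibly, the summary data frame.
#' @export
run_experiment <- function(plan, out_dir, resume = TRUE) {
  stopifnot(inherits(plan, "experiment_plan"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(child_seed(plan$seed, 0, 999))
  ref <- sample_covariates(plan$n_ref)
  for (i in seq_along(plan$scenarios)) {
    config <- plan$scenarios[[i]]
    file_i <- file.path(out_dir,
                        sprintf("records_%s.csv", config$scenario_id))
    if (resume && file.exists(file_i)) next
    res <- run_scenario(config, methods = plan$methods,
                        replicates = plan$replicates,
                        seed = child_seed(plan$seed, 2000 + i),
                        grid = plan$grid, n_validation = plan$n_validation,
                        ref = ref)
    utils::write.csv(res$records, file_i, row.names = FALSE)
  }
  records <- do.call(rbind, lapply(plan$scenarios, function(cf) {
    utils::read.csv(file.path(out_dir,
                              sprintf("records_%s.csv", cf$scenario_id)),
                    stringsAsFactors = FALSE)
  }))
  utils::write.csv(records, file.path(out_dir, "records.csv"),
                   row.names = FALSE)
  summary <- summarize_records(records)
  utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  resolved <- list(
    scenario_ids = vapply(plan$scenarios, `[[`, "", "scenario_id"),
    methods = plan$methods, replicates = plan$replicates, seed = plan$seed,
    grid = list(n = length(plan$grid), lo = plan$grid[1],
                hi = plan$grid[length(plan$grid)]),
    n_validation = plan$n_validation, n_ref = plan$n_ref,
    package_version = as.character(utils::packageVersion("ridgetune")))
  jsonlite::write_json(resolved, file.path(out_dir, "plan.resolved.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
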