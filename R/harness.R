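#' Performance measures of an estimator against known truth
#'
#' Standard simulation-study measures over `R` replicate estimates:
#' bias `mean(est) - truth`; empirical SE, the sample SD of the estimates
#' (divisor `R - 1`); and RMSE `sqrt(mean((est - truth)^2))`. Monte Carlo
#' SEs use the usual formulas: `empSE / sqrt(R)` for the bias,
#' `empSE / sqrt(2 (R - 1))` for the empirical SE, and a delta-method SE for
#' the RMSE. The algebraic identity
#' `RMSE^2 = bias^2 + empSE^2 (R - 1) / R` holds exactly.
#'
#' @param estimates Numeric vector of at least 2 replicate estimates.
#' @param truth The true value of the estimand.
#' @return A one-row data.frame with columns `bias`, `emp_se`, `rmse`,
#'   `mcse_bias`, `mcse_emp_se`, `mcse_rmse`, `n`.
#' @export
performance_measures <- function(estimates, truth) {
  if (length(estimates) < 2) stop("need at least 2 estimates")
  stopifnot(all(is.finite(estimates)), is.finite(truth))
  r <- length(estimates)
  bias <- mean(estimates) - truth
  emp_se <- stats::sd(estimates)
  sq_err <- (estimates - truth)^2
  rmse <- sqrt(mean(sq_err))
  mcse_rmse <- if (rmse > 0) {
    stats::sd(sq_err) / sqrt(r) / (2 * rmse)
  } else 0
  data.frame(bias = bias, emp_se = emp_se, rmse = rmse,
             mcse_bias = emp_se / sqrt(r),
             mcse_emp_se = emp_se / sqrt(2 * (r - 1)),
             mcse_rmse = mcse_rmse, n = r)
}

#' Default model/prior grid of the simulation study
#'
#' Normal and Gamma cost models with Uniform(0, 1000) and Uniform(0, 10000)
#' priors on the working-scale cost SD, and Log-Normal cost models with
#' Uniform(0, 0.8), (0, 1), (0, 2) and (0, 3) priors on the log-scale cost
#' SD. The QALY component is Normal throughout, matching the study design in
#' which the QALY model is held fixed while cost models vary.
#'
#' @return A data.frame with columns `cost_family` and `cost_sd_upper`.
#' @export
default_model_grid <- function() {
  rbind(
    data.frame(cost_family = "normal", cost_sd_upper = c(1000, 10000)),
    data.frame(cost_family = "gamma", cost_sd_upper = c(1000, 10000)),
    data.frame(cost_family = "lognormal", cost_sd_upper = c(0.8, 1, 2, 3))
  )
}

#' Plan a simulation study
#'
#' A study plan crosses scenarios (data skewness x proportion of zeros x
#' sample size) with a grid of cost models and Uniform prior upper bounds.
#' The default scenario grid is the full 2 x 2 x 2 design:
#' positive-cost family in \{gamma, lognormal\}, `p_zero` in \{0, 0.10\},
#' `n_per_arm` in \{100, 1000\} — eight scenarios. Replicate `r` of scenario
#' `s` uses seed `base_seed + 100000 * s + r`, making every cell
#' reproducible in isolation.
#'
#' Costs are not rescaled in the harness (`scale_factor = 1`), preserving the
#' relationship between the data scale and the prior bounds under study; the
#' continuity constant `epsilon = 1` is applied per fit only when the
#' replicate contains zero costs and the cost family has positive support.
#'
#' @param scenarios A data.frame with columns `positive_cost_family`,
#'   `p_zero`, `n_per_arm` (default: the eight-scenario grid).
#' @param models A data.frame as from [default_model_grid()].
#' @param n_reps Replicates per scenario (default 1000; reduce for desk-scale
#'   runs).
#' @param mcmc A `cea_mcmc_config` used for every fit (default: the reduced
#'   protocol of [mcmc_config_test()]).
#' @param base_seed Base seed for the scenario/replicate seed derivation.
#' @param scenario_args Extra arguments passed to every [scenario_config()]
#'   call (e.g. different true means).
#' @param coef_sd_cost Prior SD for cost-model coefficients in every fit
#'   (default 1000: since the harness leaves costs unscaled, this carries the
#'   same vagueness as Normal(0, 100^2) does on a /10 working scale).
#' @return An object of class `cea_study_plan`.
#' @export
study_plan <- function(scenarios = NULL, models = default_model_grid(),
                       n_reps = 1000, mcmc = mcmc_config_test(),
                       base_seed = 1, scenario_args = list(),
                       coef_sd_cost = 1000) {
  if (is.null(scenarios)) {
    scenarios <- expand.grid(positive_cost_family = c("gamma", "lognormal"),
                             p_zero = c(0, 0.10), n_per_arm = c(100L, 1000L),
                             stringsAsFactors = FALSE)
  }
  stopifnot(all(c("positive_cost_family", "p_zero", "n_per_arm") %in%
                  names(scenarios)),
            all(c("cost_family", "cost_sd_upper") %in% names(models)),
            n_reps >= 1, inherits(mcmc, "cea_mcmc_config"))
  stopifnot(is.numeric(coef_sd_cost), coef_sd_cost > 0)
  structure(list(scenarios = scenarios, models = models,
                 n_reps = as.integer(n_reps), mcmc = mcmc,
                 base_seed = as.integer(base_seed),
                 scenario_args = scenario_args,
                 coef_sd_cost = coef_sd_cost),
            class = "cea_study_plan")
}

#' @export
print.cea_study_plan <- function(x, ...) {
  cat("<cea_study_plan> ", nrow(x$scenarios), " scenario(s) x ",
      nrow(x$models), " model/prior combination(s) x ", x$n_reps,
      " replicate(s)\n", sep = "")
  invisible(x)
}

# fit one model to one replicate and return posterior-mean estimates of the
# arm mean costs and the incremental cost, or NULL on failure/non-convergence
.fit_one_rep <- function(ds, cost_family, cost_sd_upper, mcmc, seed,
                         coef_sd_cost = 1000) {
  has_zero <- any(ds$data$total_cost == 0)
  positive <- cost_family %in% c("gamma", "lognormal")
  spec <- model_spec(cost_family = cost_family, qaly_family = "normal",
                     epsilon = if (has_zero && positive) 1 else 0,
                     scale_factor = 1)
  priors <- prior_config(cost_sd_upper = cost_sd_upper,
                         coef_sd_cost = coef_sd_cost)
  cfg <- mcmc_config(n_chains = mcmc$n_chains, n_iter = mcmc$n_iter,
                     n_burnin = mcmc$n_burnin, thin = mcmc$thin,
                     seed = seed, rhat_threshold = mcmc$rhat_threshold)
  fit <- tryCatch(run_mcmc(ds, spec, priors, cfg), error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(ok = FALSE, reason = conditionMessage(fit)))
  }
  conv <- convergence_report(fit)
  if (!attr(conv, "pass")) {
    return(list(ok = FALSE, reason = paste0("max R-hat ",
                                            round(max(conv$rhat), 3))))
  }
  am <- arm_mean_draws(fit)
  list(ok = TRUE,
       estimates = c(mean_cost_control = mean(am$cost0),
                     mean_cost_intervention = mean(am$cost1),
                     incremental_cost = mean(am$cost1) - mean(am$cost0)))
}

#' Run a simulation study
#'
#' For each scenario replicate: generate a dataset, fit every model/prior
#' combination, keep the posterior-mean estimates of the arm mean costs and
#' the incremental cost from fits that converge (max split R-hat below the
#' threshold), record failures without aborting, and aggregate converged
#' replicates with [performance_measures()].
#'
#' When `cache_dir` is given, per-replicate results are written as one CSV
#' per (scenario, replicate) keyed by its seed, and existing files are
#' reused, so an interrupted study resumes where it stopped.
#'
#' @param plan A `cea_study_plan`.
#' @param cache_dir Optional directory for per-replicate result caching.
#' @param verbose Print progress lines (default `FALSE`).
#' @return An object of class `performance_table`: a data.frame with one row
#'   per (scenario, model, prior, estimand) carrying bias, empirical SE,
#'   RMSE, their Monte Carlo SEs, `n_converged` and `n_failed`.
#' @export
run_study <- function(plan, cache_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(plan, "cea_study_plan"))
  if (!is.null(cache_dir) && !dir.exists(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE)
  }
  all_rows <- list()
  for (s in seq_len(nrow(plan$scenarios))) {
    sc <- plan$scenarios[s, ]
    rep_results <- vector("list", plan$n_reps)
    for (r in seq_len(plan$n_reps)) {
      seed <- plan$base_seed + 100000L * s + r
      cache_file <- if (!is.null(cache_dir)) {
        file.path(cache_dir, sprintf("s%02d_r%04d_seed%d.csv", s, r, seed))
      } else NULL
      if (!is.null(cache_file) && file.exists(cache_file)) {
        rep_results[[r]] <- utils::read.csv(cache_file,
                                            stringsAsFactors = FALSE)
        next
      }
      cfg_args <- c(list(positive_cost_family = sc$positive_cost_family,
                         p_zero = sc$p_zero, n_per_arm = sc$n_per_arm,
                         seed = seed), plan$scenario_args)
      gen <- generate_scenario(do.call(scenario_config, cfg_args))
      res_m <- lapply(seq_len(nrow(plan$models)), function(m) {
        md <- plan$models[m, ]
        out <- .fit_one_rep(gen$dataset, md$cost_family, md$cost_sd_upper,
                            plan$mcmc, seed = seed + 7919L * m,
                            coef_sd_cost = plan$coef_sd_cost)
        base <- data.frame(scenario = s, rep = r,
                           cost_family = md$cost_family,
                           cost_sd_upper = md$cost_sd_upper,
                           converged = out$ok)
        if (out$ok) {
          cbind(base, as.data.frame(as.list(out$estimates)))
        } else {
          base$reason <- out$reason
          cbind(base, data.frame(mean_cost_control = NA_real_,
                                 mean_cost_intervention = NA_real_,
                                 incremental_cost = NA_real_))
        }
      })
      res <- do.call(rbind, lapply(res_m, function(d) {
        d$reason <- if ("reason" %in% names(d)) d$reason else ""
        d
      }))
      res$truth_control <- gen$truth$arm_mean_cost[1]
      res$truth_intervention <- gen$truth$arm_mean_cost[2]
      res$truth_incremental <- gen$truth$incremental_cost
      if (!is.null(cache_file)) {
        utils::write.csv(res, cache_file, row.names = FALSE)
      }
      rep_results[[r]] <- res
      if (verbose) {
        message("scenario ", s, " rep ", r, "/", plan$n_reps, " done")
      }
    }
    all_rows[[s]] <- do.call(rbind, rep_results)
  }
  raw <- do.call(rbind, all_rows)
  perf <- .aggregate_performance(raw, plan)
  attr(perf, "replicates") <- raw
  perf
}

.aggregate_performance <- function(raw, plan) {
  estimands <- c(mean_cost_control = "truth_control",
                 mean_cost_intervention = "truth_intervention",
                 incremental_cost = "truth_incremental")
  cells <- unique(raw[, c("scenario", "cost_family", "cost_sd_upper")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    sub <- raw[raw$scenario == cell$scenario &
                 raw$cost_family == cell$cost_family &
                 raw$cost_sd_upper == cell$cost_sd_upper, ]
    conv <- sub[sub$converged, ]
    for (est in names(estimands)) {
      sc <- plan$scenarios[cell$scenario, ]
      base <- data.frame(
        scenario = cell$scenario,
        positive_cost_family = sc$positive_cost_family,
        p_zero = sc$p_zero, n_per_arm = sc$n_per_arm,
        cost_family = cell$cost_family,
        cost_sd_upper = cell$cost_sd_upper, estimand = est,
        n_converged = nrow(conv), n_failed = nrow(sub) - nrow(conv))
      perf <- if (nrow(conv) >= 2) {
        performance_measures(conv[[est]], conv[[estimands[[est]]]][1])
      } else {
        data.frame(bias = NA_real_, emp_se = NA_real_, rmse = NA_real_,
                   mcse_bias = NA_real_, mcse_emp_se = NA_real_,
                   mcse_rmse = NA_real_, n = nrow(conv))
      }
      rows[[length(rows) + 1]] <- cbind(base, perf)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("performance_table", "data.frame")
  out
}

#' Prior-sensitivity sweep on one dataset
#'
#' Refits one cost family under a sequence of Uniform prior upper bounds on
#' its cost SD parameter, reporting per bound the DIC, the posterior mean
#' arm costs and incremental cost with equal-tailed 95% credible intervals,
#' and the convergence verdict — the tabular layout used to compare models
#' with different Uniform priors on a case study. Fit failures are recorded
#' in-row rather than raised.
#'
#' @param ds A `trial_dataset`.
#' @param cost_family `"normal"`, `"gamma"` or `"lognormal"`.
#' @param upper_bounds Vector of Uniform upper bounds for the cost SD
#'   (working scale for normal/gamma; log scale for lognormal).
#' @param qaly_family QALY family; default `"normal"` for a normal cost
#'   family and `"beta"` otherwise, mirroring the case-study model pairs.
#' @param mcmc A `cea_mcmc_config`.
#' @param scale_factor Cost rescaling divisor (default 10, the case-study
#'   convention).
#' @param epsilon Continuity constant; `NULL` resolves automatically.
#' @return A data.frame with one row per upper bound.
#' @export
sensitivity_sweep <- function(ds, cost_family, upper_bounds,
                              qaly_family = NULL, mcmc = mcmc_config_test(),
                              scale_factor = 10, epsilon = NULL) {
  stopifnot(inherits(ds, "trial_dataset"))
  if (is.null(qaly_family)) {
    qaly_family <- if (cost_family == "normal") "normal" else "beta"
  }
  rows <- lapply(seq_along(upper_bounds), function(i) {
    u <- upper_bounds[i]
    spec <- model_spec(cost_family = cost_family, qaly_family = qaly_family,
                       epsilon = epsilon, scale_factor = scale_factor)
    priors <- prior_config(cost_sd_upper = u)
    fit <- tryCatch(run_mcmc(ds, spec, priors, mcmc), error = function(e) e)
    if (inherits(fit, "error")) {
      return(data.frame(cost_family = cost_family, cost_sd_upper = u,
                        dic = NA_real_, cost0 = NA_real_, cost0_lo = NA_real_,
                        cost0_hi = NA_real_, cost1 = NA_real_,
                        cost1_lo = NA_real_, cost1_hi = NA_real_,
                        incremental = NA_real_, incr_lo = NA_real_,
                        incr_hi = NA_real_, max_rhat = NA_real_,
                        converged = FALSE,
                        note = conditionMessage(fit)))
    }
    conv <- convergence_report(fit)
    res <- cea_summary(fit, wtp_grid = c(20000, 30000))
    s <- res$summary
    pick <- function(est) s[s$estimand == est, ]
    c0 <- pick("mean_cost_control"); c1 <- pick("mean_cost_intervention")
    ic <- pick("incremental_cost")
    data.frame(cost_family = cost_family, cost_sd_upper = u,
               dic = dic(fit)$dic,
               cost0 = c0$mean, cost0_lo = c0$lower, cost0_hi = c0$upper,
               cost1 = c1$mean, cost1_lo = c1$lower, cost1_hi = c1$upper,
               incremental = ic$mean, incr_lo = ic$lower, incr_hi = ic$upper,
               max_rhat = max(conv$rhat, na.rm = TRUE),
               converged = attr(conv, "pass"), note = "")
  })
  do.call(rbind, rows)
}
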