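#' Deviance information criterion
#'
#' `DIC = Dbar + pD`, where `Dbar` is the posterior mean deviance
#' (`-2 * log-likelihood` averaged over draws) and the effective number of
#' parameters is `pD = Dbar - D(theta_hat)`, with the plug-in deviance
#' evaluated at the posterior mean of every scalar parameter. When the
#' posterior mean falls outside the likelihood support (possible for bounded
#' SD parameters), the variance-based fallback `pD = var(deviance) / 2` is
#' used and flagged with a warning.
#'
#' @param fit A `cea_fit` (carries its per-draw log-likelihood).
#' @return An object of class `cea_dic`: list with `dic`, `pd`,
#'   `mean_deviance`, `plugin_deviance` (NA if the fallback was used) and
#'   `method` (`"plugin"` or `"pV"`).
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "cea_fit"))
  dev <- -2 * fit$loglik
  dbar <- mean(dev)
  params <- setdiff(names(fit$draws), c("chain", "iter"))
  theta_hat <- vapply(fit$draws[params], mean, numeric(1))
  ll_hat <- log_likelihood(fit$spec, theta_hat, fit$working)
  if (is.finite(ll_hat)) {
    d_hat <- -2 * ll_hat
    pd <- dbar - d_hat
    method <- "plugin"
  } else {
    warning("posterior mean outside likelihood support; ",
            "using pV = var(deviance)/2 fallback")
    d_hat <- NA_real_
    pd <- stats::var(dev) / 2
    method <- "pV"
  }
  structure(list(dic = dbar + pd, pd = pd, mean_deviance = dbar,
                 plugin_deviance = d_hat, method = method),
            class = "cea_dic")
}

#' @export
print.cea_dic <- function(x, ...) {
  cat("DIC:", format(x$dic, digits = 6), "  (Dbar:",
      format(x$mean_deviance, digits = 6), ", pD:",
      format(x$pd, digits = 4), ",", x$method, ")\n")
  invisible(x)
}

# simulate one replicate dataset (original scales) from the parameters of a
# single draw; QALYs are replicated first and feed the cost model's centred
# QALY covariate, so the replication is of the full joint model
.simulate_replicate <- function(fit, row) {
  spec <- fit$spec
  w <- fit$working
  one_arm <- function(arm) {
    pre <- paste0("arm", arm$arm, ".")
    p <- stats::setNames(
      as.numeric(row[paste0(pre, .param_names)]), .param_names)
    eta_e <- p[["beta0"]] + p[["beta1"]] * arm$xu0 + p[["beta2"]] * arm$s
    if (spec$qaly_family == "normal") {
      we <- stats::rnorm(arm$n, eta_e, p[["sd_qaly"]])
    } else {
      mu <- stats::plogis(eta_e)
      sd_e <- pmin(p[["sd_qaly"]], 0.999 * sqrt(min(mu * (1 - mu))))
      sh <- beta_shapes(mu, sd_e)
      we <- stats::rbeta(arm$n, sh$kappa, sh$gamma)
    }
    eta_c <- p[["alpha0"]] + p[["alpha1"]] * arm$xc0 +
      p[["alpha2"]] * (we - arm$centres[["e"]]) + p[["alpha3"]] * arm$s
    wc <- switch(spec$cost_family,
      normal = stats::rnorm(arm$n, eta_c, p[["sd_cost"]]),
      gamma = {
        sr <- gamma_shape_rate(exp(pmin(pmax(eta_c, -15), 15)), p[["sd_cost"]])
        stats::rgamma(arm$n, shape = sr$shape, rate = sr$rate)
      },
      lognormal = stats::rlnorm(arm$n, eta_c, p[["sd_cost"]]))
    list(cost = wc * spec$scale_factor - w$epsilon,
         qaly = if (spec$qaly_family == "beta") we * w$horizon_max else we)
  }
  r0 <- one_arm(w$arm0)
  r1 <- one_arm(w$arm1)
  list(cost = c(r0$cost, r1$cost), qaly = c(r0$qaly, r1$qaly))
}

#' Posterior predictive checks
#'
#' Simulates replicate datasets from the fitted joint model (QALYs first,
#' which then feed the cost model's centred-QALY covariate) for a subset of
#' retained draws, and compares replicate cost statistics against the
#' observed data. The Bayesian p-value of a statistic is the fraction of
#' replicates whose statistic is greater than or equal to the observed one;
#' values near 0 or 1 flag misfit in that feature of the data.
#'
#' Default statistics: mean, SD and maximum of costs, and the proportion of
#' near-zero costs (cost at or below the continuity constant `epsilon`).
#'
#' @param fit A `cea_fit`.
#' @param n_rep Number of replicates (capped at the number of retained
#'   draws); the draws used are evenly spaced through the retained sample.
#' @param seed Seed for the replicate simulation.
#' @return An object of class `cea_ppc`: list with `checks` (data.frame
#'   `statistic`, `observed`, `p_value`) and `replicates` (data.frame of
#'   per-replicate statistics, for density-overlay style plots).
#' @export
ppc <- function(fit, n_rep = 500, seed = 1) {
  stopifnot(inherits(fit, "cea_fit"), n_rep >= 1)
  n_rep <- min(n_rep, nrow(fit$draws))
  idx <- unique(round(seq(1, nrow(fit$draws), length.out = n_rep)))
  obs_cost <- c(fit$working$arm0$wc, fit$working$arm1$wc) *
    fit$spec$scale_factor - fit$working$epsilon
  zero_thr <- fit$working$epsilon
  stat_fns <- list(
    mean_cost = mean,
    sd_cost = stats::sd,
    max_cost = max,
    prop_near_zero = function(x) mean(x <= zero_thr)
  )
  observed <- vapply(stat_fns, function(f) f(obs_cost), numeric(1))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  reps <- t(vapply(idx, function(i) {
    r <- .simulate_replicate(fit, fit$draws[i, ])
    vapply(stat_fns, function(f) f(r$cost), numeric(1))
  }, numeric(length(stat_fns))))
  p_values <- vapply(seq_along(stat_fns), function(j) {
    mean(reps[, j] >= observed[j])
  }, numeric(1))
  structure(list(
    checks = data.frame(statistic = names(stat_fns), observed = observed,
                        p_value = p_values, row.names = NULL),
    replicates = as.data.frame(reps)),
    class = "cea_ppc")
}

#' @export
print.cea_ppc <- function(x, ...) {
  cat("<cea_ppc> posterior predictive checks (", nrow(x$replicates),
      " replicates)\n", sep = "")
  print(x$checks, row.names = FALSE, digits = 4)
  invisible(x)
}
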