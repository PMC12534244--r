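#' Per-draw posterior arm means on the original scales
#'
#' For each retained draw, computes the marginal mean cost and mean QALY of
#' each arm by plug-in standardisation: the individual-level means implied by
#' the draw are evaluated at every observed covariate row of the arm and
#' averaged. Family-specific mean functions: identity (Normal), `exp`
#' (Gamma, log link) and `exp(nu + delta^2/2)` (Log-Normal, via the
#' original-scale moment back-transformation). Costs are then un-rescaled
#' (`* scale_factor - epsilon`) and Beta-family QALY means are mapped back to
#' the horizon scale (`* horizon_max`).
#'
#' @param fit A `cea_fit` from [run_mcmc()].
#' @return A data.frame with one row per draw: `cost0`, `cost1`, `qaly0`,
#'   `qaly1`.
#' @export
arm_mean_draws <- function(fit) {
  stopifnot(inherits(fit, "cea_fit"))
  spec <- fit$spec
  w <- fit$working
  one_arm <- function(arm) {
    pre <- paste0("arm", arm$arm, ".")
    g <- function(nm) fit$draws[[paste0(pre, nm)]]
    a <- cbind(g("alpha0"), g("alpha1"), g("alpha2"), g("alpha3"))
    b <- cbind(g("beta0"), g("beta1"), g("beta2"))
    xc <- rbind(1, arm$xc0, arm$xe, arm$s)
    xe <- rbind(1, arm$xu0, arm$s)
    eta_c <- a %*% xc      # draws x individuals
    eta_e <- b %*% xe
    mu_c <- switch(spec$cost_family,
                   normal = eta_c,
                   gamma = exp(eta_c),
                   lognormal = exp(eta_c + g("sd_cost")^2 / 2))
    cost <- rowMeans(mu_c) * spec$scale_factor - w$epsilon
    qaly <- if (spec$qaly_family == "beta") {
      rowMeans(stats::plogis(eta_e)) * w$horizon_max
    } else {
      rowMeans(eta_e)
    }
    list(cost = cost, qaly = qaly)
  }
  m0 <- one_arm(w$arm0)
  m1 <- one_arm(w$arm1)
  data.frame(cost0 = m0$cost, cost1 = m1$cost,
             qaly0 = m0$qaly, qaly1 = m1$qaly)
}

#' Incremental cost and QALY draws
#'
#' Pairwise differences (intervention minus control) of the per-draw arm
#' means.
#'
#' @param arm_means A data.frame as returned by [arm_mean_draws()], or any
#'   data.frame with columns `cost0`, `cost1`, `qaly0`, `qaly1` of equal
#'   length.
#' @return A data.frame with columns `delta_cost`, `delta_qaly`.
#' @export
incremental_draws <- function(arm_means) {
  need <- c("cost0", "cost1", "qaly0", "qaly1")
  if (!all(need %in% names(arm_means))) {
    stop("`arm_means` must have columns ", paste(need, collapse = ", "))
  }
  lens <- lengths(arm_means[need])
  if (length(unique(lens)) != 1) stop("unequal draw counts across arms")
  data.frame(delta_cost = arm_means$cost1 - arm_means$cost0,
             delta_qaly = arm_means$qaly1 - arm_means$qaly0)
}

#' Incremental cost-effectiveness ratio
#'
#' Ratio of posterior means, `mean(delta_cost) / mean(delta_qaly)` — the
#' single point plotted on the cost-effectiveness plane (not the mean of
#' per-draw ratios).
#'
#' @param delta_cost,delta_qaly Numeric vectors of incremental draws.
#' @return A single number; `NA` with a warning when `mean(delta_qaly)` is 0.
#' @export
icer <- function(delta_cost, delta_qaly) {
  de <- mean(delta_qaly)
  if (de == 0) {
    warning("mean incremental QALY is zero; ICER undefined")
    return(NA_real_)
  }
  mean(delta_cost) / de
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value `k`, the posterior probability that the
#' intervention is cost-effective: the fraction of draws with positive
#' incremental net monetary benefit, `k * delta_qaly - delta_cost > 0`
#' (strict inequality; ties count as not cost-effective).
#'
#' @inheritParams icer
#' @param wtp_grid Non-empty grid of willingness-to-pay values (currency per
#'   QALY); default 0 to 50,000 in steps of 100.
#' @return A data.frame with columns `wtp` and `prob`.
#' @export
ceac <- function(delta_cost, delta_qaly, wtp_grid = seq(0, 50000, by = 100)) {
  if (length(wtp_grid) == 0) stop("`wtp_grid` must be non-empty")
  if (length(delta_cost) != length(delta_qaly)) {
    stop("unequal draw counts")
  }
  prob <- vapply(wtp_grid, function(k) {
    mean(k * delta_qaly - delta_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, prob = prob)
}

#' Cost-effectiveness plane export
#'
#' Plot-ready data for a cost-effectiveness plane: the posterior cloud of
#' `(delta_qaly, delta_cost)` pairs, the fraction of draws falling below each
#' willingness-to-pay threshold line `k * delta_qaly - delta_cost = 0`
#' (identical to the CEAC value at `k`), and the ICER point.
#'
#' @inheritParams icer
#' @param thresholds Willingness-to-pay threshold lines to annotate
#'   (default £20,000 and £30,000 per QALY).
#' @return A list with `points` (data.frame `delta_qaly`, `delta_cost`),
#'   `below` (data.frame `wtp`, `fraction`) and `icer`.
#' @export
ce_plane <- function(delta_cost, delta_qaly, thresholds = c(20000, 30000)) {
  below <- ceac(delta_cost, delta_qaly, wtp_grid = thresholds)
  names(below) <- c("wtp", "fraction")
  list(points = data.frame(delta_qaly = delta_qaly, delta_cost = delta_cost),
       below = below,
       icer = icer(delta_cost, delta_qaly))
}

#' Full cost-effectiveness analysis of a fitted model
#'
#' Convenience wrapper combining [arm_mean_draws()], [incremental_draws()],
#' [icer()], [ceac()] and [ce_plane()] into one result, with posterior means
#' and equal-tailed 95% credible intervals for the arm means and increments.
#'
#' @param fit A `cea_fit`.
#' @param wtp_grid Willingness-to-pay grid for the CEAC.
#' @param thresholds Threshold lines for the CE plane.
#' @return An object of class `cea_result`: list with `arm_means` (per-draw),
#'   `increments` (per-draw), `summary` (data.frame of posterior mean and
#'   95% CrI per estimand), `icer`, `ceac`, `ce_plane`.
#' @export
cea_summary <- function(fit, wtp_grid = seq(0, 50000, by = 100),
                        thresholds = c(20000, 30000)) {
  am <- arm_mean_draws(fit)
  inc <- incremental_draws(am)
  summ_one <- function(x, name) {
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    data.frame(estimand = name, mean = mean(x), lower = q[1], upper = q[2])
  }
  summary <- rbind(
    summ_one(am$cost0, "mean_cost_control"),
    summ_one(am$cost1, "mean_cost_intervention"),
    summ_one(am$qaly0, "mean_qaly_control"),
    summ_one(am$qaly1, "mean_qaly_intervention"),
    summ_one(inc$delta_cost, "incremental_cost"),
    summ_one(inc$delta_qaly, "incremental_qaly")
  )
  structure(list(arm_means = am, increments = inc, summary = summary,
                 icer = icer(inc$delta_cost, inc$delta_qaly),
                 ceac = ceac(inc$delta_cost, inc$delta_qaly, wtp_grid),
                 ce_plane = ce_plane(inc$delta_cost, inc$delta_qaly,
                                     thresholds)),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>\n")
  print(x$summary, row.names = FALSE, digits = 4)
  cat("ICER (ratio of posterior means):", format(x$icer, digits = 5), "\n")
  invisible(x)
}
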