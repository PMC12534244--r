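#' Specify a joint cost-QALY model
#'
#' The joint density of costs and QALYs is factorised as
#' `p(c, e) = p(c | e) p(e)`. Three cost families are supported for
#' `p(c | e)` — Normal (identity link), Gamma (log link) and Log-Normal
#' (linear predictor on the log-scale mean) — and two QALY families for
#' `p(e)` — Normal (identity link) and Beta (logit link, after rescaling
#' QALYs to (0,1) by the horizon). The covariate sets are fixed: the cost
#' linear predictor uses centred baseline cost, centred QALY and site; the
#' QALY linear predictor uses centred baseline utility and site. Arms are
#' modelled with independent parameter blocks.
#'
#' Positive-support cost families need strictly positive data, so a
#' continuity constant `epsilon` is added to all costs before fitting when
#' zero costs are present (the conventional choice is 1 currency unit).
#' Costs are also divided by `scale_factor` (default 10) to bring costs and
#' QALYs onto more comparable scales, which helps MCMC convergence; all
#' reported results are back-transformed to the original currency.
#'
#' @param cost_family One of `"normal"`, `"gamma"`, `"lognormal"`.
#' @param qaly_family One of `"normal"`, `"beta"`. `"normal"` + `"beta"` cost
#'   is allowed (used by the simulation harness); `"normal"` cost with
#'   `"beta"` QALYs is not a supported pair.
#' @param epsilon Continuity constant added to costs before rescaling.
#'   `NULL` (default) resolves at preprocessing time to 1 if zero costs are
#'   present and the cost family has positive support, else 0.
#' @param scale_factor Positive divisor applied to costs (and the
#'   baseline-cost covariate) before fitting. Default 10.
#' @return An object of class `cea_model_spec`.
#' @export
model_spec <- function(cost_family = c("normal", "gamma", "lognormal"),
                       qaly_family = c("normal", "beta"),
                       epsilon = NULL, scale_factor = 10) {
  cost_family <- match.arg(cost_family)
  qaly_family <- match.arg(qaly_family)
  allowed <- list(c("normal", "normal"), c("gamma", "beta"),
                  c("lognormal", "beta"), c("gamma", "normal"),
                  c("lognormal", "normal"))
  ok <- any(vapply(allowed, function(p)
    identical(p, c(cost_family, qaly_family)), logical(1)))
  if (!ok) {
    stop("unsupported family pair: ", cost_family, " + ", qaly_family)
  }
  if (!is.null(epsilon)) {
    stopifnot(is.numeric(epsilon), length(epsilon) == 1, epsilon >= 0)
  }
  stopifnot(is.numeric(scale_factor), length(scale_factor) == 1,
            scale_factor > 0)
  structure(list(cost_family = cost_family, qaly_family = qaly_family,
                 epsilon = epsilon, scale_factor = scale_factor),
            class = "cea_model_spec")
}

#' @export
print.cea_model_spec <- function(x, ...) {
  cat("<cea_model_spec> cost:", x$cost_family, "| qaly:", x$qaly_family,
      "| epsilon:", if (is.null(x$epsilon)) "auto" else x$epsilon,
      "| scale_factor:", x$scale_factor, "\n")
  invisible(x)
}

#' Prior configuration
#'
#' Priors follow the mean/SD re-parameterisations: independent
#' `Normal(0, coef_sd^2)` priors on all regression coefficients and
#' `Uniform(0, upper)` priors on the standard-deviation parameters. For the
#' cost model the Uniform bound applies to the working-scale SD (`sigma_c`,
#' Normal/Gamma families) or to the log-scale SD (`delta_c`, Log-Normal
#' family) — the latter is the sensitivity knob this package exists to
#' study. For a Beta QALY family the SD is bounded by
#' `sqrt(mu_e (1 - mu_e))` (a property of the Beta distribution), so
#' `qaly_sd_upper` applies only to the Normal QALY family.
#'
#' @param cost_sd_upper Upper bound of the Uniform prior on the cost SD
#'   parameter. Conventional choices: 1000 or 10000 (Normal/Gamma, working
#'   scale); 0.8, 1, 2 or 3 (Log-Normal, log scale).
#' @param coef_sd_cost Prior SD of cost-model coefficients (default 100 on
#'   the rescaled working scale).
#' @param coef_sd_qaly Prior SD of QALY-model coefficients (default 2, a
#'   vague choice under a logit link).
#' @param qaly_sd_upper Uniform upper bound for the QALY SD under a Normal
#'   QALY family (default 1; ignored for the Beta family).
#' @return An object of class `cea_prior_config`.
#' @export
prior_config <- function(cost_sd_upper = 1000, coef_sd_cost = 100,
                         coef_sd_qaly = 2, qaly_sd_upper = 1) {
  vals <- c(cost_sd_upper, coef_sd_cost, coef_sd_qaly, qaly_sd_upper)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all prior hyperparameters must be positive and finite")
  }
  structure(list(cost_sd_upper = cost_sd_upper, coef_sd_cost = coef_sd_cost,
                 coef_sd_qaly = coef_sd_qaly, qaly_sd_upper = qaly_sd_upper),
            class = "cea_prior_config")
}

#' @export
print.cea_prior_config <- function(x, ...) {
  cat("<cea_prior_config> cost SD ~ U(0,", x$cost_sd_upper,
      "); coef SDs (cost, qaly): ", x$coef_sd_cost, ", ", x$coef_sd_qaly,
      "; qaly SD upper (normal family): ", x$qaly_sd_upper, "\n", sep = "")
  invisible(x)
}

#' Preprocess a trial dataset for model fitting
#'
#' Builds the per-arm working data: working costs `(c + epsilon) /
#' scale_factor`, working QALYs (`e / H` mapped to (0,1) for the Beta
#' family, untouched otherwise), the baseline-cost covariate on the same
#' rescaled cost scale, and per-arm centring constants for all covariates.
#' The centring constants are stored so fitted means can be back-transformed.
#'
#' @param ds A `trial_dataset`.
#' @param spec A `cea_model_spec`.
#' @return An object of class `cea_working`, a list with one entry per arm
#'   plus resolved `epsilon`, `scale_factor`, `horizon_max` and the spec.
#' @export
preprocess <- function(ds, spec) {
  stopifnot(inherits(ds, "trial_dataset"), inherits(spec, "cea_model_spec"))
  has_zero <- any(ds$data$total_cost == 0)
  positive_family <- spec$cost_family %in% c("gamma", "lognormal")
  eps <- spec$epsilon
  if (is.null(eps)) eps <- if (has_zero && positive_family) 1 else 0
  if (has_zero && positive_family && eps == 0) {
    stop("zero costs present with a positive-support cost family; ",
         "set `epsilon` > 0 (continuity correction)")
  }
  H <- ds$horizon_max
  arms <- lapply(c(0, 1), function(a) {
    d <- ds$data[ds$data$arm == a, ]
    wc <- (d$total_cost + eps) / spec$scale_factor
    we <- if (spec$qaly_family == "beta") d$qaly / H else d$qaly
    bc <- d$baseline_cost / spec$scale_factor
    centres <- c(c0 = mean(bc), e = mean(we), u0 = mean(d$baseline_utility),
                 s = mean(d$site))
    list(arm = a, n = nrow(d), wc = wc, we = we,
         xc0 = bc - centres[["c0"]], xe = we - centres[["e"]],
         xu0 = d$baseline_utility - centres[["u0"]], s = d$site,
         centres = centres)
  })
  names(arms) <- c("arm0", "arm1")
  structure(list(arm0 = arms$arm0, arm1 = arms$arm1, epsilon = eps,
                 scale_factor = spec$scale_factor, horizon_max = H,
                 spec = spec),
            class = "cea_working")
}

# canonical per-arm parameter names
.param_names <- c("alpha0", "alpha1", "alpha2", "alpha3",
                  "beta0", "beta1", "beta2", "sd_cost", "sd_qaly")

#' Linear predictors for one arm
#'
#' Computes the cost-scale and QALY-scale linear predictors
#' `eta_c = alpha0 + alpha1 (c0 - c0bar) + alpha2 (e - ebar) + alpha3 s` and
#' `eta_e = beta0 + beta1 (u0 - u0bar) + beta2 s` for every row of a working
#' arm. Interpretation depends on the link: identity (Normal mean), log
#' (Gamma mean), log-scale mean (Log-Normal `nu`), logit (Beta mean).
#'
#' @param params Named numeric vector with elements `alpha0..alpha3`,
#'   `beta0..beta2` (and optionally `sd_cost`, `sd_qaly`, ignored here).
#' @param arm One arm element of a `cea_working` object.
#' @return A list with vectors `eta_c` and `eta_e`.
#' @export
linear_predictors <- function(params, arm) {
  p <- params
  eta_c <- p[["alpha0"]] + p[["alpha1"]] * arm$xc0 +
    p[["alpha2"]] * arm$xe + p[["alpha3"]] * arm$s
  eta_e <- p[["beta0"]] + p[["beta1"]] * arm$xu0 + p[["beta2"]] * arm$s
  list(eta_c = eta_c, eta_e = eta_e)
}

# log-likelihood contribution of one arm; returns -Inf (never an error) when
# the parameter value leaves the likelihood support (e.g. Beta SD bound).
.loglik_arm <- function(spec, p, arm) {
  if (!all(.param_names %in% names(p))) {
    stop("params must contain: ", paste(.param_names, collapse = ", "))
  }
  eta <- linear_predictors(p, arm)
  sd_c <- p[["sd_cost"]]; sd_e <- p[["sd_qaly"]]
  if (!is.finite(sd_c) || !is.finite(sd_e) || sd_c <= 0 || sd_e <= 0) {
    return(-Inf)
  }
  ll_c <- switch(spec$cost_family,
    normal = sum(stats::dnorm(arm$wc, eta$eta_c, sd_c, log = TRUE)),
    gamma = {
      mu <- exp(pmin(pmax(eta$eta_c, -15), 15))
      sr <- gamma_shape_rate(mu, sd_c)
      sum(stats::dgamma(arm$wc, shape = sr$shape, rate = sr$rate, log = TRUE))
    },
    lognormal = sum(stats::dlnorm(arm$wc, eta$eta_c, sd_c, log = TRUE))
  )
  ll_e <- if (spec$qaly_family == "normal") {
    sum(stats::dnorm(arm$we, eta$eta_e, sd_e, log = TRUE))
  } else {
    mu <- stats::plogis(eta$eta_e)
    if (any(sd_e^2 >= mu * (1 - mu))) return(-Inf)
    sh <- beta_shapes(mu, sd_e)
    sum(stats::dbeta(arm$we, sh$kappa, sh$gamma, log = TRUE))
  }
  total <- ll_c + ll_e
  if (is.nan(total)) -Inf else total
}

#' Joint log-likelihood
#'
#' Sum over individuals and arms of `log p(c | e) + log p(e)`, with each arm
#' using its own parameter block. Returns `-Inf` rather than raising when a
#' parameter value leaves the likelihood support (e.g. the Beta SD bound
#' `sigma_e^2 < mu_ei (1 - mu_ei)` fails for some individual).
#'
#' @param spec A `cea_model_spec`.
#' @param params Named numeric vector with per-arm parameters prefixed
#'   `arm0.` and `arm1.` (e.g. `arm0.alpha0`, `arm1.sd_cost`), or a list
#'   `list(arm0 = ..., arm1 = ...)` of named vectors.
#' @param working A `cea_working` object from [preprocess()].
#' @return A single number (possibly `-Inf`).
#' @export
log_likelihood <- function(spec, params, working) {
  stopifnot(inherits(working, "cea_working"))
  if (!identical(spec$cost_family, working$spec$cost_family) ||
      !identical(spec$qaly_family, working$spec$qaly_family)) {
    stop("`spec` does not match the spec used to build `working`")
  }
  pl <- .split_params(params)
  .loglik_arm(spec, pl$arm0, working$arm0) +
    .loglik_arm(spec, pl$arm1, working$arm1)
}

.split_params <- function(params) {
  if (is.list(params) && !is.null(params$arm0)) return(params)
  nm <- names(params)
  list(arm0 = stats::setNames(params[startsWith(nm, "arm0.")],
                              sub("^arm0\\.", "", nm[startsWith(nm, "arm0.")])),
       arm1 = stats::setNames(params[startsWith(nm, "arm1.")],
                              sub("^arm1\\.", "", nm[startsWith(nm, "arm1.")])))
}

#' Joint log-prior
#'
#' Sum of `Normal(0, coef_sd^2)` log-densities for the regression
#' coefficients and `Uniform(0, upper)` log-densities for the SD parameters
#' of both arms; `-Inf` outside any Uniform support. For a Beta QALY family
#' the SD bound is `sqrt(mu_e (1 - mu_e))` evaluated at the arm-level mean
#' (covariates at their arm means), using the stored site mean when
#' `working` is supplied and 0 otherwise.
#'
#' @inheritParams log_likelihood
#' @param priors A `cea_prior_config`.
#' @param working Optional `cea_working`; used only for the Beta QALY SD
#'   bound's site mean.
#' @return A single number (possibly `-Inf`).
#' @export
log_prior <- function(spec, params, priors, working = NULL) {
  stopifnot(inherits(spec, "cea_model_spec"),
            inherits(priors, "cea_prior_config"))
  pl <- .split_params(params)
  lp_arm <- function(p, arm) {
    coefs_c <- p[c("alpha0", "alpha1", "alpha2", "alpha3")]
    coefs_e <- p[c("beta0", "beta1", "beta2")]
    lp <- sum(stats::dnorm(coefs_c, 0, priors$coef_sd_cost, log = TRUE)) +
      sum(stats::dnorm(coefs_e, 0, priors$coef_sd_qaly, log = TRUE))
    if (p[["sd_cost"]] <= 0 || p[["sd_cost"]] >= priors$cost_sd_upper) {
      return(-Inf)
    }
    lp <- lp - log(priors$cost_sd_upper)
    if (spec$qaly_family == "normal") {
      upper_e <- priors$qaly_sd_upper
    } else {
      sbar <- if (!is.null(arm)) arm$centres[["s"]] else 0
      mu_bar <- stats::plogis(p[["beta0"]] + p[["beta2"]] * sbar)
      upper_e <- sqrt(mu_bar * (1 - mu_bar))
    }
    if (p[["sd_qaly"]] <= 0 || p[["sd_qaly"]] >= upper_e) return(-Inf)
    lp - log(upper_e)
  }
  lp_arm(pl$arm0, if (is.null(working)) NULL else working$arm0) +
    lp_arm(pl$arm1, if (is.null(working)) NULL else working$arm1)
}
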