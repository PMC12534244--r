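#' MCMC configuration
#'
#' Chain protocol for posterior sampling. The production default matches the
#' convention of running two chains of 52,000 iterations each, discarding the
#' first 2,000 as burn-in and thinning by 10, which retains
#' `2 * (52000 - 2000) / 10 = 10000` draws for inference. Tests and the
#' simulation harness use shorter protocols (see [mcmc_config_test()]).
#'
#' @param n_chains Number of chains (default 2).
#' @param n_iter Total iterations per chain, including burn-in.
#' @param n_burnin Burn-in iterations discarded per chain (includes the
#'   sampler's adaptation phase).
#' @param thin Thinning interval; `(n_iter - n_burnin)` must be divisible by
#'   `thin`.
#' @param seed Master seed; chain `c` of arm `a` uses a seed derived
#'   deterministically from it, so identical inputs give identical draws.
#' @param rhat_threshold Convergence threshold on the split R-hat
#'   (default 1.05).
#' @return An object of class `cea_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2, n_iter = 52000, n_burnin = 2000,
                        thin = 10, seed = 1, rhat_threshold = 1.05) {
  stopifnot(n_chains >= 1, n_iter > n_burnin, n_burnin >= 0, thin >= 1,
            rhat_threshold > 1)
  if ((n_iter - n_burnin) %% thin != 0) {
    stop("(n_iter - n_burnin) must be divisible by `thin`")
  }
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed), rhat_threshold = rhat_threshold),
            class = "cea_mcmc_config")
}

#' Reduced-scale MCMC protocol
#'
#' A desk-scale protocol (2 chains of 6,000 iterations, 1,000 burn-in,
#' thinning 5, i.e. 2,000 retained draws) for tests, examples and the
#' simulation harness, where many fits are run. The full protocol of
#' [mcmc_config()] remains the production default for single analyses.
#'
#' @inheritParams mcmc_config
#' @param ... Passed on to [mcmc_config()].
#' @return An object of class `cea_mcmc_config`.
#' @export
mcmc_config_test <- function(n_iter = 6000, n_burnin = 1000, thin = 5,
                             seed = 1, ...) {
  mcmc_config(n_iter = n_iter, n_burnin = n_burnin, thin = thin, seed = seed,
              ...)
}

#' Number of retained draws implied by an MCMC configuration
#'
#' `n_chains * (n_iter - n_burnin) / thin`.
#'
#' @param cfg A `cea_mcmc_config`.
#' @return An integer.
#' @export
n_retained <- function(cfg) {
  stopifnot(inherits(cfg, "cea_mcmc_config"))
  as.integer(cfg$n_chains * (cfg$n_iter - cfg$n_burnin) / cfg$thin)
}

# classed error so the simulation harness can record sampler failures
# instead of aborting a whole study
.sampler_error <- function(message, diagnostics = NULL) {
  structure(class = c("cea_sampler_error", "error", "condition"),
            list(message = message, call = NULL, diagnostics = diagnostics))
}

# JAGS model source for one arm, given the family pair
.jags_model_string <- function(spec, qaly_normal_upper = TRUE) {
  cost_block <- switch(spec$cost_family,
    normal = "
    wc[i] ~ dnorm(eta_c[i], pow(sd_cost, -2))",
    gamma = "
    wc[i] ~ dgamma(mu_c[i] * rt[i], rt[i])
    rt[i] <- mu_c[i] / pow(sd_cost, 2)
    mu_c[i] <- exp(max(-15, min(15, eta_c[i])))",
    lognormal = "
    wc[i] ~ dlnorm(eta_c[i], pow(sd_cost, -2))")
  qaly_block <- if (spec$qaly_family == "normal") "
    we[i] ~ dnorm(eta_e[i], pow(sd_qaly, -2))" else "
    we[i] ~ dbeta(mu_e[i] * phi[i], (1 - mu_e[i]) * phi[i])
    logit(mu_e[i]) <- eta_e[i]
    phi[i] <- mu_e[i] * (1 - mu_e[i]) / pow(sd_qaly, 2) - 1
    bnd[i] <- mu_e[i] * (1 - mu_e[i])"
  qaly_sd_prior <- if (spec$qaly_family == "normal") "
  sd_qaly ~ dunif(0, qaly_upper)" else "
  sd_qaly ~ dunif(0, sqrt(min(bnd)))"
  paste0("
model {
  for (i in 1:N) {", cost_block, "
    eta_c[i] <- alpha0 + alpha1 * xc0[i] + alpha2 * xe[i] + alpha3 * s[i]",
    qaly_block, "
    eta_e[i] <- beta0 + beta1 * xu0[i] + beta2 * s[i]
  }
  alpha0 ~ dnorm(0, prec_c)
  alpha1 ~ dnorm(0, prec_c)
  alpha2 ~ dnorm(0, prec_c)
  alpha3 ~ dnorm(0, prec_c)
  beta0 ~ dnorm(0, prec_e)
  beta1 ~ dnorm(0, prec_e)
  beta2 ~ dnorm(0, prec_e)
  sd_cost ~ dunif(0, cost_upper)", qaly_sd_prior, "
}")
}

# data-driven starting values; chains are mildly dispersed around them
.jags_inits <- function(spec, priors, arm, chain, rng_seed) {
  wc <- arm$wc; we <- arm$we
  a0 <- switch(spec$cost_family,
               normal = mean(wc),
               gamma = log(mean(wc)),
               lognormal = mean(log(wc)))
  sdc0 <- switch(spec$cost_family,
                 normal = stats::sd(wc),
                 gamma = stats::sd(wc),
                 lognormal = stats::sd(log(wc)))
  sdc0 <- min(max(sdc0, 1e-3), 0.95 * priors$cost_sd_upper)
  if (spec$qaly_family == "normal") {
    b0 <- mean(we)
    sde0 <- min(max(stats::sd(we), 1e-4), 0.95 * priors$qaly_sd_upper)
  } else {
    mbar <- mean(we)
    b0 <- stats::qlogis(mbar)
    sde0 <- min(max(stats::sd(we), 1e-4), 0.5 * sqrt(mbar * (1 - mbar)))
  }
  scale <- c(1, 0.7, 1.3, 0.85)[((chain - 1) %% 4) + 1]
  list(alpha0 = a0, alpha1 = 0, alpha2 = 0, alpha3 = 0,
       beta0 = b0, beta1 = 0, beta2 = 0,
       sd_cost = sdc0 * scale, sd_qaly = sde0 * scale,
       .RNG.name = "base::Mersenne-Twister", .RNG.seed = rng_seed)
}

.fit_arm <- function(spec, priors, arm, cfg) {
  dat <- list(N = arm$n, wc = arm$wc, we = arm$we, xc0 = arm$xc0,
              xe = arm$xe, xu0 = arm$xu0, s = arm$s,
              prec_c = priors$coef_sd_cost^-2,
              prec_e = priors$coef_sd_qaly^-2,
              cost_upper = priors$cost_sd_upper)
  if (spec$qaly_family == "normal") dat$qaly_upper <- priors$qaly_sd_upper
  inits <- lapply(seq_len(cfg$n_chains), function(ch) {
    .jags_inits(spec, priors, arm, ch,
                rng_seed = cfg$seed + 1000003L * arm$arm + ch)
  })
  n_adapt <- min(1000L, max(1L, cfg$n_burnin %/% 2L))
  model_src <- .jags_model_string(spec)
  jm <- rjags::jags.model(textConnection(model_src), data = dat,
                          inits = inits, n.chains = cfg$n_chains,
                          n.adapt = n_adapt, quiet = TRUE)
  if (cfg$n_burnin > n_adapt) {
    stats::update(jm, cfg$n_burnin - n_adapt, progress.bar = "none")
  }
  sm <- rjags::coda.samples(jm, variable.names = .param_names,
                            n.iter = cfg$n_iter - cfg$n_burnin,
                            thin = cfg$thin, progress.bar = "none")
  sm
}

#' Fit a joint cost-QALY model by MCMC
#'
#' Draws from the posterior of both arms' parameter blocks using JAGS. Arms
#' share no parameters, so each arm is fitted as its own model; the retained
#' draws are combined into one chain-tagged draws table with per-arm column
#' prefixes (`arm0.`, `arm1.`). The per-draw joint log-likelihood (computed
#' with [log_likelihood()]) is attached for DIC.
#'
#' Sampler failures (e.g. a likelihood that cannot be evaluated at any
#' reachable parameter value) are raised as a classed condition
#' (`cea_sampler_error`) carrying the underlying diagnostic, so a simulation
#' harness can record the failure rather than crash.
#'
#' @param ds A `trial_dataset`.
#' @param spec A `cea_model_spec`.
#' @param priors A `cea_prior_config`.
#' @param cfg A `cea_mcmc_config`.
#' @return An object of class `cea_fit`: a list with `draws` (data.frame:
#'   `chain`, `iter`, then parameter columns), `loglik` (per-draw joint
#'   log-likelihood), `working`, `spec`, `priors`, `mcmc`.
#' @export
run_mcmc <- function(ds, spec, priors, cfg = mcmc_config()) {
  stopifnot(inherits(ds, "trial_dataset"), inherits(spec, "cea_model_spec"),
            inherits(priors, "cea_prior_config"),
            inherits(cfg, "cea_mcmc_config"))
  working <- preprocess(ds, spec)
  spec_resolved <- working$spec
  spec_resolved$epsilon <- working$epsilon
  fits <- lapply(list(working$arm0, working$arm1), function(arm) {
    tryCatch(.fit_arm(spec_resolved, priors, arm, cfg),
             error = function(e) {
               stop(.sampler_error(
                 paste0("MCMC failed for arm ", arm$arm, ": ",
                        conditionMessage(e)),
                 diagnostics = list(arm = arm$arm, cause = conditionMessage(e))))
             })
  })
  per_chain <- (cfg$n_iter - cfg$n_burnin) %/% cfg$thin
  to_matrix <- function(mcmc_list, prefix) {
    m <- do.call(rbind, lapply(mcmc_list, as.matrix))
    colnames(m) <- paste0(prefix, ".", colnames(m))
    m
  }
  draws <- cbind(to_matrix(fits[[1]], "arm0"), to_matrix(fits[[2]], "arm1"))
  chain <- rep(seq_len(cfg$n_chains), each = per_chain)
  iter <- rep(seq_len(per_chain), times = cfg$n_chains)
  loglik <- apply(draws, 1, function(row) {
    log_likelihood(spec_resolved, row, working)
  })
  fit <- structure(
    list(draws = data.frame(chain = chain, iter = iter, draws,
                            check.names = FALSE),
         loglik = loglik, working = working, spec = spec_resolved,
         priors = priors, mcmc = cfg),
    class = "cea_fit")
  fit
}

#' @export
print.cea_fit <- function(x, ...) {
  cat("<cea_fit> ", x$spec$cost_family, " cost + ", x$spec$qaly_family,
      " QALY model; ", nrow(x$draws), " retained draws (",
      x$mcmc$n_chains, " chains)\n", sep = "")
  cat("  cost SD prior: Uniform(0, ", x$priors$cost_sd_upper,
      "); epsilon = ", x$spec$epsilon, "; scale_factor = ",
      x$spec$scale_factor, "\n", sep = "")
  invisible(x)
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Each chain is split in half, and R-hat is the usual
#' `sqrt(((n-1)/n W + B/n) / W)` computed over the split halves, where `W`
#' is the mean within-half variance and `B/n` the variance of half means.
#' Values near 1 indicate the chains are mixing over the same distribution.
#'
#' @param x A numeric matrix of draws, one column per chain (iterations in
#'   rows), with at least 2 chains... a single-chain matrix is accepted since
#'   splitting yields two sequences.
#' @return R-hat as a single number, or `NA` with attribute
#'   `degenerate = TRUE` when the pooled variance is zero.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n_half <- nrow(x) %/% 2
  if (n_half < 2) stop("need at least 4 draws per chain")
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(n_half), j], x[nrow(x) - n_half + seq_len(n_half), j])
  }))
  if (stats::var(as.vector(halves)) == 0) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  w <- mean(apply(halves, 2, stats::var))
  b_over_n <- stats::var(colMeans(halves))
  if (w == 0) return(structure(NA_real_, degenerate = TRUE))
  sqrt(((n_half - 1) / n_half * w + b_over_n) / w)
}

#' Per-parameter convergence report
#'
#' Computes the split R-hat of every scalar parameter across chains and
#' flags the fit as converged when the largest R-hat is below the
#' configuration's threshold. The raw draws table of the fit (`fit$draws`)
#' doubles as trace-plot data (chain, iteration, value per parameter); see
#' [trace_data()] for a long-format export.
#'
#' @param fit A `cea_fit`.
#' @return A data.frame with columns `parameter`, `rhat`, `converged`;
#'   attribute `pass` is the overall verdict.
#' @export
convergence_report <- function(fit) {
  stopifnot(inherits(fit, "cea_fit"))
  params <- setdiff(names(fit$draws), c("chain", "iter"))
  rhats <- vapply(params, function(p) {
    m <- matrix(fit$draws[[p]], ncol = fit$mcmc$n_chains)
    as.numeric(split_rhat(m))
  }, numeric(1))
  out <- data.frame(parameter = params, rhat = rhats,
                    converged = !is.na(rhats) &
                      rhats < fit$mcmc$rhat_threshold,
                    row.names = NULL)
  attr(out, "pass") <- all(out$converged)
  out
}

#' Long-format trace data
#'
#' @param fit A `cea_fit`.
#' @return A data.frame with columns `chain`, `iter`, `parameter`, `value`,
#'   suitable for trace plots.
#' @export
trace_data <- function(fit) {
  stopifnot(inherits(fit, "cea_fit"))
  params <- setdiff(names(fit$draws), c("chain", "iter"))
  do.call(rbind, lapply(params, function(p) {
    data.frame(chain = fit$draws$chain, iter = fit$draws$iter,
               parameter = p, value = fit$draws[[p]])
  }))
}
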