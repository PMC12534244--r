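# shared fixtures, all built in code

tiny_trial_df <- function() {
  data.frame(
    id = c("p1", "p2", "p3", "p4"),
    arm = c(0, 0, 1, 1),
    baseline_cost = c(100, 150, 120, 80),
    baseline_utility = c(0.30, 0.40, 0.35, 0.45),
    site = c(0, 1, 0, 1),
    total_cost = c(250, 0, 400, 125),
    qaly = c(0.35, 0.42, 0.38, 0.44)
  )
}

# two-arm dataset with constant baseline covariates and site 0 everywhere,
# so only the intercepts and the QALY covariate carry likelihood information:
# the cost model reduces to a conjugate-style normal location problem
toy_conjugate_dataset <- function(n0 = 80, n1 = 80, mean0 = 55, mean1 = 60,
                                  sd_cost = 4, seed = 42) {
  set.seed(seed)
  one <- function(a, n, m) {
    data.frame(id = paste0("a", a, "-", seq_len(n)), arm = a,
               baseline_cost = 100, baseline_utility = 0.4, site = 0,
               total_cost = stats::rnorm(n, m, sd_cost),
               qaly = pmin(pmax(stats::rnorm(n, 0.4, 0.05), 0.02), 0.48))
  }
  trial_dataset(rbind(one(0, n0, mean0), one(1, n1, mean1)),
                horizon_max = 0.5)
}

# short chain protocol for unit tests (2 x 500 retained draws)
quick_mcmc <- function(seed = 1, n_iter = 3000, n_burnin = 500, thin = 5,
                       ...) {
  mcmc_config(n_iter = n_iter, n_burnin = n_burnin, thin = thin, seed = seed,
              ...)
}

# single-site random-walk Metropolis over the active parameters of the
# toy conjugate dataset's normal+normal model for one arm; an independent
# sampler (and independent density code) used as a brute-force oracle
oracle_mh_arm <- function(cost, qaly, n_iter = 30000, n_burnin = 5000,
                          thin = 5, seed = 7) {
  set.seed(seed)
  xe <- qaly - mean(qaly)
  n <- length(cost)
  logpost <- function(p) {
    if (p[3] <= 0 || p[3] >= 1000 || p[5] <= 0 || p[5] >= 1) return(-Inf)
    sum(dnorm(cost, p[1] + p[2] * xe, p[3], log = TRUE)) +
      sum(dnorm(qaly, p[4], p[5], log = TRUE)) +
      dnorm(p[1], 0, 100, log = TRUE) + dnorm(p[2], 0, 100, log = TRUE) +
      dnorm(p[4], 0, 2, log = TRUE) - log(1000) - log(1)
  }
  p <- c(mean(cost), 0, sd(cost), mean(qaly), sd(qaly))
  step <- c(sd(cost) / sqrt(n), sd(cost) / (sd(xe) * sqrt(n)),
            sd(cost) / sqrt(2 * n), sd(qaly) / sqrt(n),
            sd(qaly) / sqrt(2 * n)) * 2.4
  lp <- logpost(p)
  keep <- matrix(NA_real_, nrow = (n_iter - n_burnin) %/% thin, ncol = 5)
  k <- 0
  for (it in seq_len(n_iter)) {
    for (j in 1:5) {
      prop <- p
      prop[j] <- p[j] + rnorm(1, 0, step[j])
      lp_prop <- logpost(prop)
      if (log(runif(1)) < lp_prop - lp) {
        p <- prop
        lp <- lp_prop
      }
    }
    if (it > n_burnin && (it - n_burnin) %% thin == 0) {
      k <- k + 1
      keep[k, ] <- p
    }
  }
  colnames(keep) <- c("alpha0", "alpha2", "sd_cost", "beta0", "sd_qaly")
  keep
}

# arm deviance (cost | qaly model + qaly model) for the toy dataset,
# written directly against dnorm — independent of package internals
oracle_deviance_arm <- function(draws, cost, qaly) {
  xe <- qaly - mean(qaly)
  apply(draws, 1, function(p) {
    -2 * (sum(dnorm(cost, p[["alpha0"]] + p[["alpha2"]] * xe, p[["sd_cost"]],
                    log = TRUE)) +
            sum(dnorm(qaly, p[["beta0"]], p[["sd_qaly"]], log = TRUE)))
  })
}
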