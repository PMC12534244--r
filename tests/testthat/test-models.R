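test_that("preprocessing applies the continuity constant and rescaling", {
  df <- tiny_trial_df()
  ds <- trial_dataset(df)
  w <- preprocess(ds, model_spec("lognormal", "beta", epsilon = 1,
                                 scale_factor = 10))
  # row 2 (arm 0) has zero cost: (0 + 1) / 10 = 0.1
  expect_equal(w$arm0$wc[2], 0.1)
  expect_equal(w$arm0$wc[1], (250 + 1) / 10)
  # beta-family QALYs are mapped to (0, 1) by the horizon
  expect_equal(w$arm0$we, df$qaly[df$arm == 0] / 0.5)
  # identity preprocessing
  w0 <- preprocess(ds, model_spec("normal", "normal", epsilon = 0,
                                  scale_factor = 1))
  expect_equal(w0$arm1$wc, df$total_cost[df$arm == 1])
  expect_equal(w0$arm1$we, df$qaly[df$arm == 1])
  # zeros with a positive-support family and epsilon = 0 is an error
  expect_error(preprocess(ds, model_spec("lognormal", "beta", epsilon = 0)),
               "epsilon")
  # epsilon = NULL resolves to 1 when zeros are present
  w_auto <- preprocess(ds, model_spec("gamma", "beta"))
  expect_equal(w_auto$epsilon, 1)
  expect_equal(preprocess(ds, model_spec("normal", "normal"))$epsilon, 0)
})

test_that("only the supported family pairs are accepted", {
  expect_error(model_spec("normal", "beta"), "unsupported")
  expect_s3_class(model_spec("gamma", "normal"), "cea_model_spec")
  expect_s3_class(model_spec("lognormal", "beta"), "cea_model_spec")
})

test_that("linear predictors are plain affine maps of the covariates", {
  ds <- trial_dataset(tiny_trial_df())
  w <- preprocess(ds, model_spec("normal", "normal", epsilon = 0,
                                 scale_factor = 1))
  p0 <- setNames(rep(0, 9), c("alpha0", "alpha1", "alpha2", "alpha3",
                              "beta0", "beta1", "beta2", "sd_cost",
                              "sd_qaly"))
  lp <- linear_predictors(p0, w$arm0)
  expect_equal(lp$eta_c, c(0, 0))
  expect_equal(lp$eta_e, c(0, 0))
  # hand case: alpha = (1, 0.5, 0, 2), centred baseline cost 2, site 1
  arm <- list(xc0 = 2, xe = 0, xu0 = 0, s = 1, n = 1)
  p <- p0
  p[c("alpha0", "alpha1", "alpha2", "alpha3")] <- c(1, 0.5, 0, 2)
  expect_equal(linear_predictors(p, arm)$eta_c, 1 + 0.5 * 2 + 2)
  # permuting rows permutes predictors identically
  set.seed(3)
  arm_big <- list(xc0 = rnorm(10), xe = rnorm(10), xu0 = rnorm(10),
                  s = rbinom(10, 1, 0.5), n = 10)
  p[] <- rnorm(9)
  perm <- sample(10)
  lp1 <- linear_predictors(p, arm_big)
  arm_perm <- lapply(arm_big, function(x) if (length(x) == 10) x[perm] else x)
  lp2 <- linear_predictors(p, arm_perm)
  expect_equal(lp2$eta_c, lp1$eta_c[perm])
  expect_equal(lp2$eta_e, lp1$eta_e[perm])
})

test_that("normal+normal log-likelihood equals the hand-computed sum", {
  df <- data.frame(id = c("a", "b", "c", "d"), arm = c(0, 0, 1, 1),
                   baseline_cost = c(10, 20, 10, 20),
                   baseline_utility = c(0.3, 0.4, 0.3, 0.4),
                   site = c(0, 1, 0, 1),
                   total_cost = c(100, 200, 150, 250),
                   qaly = c(0.30, 0.40, 0.32, 0.42))
  ds <- trial_dataset(df)
  spec <- model_spec("normal", "normal", epsilon = 0, scale_factor = 1)
  w <- preprocess(ds, spec)
  params <- c(arm0.alpha0 = 150, arm0.alpha1 = 1, arm0.alpha2 = 50,
              arm0.alpha3 = 10, arm0.beta0 = 0.35, arm0.beta1 = 0.5,
              arm0.beta2 = 0.02, arm0.sd_cost = 40, arm0.sd_qaly = 0.05,
              arm1.alpha0 = 200, arm1.alpha1 = 0, arm1.alpha2 = 0,
              arm1.alpha3 = 0, arm1.beta0 = 0.37, arm1.beta1 = 0,
              arm1.beta2 = 0, arm1.sd_cost = 60, arm1.sd_qaly = 0.06)
  # arm 0 by hand: centres c0bar = 15, ebar = 0.35, u0bar = 0.35
  mu_c0 <- 150 + 1 * c(-5, 5) + 50 * c(-0.05, 0.05) + 10 * c(0, 1)
  mu_e0 <- 0.35 + 0.5 * c(-0.05, 0.05) + 0.02 * c(0, 1)
  ll0 <- sum(dnorm(c(100, 200), mu_c0, 40, log = TRUE)) +
    sum(dnorm(c(0.30, 0.40), mu_e0, 0.05, log = TRUE))
  ll1 <- sum(dnorm(c(150, 250), 200, 60, log = TRUE)) +
    sum(dnorm(c(0.32, 0.42), 0.37, 0.06, log = TRUE))
  expect_equal(log_likelihood(spec, params, w), ll0 + ll1, tolerance = 1e-12)
})

test_that("the beta QALY support bound returns -Inf, not an error", {
  ds <- generate_orbit_like(seed = 2)
  spec <- model_spec("lognormal", "beta")
  w <- preprocess(ds, spec)
  params <- c(arm0.alpha0 = 3, arm0.alpha1 = 0, arm0.alpha2 = 0,
              arm0.alpha3 = 0, arm0.beta0 = 1.4, arm0.beta1 = 0,
              arm0.beta2 = 0, arm0.sd_cost = 1, arm0.sd_qaly = 0.1,
              arm1.alpha0 = 3, arm1.alpha1 = 0, arm1.alpha2 = 0,
              arm1.alpha3 = 0, arm1.beta0 = 1.4, arm1.beta1 = 0,
              arm1.beta2 = 0, arm1.sd_cost = 1, arm1.sd_qaly = 0.1)
  expect_true(is.finite(log_likelihood(spec, params, w)))
  bad <- params
  bad["arm0.sd_qaly"] <- 0.6   # above sqrt(mu (1 - mu)) for every mu
  expect_identical(log_likelihood(spec, bad, w), -Inf)
})

test_that("log-prior follows the Normal + Uniform construction", {
  spec <- model_spec("normal", "normal")
  priors <- prior_config(cost_sd_upper = 1000, qaly_sd_upper = 1)
  mk <- function(sd_c, sd_e) {
    p <- setNames(rep(0, 18), c(paste0("arm0.", c("alpha0", "alpha1",
      "alpha2", "alpha3", "beta0", "beta1", "beta2", "sd_cost", "sd_qaly")),
      paste0("arm1.", c("alpha0", "alpha1", "alpha2", "alpha3", "beta0",
      "beta1", "beta2", "sd_cost", "sd_qaly"))))
    p[c("arm0.sd_cost", "arm1.sd_cost")] <- sd_c
    p[c("arm0.sd_qaly", "arm1.sd_qaly")] <- sd_e
    p
  }
  # outside the Uniform support
  expect_identical(log_prior(spec, mk(1500, 0.5), priors), -Inf)
  expect_identical(log_prior(spec, mk(500, 1.5), priors), -Inf)
  # all coefficients at 0, SDs mid-support: direct formula
  lp <- log_prior(spec, mk(500, 0.5), priors)
  expected <- 2 * (4 * dnorm(0, 0, 100, log = TRUE) +
                   3 * dnorm(0, 0, 2, log = TRUE) - log(1000) - log(1))
  expect_equal(lp, expected, tolerance = 1e-12)
  # doubling the cost bound lowers each in-support SD log-prior by log 2
  priors2 <- prior_config(cost_sd_upper = 2000, qaly_sd_upper = 1)
  expect_equal(log_prior(spec, mk(500, 0.5), priors2), lp - 2 * log(2),
               tolerance = 1e-12)
})

test_that("with vague priors the posterior mean tracks the OLS solution", {
  gen <- generate_scenario(scenario_config("gamma", p_zero = 0,
                                           n_per_arm = 150, seed = 21))
  spec <- model_spec("normal", "normal", epsilon = 0, scale_factor = 1)
  fit <- run_mcmc(gen$dataset, spec,
                  prior_config(cost_sd_upper = 10000, coef_sd_cost = 1e4),
                  quick_mcmc(seed = 4))
  w <- fit$working
  for (a in 0:1) {
    arm <- w[[paste0("arm", a)]]
    ols <- coef(lm(arm$wc ~ arm$xc0 + arm$xe + arm$s))
    cols <- paste0("arm", a, ".", c("alpha0", "alpha1", "alpha2", "alpha3"))
    post <- colMeans(fit$draws[cols])
    # agreement to 1% of the response scale, up to Monte Carlo error in the
    # posterior-mean estimate
    mcse <- vapply(cols, function(cl) {
      x <- fit$draws[[cl]]
      sd(x) / sqrt(max(coda::effectiveSize(x), 50))
    }, numeric(1))
    expect_true(all(abs(unname(post) - unname(ols)) <
                      0.01 * sd(arm$wc) + 4 * mcse))
  }
})
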