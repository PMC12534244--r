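# build a cea_fit by hand so the mean back-transformations can be checked
# against arithmetic done on paper
fake_fit <- function(ds, spec, draws_df) {
  w <- preprocess(ds, spec)
  spec$epsilon <- w$epsilon
  structure(list(draws = draws_df, loglik = rep(0, nrow(draws_df)),
                 working = w, spec = spec, priors = prior_config(),
                 mcmc = mcmc_config(seed = 1)),
            class = "cea_fit")
}

blank_draws <- function(n) {
  cols <- c(outer(c("arm0.", "arm1."),
                  c("alpha0", "alpha1", "alpha2", "alpha3", "beta0", "beta1",
                    "beta2", "sd_cost", "sd_qaly"), paste0))
  d <- as.data.frame(matrix(0, nrow = n, ncol = length(cols)),
                     optional = TRUE)
  names(d) <- cols
  d$arm0.sd_cost <- d$arm1.sd_cost <- 1
  d$arm0.sd_qaly <- d$arm1.sd_qaly <- 0.05
  cbind(data.frame(chain = 1, iter = seq_len(n)), d)
}

test_that("normal-family arm means are the rescaled intercepts when slopes vanish", {
  ds <- trial_dataset(tiny_trial_df())
  spec <- model_spec("normal", "normal", epsilon = 0, scale_factor = 10)
  d <- blank_draws(3)
  d$arm0.alpha0 <- c(10, 20, 30)
  d$arm1.alpha0 <- c(5, 5, 5)
  d$arm0.beta0 <- 0.4
  am <- arm_mean_draws(fake_fit(ds, spec, d))
  expect_equal(am$cost0, c(100, 200, 300))
  expect_equal(am$cost1, c(50, 50, 50))
  expect_equal(am$qaly0, rep(0.4, 3))
})

test_that("lognormal arm means follow the moment back-transformation", {
  ds <- trial_dataset(tiny_trial_df())
  spec <- model_spec("lognormal", "beta", epsilon = 1, scale_factor = 10)
  d <- blank_draws(1)
  d$arm0.alpha0 <- 2
  d$arm0.alpha2 <- 0.5
  d$arm0.sd_cost <- 1.5
  d$arm0.beta0 <- 1
  w <- preprocess(ds, spec)
  nu <- 2 + 0.5 * w$arm0$xe
  expected_cost0 <- mean(exp(nu + 1.5^2 / 2)) * 10 - 1
  am <- arm_mean_draws(fake_fit(ds, spec, d))
  expect_equal(am$cost0[1], expected_cost0, tolerance = 1e-12)
  # beta-family QALY mean: inverse logit, averaged, times the horizon
  expect_equal(am$qaly0[1], mean(plogis(1 + 0 * w$arm0$xu0)) * 0.5,
               tolerance = 1e-12)
})

test_that("incremental draws are pairwise differences with sort-based CrIs", {
  am <- data.frame(cost0 = c(1, 2, 3), cost1 = c(2, 4, 6),
                   qaly0 = c(0.1, 0.1, 0.1), qaly1 = c(0.1, 0.1, 0.1))
  inc <- incremental_draws(am)
  expect_equal(inc$delta_cost, c(1, 2, 3))
  expect_equal(mean(inc$delta_cost), 2)
  expect_equal(inc$delta_qaly, c(0, 0, 0))
  # identical arms give identically zero increments
  am2 <- data.frame(cost0 = 1:5, cost1 = 1:5, qaly0 = 1:5, qaly1 = 1:5)
  expect_true(all(incremental_draws(am2) == 0))
  expect_error(incremental_draws(data.frame(cost0 = 1:3, cost1 = 1:2,
                                            qaly0 = 1:3, qaly1 = 1:3)))
})

test_that("credible intervals match a brute-force sort on small draw sets", {
  # with 41 draws the 2.5% and 97.5% equal-tailed points interpolate to the
  # 2nd and 40th order statistics exactly
  set.seed(8)
  x <- rnorm(41, 100, 20)
  ds <- trial_dataset(tiny_trial_df())
  spec <- model_spec("normal", "normal", epsilon = 0, scale_factor = 1)
  d <- blank_draws(41)
  d$arm1.alpha0 <- x
  # the fake draws have zero QALY effect, so the ICER warning is expected
  res <- suppressWarnings(cea_summary(fake_fit(ds, spec, d),
                                      wtp_grid = c(0, 20000)))
  ic <- res$summary[res$summary$estimand == "incremental_cost", ]
  xs <- sort(x)
  expect_equal(ic$lower, xs[2], tolerance = 1e-12)
  expect_equal(ic$upper, xs[40], tolerance = 1e-12)
  expect_lte(ic$lower, ic$upper)
})

test_that("ICER is the ratio of posterior means", {
  expect_equal(icer(rep(100, 5), rep(0.01, 5)), 10000)
  expect_lt(icer(c(-50, -30), c(0.02, 0.04)), 0)   # dominance quadrant
  expect_warning(val <- icer(c(1, 2), c(-1, 1)), "undefined")
  expect_true(is.na(val))
})

test_that("CEAC is the net-benefit exceedance curve", {
  dc <- c(-10, 5, 20, -5)
  de <- c(0.001, 0.002, -0.001, 0.004)
  cv <- ceac(dc, de, wtp_grid = c(0, 10000))
  expect_equal(cv$prob[cv$wtp == 0], mean(dc < 0))
  expect_equal(cv$prob[cv$wtp == 10000],
               mean(10000 * de - dc > 0))
  # all effects positive: curve tends to 1
  cv2 <- ceac(rep(1, 4), rep(0.01, 4), wtp_grid = c(0, 1e7))
  expect_equal(cv2$prob, c(0, 1))
  # symmetric costs with zero effect: 0.5 at every threshold
  cv3 <- ceac(c(-3, 3, -7, 7), rep(0, 4), wtp_grid = c(0, 20000, 50000))
  expect_equal(cv3$prob, rep(0.5, 3))
  expect_error(ceac(dc, de, wtp_grid = numeric(0)), "non-empty")
  expect_true(all(ceac(dc, de)$prob >= 0 & ceac(dc, de)$prob <= 1))
})

test_that("CE-plane fractions share the CEAC definition and tie rule", {
  dc <- c(100, 600, -200)
  de <- c(0.01, 0.01, 0.01)
  cp <- ce_plane(dc, de, thresholds = c(20000, 30000))
  expect_equal(cp$below$fraction,
               ceac(dc, de, wtp_grid = c(20000, 30000))$prob)
  expect_equal(cp$icer, icer(dc, de))
  # a draw exactly on the threshold line counts as not below (strict rule)
  on_line <- ce_plane(200, 0.01, thresholds = 20000)
  expect_equal(on_line$below$fraction, 0)
  # all points below the line
  all_below <- ce_plane(rep(-1, 3), rep(0.01, 3), thresholds = 30000)
  expect_equal(all_below$below$fraction, 1)
})

test_that("posterior arm mean matches the sample mean on normal data", {
  ds <- toy_conjugate_dataset(n0 = 60, n1 = 60, mean0 = 500, mean1 = 550,
                              sd_cost = 80, seed = 12)
  spec <- model_spec("normal", "normal", epsilon = 0, scale_factor = 1)
  fit <- run_mcmc(ds, spec,
                  prior_config(cost_sd_upper = 10000, coef_sd_cost = 1e4),
                  quick_mcmc(seed = 5))
  am <- arm_mean_draws(fit)
  res <- cea_summary(fit)
  expect_s3_class(res, "cea_result")
  for (a in 0:1) {
    y <- ds$data$total_cost[ds$data$arm == a]
    draws <- am[[paste0("cost", a)]]
    ess <- max(coda::effectiveSize(draws), 100)
    expect_lt(abs(mean(draws) - mean(y)), 3 * sd(draws) / sqrt(ess) +
                0.002 * mean(y))
  }
  # delta summaries are consistent with per-arm draws, draw by draw
  expect_equal(res$increments$delta_cost, am$cost1 - am$cost0)
})
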