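---
title: "Joint Bayesian cost-effectiveness models and Uniform priors on cost standard deviations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint Bayesian cost-effectiveness models and Uniform priors on cost standard deviations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Trial-based cost-effectiveness analysis (CEA) compares two interventions by
individual-level total costs $c_i$ and quality-adjusted life years (QALYs)
$e_i$ accrued over a fixed horizon. Both outcomes are awkward for routine
Gaussian modelling: costs are non-negative, right-skewed and often contain a
spike at zero (participants who used no health care), while QALYs over a
6-month horizon are confined to $(0, 0.5)$ and left-skewed. In a Bayesian
analysis every parameter needs a prior, and when little is known the habit
is to use "minimally informative" Uniform$(0, U)$ priors on standard
deviations. This package exists to make one specific hazard reproducible and
measurable: *when costs are modelled Log-Normally, the Uniform prior on the
log-scale SD is emphatically not minimally informative on the currency
scale, and its upper bound $U$ can drive the estimated mean costs — and
hence the CEA conclusion — especially when the data contain zeros.*

## The models

All three models factorise the joint density as
$p(c, e) = p(c \mid e)\, p(e)$ and are fitted with independent parameter
blocks per trial arm (no parameters are shared across arms). The cost linear
predictor is always

$$\eta_{ci} = \alpha_0 + \alpha_1 (c_{0i} - \bar c_0) + \alpha_2 (e_i - \bar e) + \alpha_3 s_i,$$

with centred baseline cost, centred QALY and a binary site indicator, and
the QALY predictor is $\eta_{ei} = \beta_0 + \beta_1 (u_{0i} - \bar u_0) +
\beta_2 s_i$ with centred baseline utility. Covariates are centred *within
arm*.

* **Normal / Normal** — $c_i \mid e_i \sim \mathrm{N}(\eta_{ci},
  \sigma_c^2)$ and $e_i \sim \mathrm{N}(\eta_{ei}, \sigma_e^2)$; a Bayesian
  analogue of seemingly-unrelated regression and a stand-in for routine
  practice.
* **Gamma / Beta** — $c_i \mid e_i \sim
  \mathrm{Gamma}(\mu_{ci}\tau_{ci}, \tau_{ci})$ with
  $\tau_{ci} = \mu_{ci}/\sigma_c^2$ and $\log \mu_{ci} = \eta_{ci}$;
  $e_i/H \sim \mathrm{Beta}(\mu_{ei}\phi_{ei}, (1-\mu_{ei})\phi_{ei})$ with
  $\phi_{ei} = \mu_{ei}(1-\mu_{ei})/\sigma_e^2 - 1$ and
  $\mathrm{logit}\,\mu_{ei} = \eta_{ei}$. The re-parameterisations (exposed
  as `gamma_shape_rate()` and `beta_shapes()`) let priors act on the
  interpretable mean/SD scale instead of shape/rate.
* **Log-Normal / Beta** — $c_i \mid e_i \sim
  \text{Log-Normal}(\nu_{ci}, \delta_c^2)$ with $\nu_{ci} = \eta_{ci}$ the
  *log-scale* mean. Original-scale moments come from
  $\mu_{ci} = \exp(\nu_{ci} + \delta_c^2/2)$ and $\sigma_{ci} =
  \sqrt{(\mathrm e^{\delta_c^2}-1)\exp(2\nu_{ci}+\delta_c^2)}$
  (`lognormal_moments()`).

Priors: Normal$(0, 100^2)$ on cost coefficients (on the rescaled working
scale), Normal$(0, 2^2)$ on QALY coefficients (vague under a logit link),
and Uniform$(0, U)$ on the SD parameters. For the Beta QALY family the SD is
bounded by $\sqrt{\mu_e(1-\mu_e)}$ — a property of the Beta distribution —
so its Uniform prior uses that bound rather than a free $U$. The sensitivity
knob of the whole package is the cost bound: $U \in \{1000, 10000\}$ on the
working-scale SD for Normal/Gamma, and $U \in \{0.8, 1, 2, 3\}$ on the
log-scale SD $\delta_c$ for Log-Normal.

### Why the Log-Normal is special

`implied_sd_grid()` pushes a Uniform$(0, U)$ grid of $\delta_c$ values
through the moment map. With a typical cost of £400:

```{r}
library(bayescea)
implied_sd_grid(nu = log(400), upper = 3, n_grid = 6)
```

A log-scale SD of 3 implies an original-scale SD in the *millions* of
pounds: the flat prior on $\delta_c$ concentrates enormous prior mass on
currency-scale dispersion no trial could exhibit. When ~8% of costs are
zeros, the continuity correction maps them to small working values whose
logs sit far below the rest of the data, the likelihood rewards large
$\delta_c$, and the posterior mean cost $\propto \exp(\delta_c^2/2)$
inflates with whatever $U$ allows.

## Data handling

* Zero costs are incompatible with positive-support likelihoods, so a
  continuity constant $\epsilon$ (1 currency unit by default, and only when
  zeros are present) is added to *all* costs before fitting; reported means
  subtract it again. Incremental costs are essentially unaffected by this
  convention.
* Costs (and the baseline-cost covariate) are divided by `scale_factor`
  (default 10) to bring costs and QALYs onto comparable scales, which helps
  MCMC mixing; results are reported back on the original currency scale.
* Beta-family QALYs are divided by the horizon $H$ (0.5 for 6 months) to map
  them to $(0,1)$; fitted means are multiplied back by $H$. QALY values of
  exactly 0 or $H$ are rejected at validation, because the Beta likelihood
  has no mass there.
* Missing data are a hard error: the analysis contract is complete cases.

## Inference

Posterior sampling uses JAGS (via rjags) with, by default, 2 chains of
52,000 iterations, 2,000 burn-in and thinning 10 — 10,000 retained draws.
Tests, examples and the simulation harness use a reduced desk-scale protocol
(`mcmc_config_test()`: 2 × 6,000, 1,000 burn-in, thin 5, i.e. 2,000 draws),
and the heaviest checks reduce further (2 × 3,000 or 2 × 1,500); those
problem sizes are a deliberate design choice so the whole suite runs on one
CPU in minutes. Determinism is exact: chain $c$ of arm $a$ seeds JAGS's
Mersenne-Twister with a value derived from the master seed, so identical
inputs give bit-identical draws.

Two numerical guards are built into the JAGS model code rather than left to
chance:

* the log-link linear predictor of the Gamma model is clamped to
  $[-15, 15]$ before exponentiation. Under Normal$(0, 100^2)$ coefficient
  priors the adaptation phase can otherwise propose predictors whose
  exponential overflows and aborts sampling. The clamp binds only where the
  working-scale mean would exceed $e^{15}$ (about £33 million after
  rescaling) — a region of essentially zero posterior mass;
* the Beta QALY SD prior is Uniform$(0, \sqrt{\min_i \mu_{ei}(1-\mu_{ei})})$
  with the minimum taken over individuals at the current coefficient values.
  This enforces the likelihood-support restriction exactly inside the
  sampler, so Beta shape parameters can never go negative. The R-side
  `log_prior()` places the bound at the arm-level mean and
  `log_likelihood()` returns $-\infty$ on any individual-level violation;
  the two constructions differ only by a normalisation that is immaterial to
  every reported quantity.

Convergence is judged by the split-chain $\widehat R$ (`split_rhat()`,
threshold 1.05) on every scalar parameter; `trace_data()` exports plot-ready
chains. Fit is assessed by DIC (plug-in deviance at the posterior mean, with
a `pV = var(deviance)/2` fallback if the posterior mean leaves the
likelihood support) and by posterior predictive checks on the mean, SD,
maximum and near-zero proportion of costs, replicating the *joint* model:
QALYs are replicated first and feed the cost model's centred-QALY covariate.

## CEA outputs

`arm_mean_draws()` computes, per retained draw, the marginal mean cost and
QALY of each arm by plug-in standardisation over the arm's *observed*
covariate rows (not covariates-at-zero; for nonlinear links the two differ).
Increments are draw-by-draw differences, the ICER is the ratio of posterior
means (the single dot on a cost-effectiveness plane, not a mean of ratios),
and the CEAC at willingness-to-pay $k$ is the fraction of draws with
$k\,\Delta e - \Delta c > 0$ — strict inequality, so a draw exactly on the
threshold line counts as not cost-effective (a measure-zero event under
continuous models; the rule just makes the tie-break deterministic). The
default grid runs £0–£50,000 in £100 steps, bracketing the conventional
£20,000–£30,000 thresholds. Credible intervals are equal-tailed 2.5/97.5
percentiles throughout.

## Synthetic data

Because the motivating trial's data are not public, the package generates
its own:

* `generate_orbit_like()` builds a synthetic case-study fixture: 71 control
  and 62 intervention participants; zero-cost *counts* fixed by construction
  at 6 and 5 (8.45% and 8.06%) so prior sweeps are stable across seeds;
  positive costs Log-Normal with roughly 95% below £2000 and a heavy right
  tail; QALYs $0.5 \times \mathrm{Beta}(12, 3)$, concentrated in
  $(0.3, 0.5)$ and never reaching the horizon. These choices were calibrated
  once to the observable scale of the case study (arm mean costs of roughly
  £480–£710 under robust models, QALYs near 0.4).
* `generate_scenario()` implements the two-part simulation DGP: QALYs
  Normal (truncated to the horizon by rejection; negligible rejection rate
  at the defaults), a Bernoulli zero mass with probability `p_zero`
  independent of covariates, and a Gamma or Log-Normal positive part
  moment-matched to an individual mean that shifts with the QALY
  (`cost_qaly_slope`, default −£500/QALY, floored at £1 if a shift drives it
  non-positive). Defaults: positive-part means £500/£650, SDs 1.5 × mean
  (right-skewed), QALY means 0.40/0.41 with SD 0.05, 100 or 1000 per arm,
  `p_zero` 0 or 0.10. The stored estimand truth is the arm mean *including*
  the zero mass, $(1 - p_{\text{zero}}) \cdot \text{mean}$.

What the generator deliberately does **not** emulate: longitudinal
visit-level accrual, missingness, covariate-dependent zero mass, utility
tariffs, and any claim of numeric equality with the original trial. Passing
tests therefore demonstrate the *mechanisms* (prior-bound sensitivity,
zero-induced misfit) on data with the right structure and scale — not a
re-analysis of the trial.

## The simulation harness

`study_plan()` crosses the eight scenarios (2 families × 2 zero levels × 2
sample sizes) with the default model grid (Normal and Gamma with
$U \in \{1000, 10000\}$; Log-Normal with $U \in \{0.8, 1, 2, 3\}$; Normal
QALY component throughout) and `run_study()` measures bias, empirical SE
(divisor $R-1$) and RMSE of the posterior-mean estimates against the stored
truth, with Monte Carlo SEs; the identity
$\mathrm{RMSE}^2 = \mathrm{bias}^2 + \mathrm{EmpSE}^2 (R-1)/R$ holds exactly
by construction. Replicates whose fit fails or whose maximum
$\widehat R \ge 1.05$ are excluded and counted, never fatal. Costs are *not*
rescaled in the harness — rescaling would distort the relationship between
the data scale and the prior bound under study — and $\epsilon = 1$ is
applied per fit only when the replicate actually contains zeros.

Two harness design choices deserve a note:

* **Coefficient prior vagueness.** Because harness costs stay on the raw £
  scale, Normal$(0, 100^2)$ coefficient priors would *not* be vague there
  (they visibly shrink a £500 intercept at $n = 100$). The harness default
  is `coef_sd_cost = 1000`, which carries the same vagueness as
  Normal$(0, 100^2)$ does on a ÷10 working scale.
* **SD prior bounds can bind.** With SDs of 1.5 × mean, the intervention
  arm's true cost SD (£975) sits just below the conventional
  $U = 1000$ bound, and the truncation alone induces visible downward bias
  in the Gamma model's estimates; $U = 10000$ removes it. This is the same
  lesson as the headline finding, in a milder form: a Uniform bound close to
  the truth is an informative prior. The unbiasedness checks therefore use
  the non-binding bound.

Point estimates are posterior means (switch to medians by post-processing
`arm_mean_draws()` output if desired); whether the original analyses used
means or medians for bias is not stated anywhere we can check, and means
match the tabulated cost estimates.

## Worked example

```{r}
library(bayescea)

ds <- generate_orbit_like(seed = 1)
summarise_dataset(ds)

sweep <- sensitivity_sweep(ds, "lognormal", c(0.8, 1, 2, 3),
                           mcmc = mcmc_config_test(seed = 1))
sweep[, c("cost_sd_upper", "dic", "cost0", "cost1", "incremental")]

fit <- run_mcmc(ds, model_spec("gamma", "beta"),
                prior_config(cost_sd_upper = 1000),
                mcmc_config_test(seed = 1))
cea_summary(fit)
dic(fit)
ppc(fit, n_rep = 300)
```

## Known limitations

* The Beta QALY SD bound couples the SD prior to the coefficients; its
  normalisation differs slightly between the sampler (min over individuals)
  and the exposed `log_prior()` (arm-level mean). Neither affects reported
  estimands.
* DIC's plug-in deviance follows the posterior-mean convention; for
  strongly skewed SD posteriors the pV fallback can give different effective
  parameter counts.
* The ICER is undefined at $\overline{\Delta e} = 0$ and returned as `NA`
  with a warning rather than a signed infinity.
* Two-part (hurdle) *fitting* models are out of scope: the package
  quantifies the damage zeros do to single-part models, it does not provide
  the remedy.
* `run_study()` is sequential; very large plans should rely on the
  per-replicate cache (`cache_dir`) and multiple invocations.
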