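---
title: "Model-informed Bayesian extrapolation of treatment effects in myasthenia gravis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-informed Bayesian extrapolation of treatment effects in myasthenia gravis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Placebo-controlled trials in generalised myasthenia gravis (gMG) typically
run a 12-week double-blind period, after which control patients cross over
to active drug in an open-label extension. Treated patients are observed
through week 24 and beyond, but there is no randomised control arm past
week 12: a direct 24-week placebo-controlled contrast on the MG-ADL
(0–24, higher = worse) or QMG (0–39) scales cannot be estimated from the
trial alone.

`mgborrow` implements a two-part Bayesian analysis that fills the gap with
external control information:

* **Part 1** synthesises aggregate control-arm change-from-baseline (CFB)
  summaries — least-squares means and standard errors per visit, extracted
  from published placebo arms and from external individual-patient sources
  summarised in-package — through a meta-regression on log time, and
  moment-matches the posterior of the control trajectory parameters into a
  bivariate normal prior.
* **Part 2** fits a Bayesian random-intercept regression on log time to
  the trial's individual patient data, placing that prior — down-weighted
  by a borrowing weight — on the control intercept and slope. The
  posterior yields predicted trajectories through week 24, the
  treated-minus-control difference with 95% credible intervals, and the
  posterior probabilities that define the clinical conclusions.

## Part 1: control meta-regression

Observed aggregate means $y_{st}$ for source $s$ at week $t$ follow

$$y_{st} \sim N(\mu_0 + a_s + \mu_1 \ln t,\; \mathrm{se}_{st}^2), \qquad
  a_s \sim N(0, \tau^2),$$

a measurement-error meta-regression with source random intercepts.
Hyperpriors are weakly informative on the score scale:
$\mu_0, \mu_1 \sim N(0, 10^2)$ and $\tau \sim$ half-normal$(0, 2)$. Log
time is the natural logarithm and is left uncentred, so $\mu_0$ is the
control mean CFB at week 1 and has a fixed interpretation across the
package. With a single source the intercept offset is confounded with
$\mu_0$; `fit_control_metareg()` then fixes $\tau = 0$ and says so.

Published sources are usable directly; external individual-patient
sources first pass through comparability preparation:

* **Censoring** (`apply_censoring()`): visits within 26 weeks after a
  thymectomy and within 4 weeks after rescue therapy are removed, as are
  source-specific lead-in windows (13 weeks for a prednisone-monotherapy
  cohort, 52 weeks for a thymectomy cohort). Months convert to weeks at
  3 = 13, 6 = 26, 12 = 52 — a fixed deterministic rule. Two re-baselining
  modes exist: `first_surviving` re-anchors CFB at the first surviving
  scored visit (the anchor row is kept, flagged, and excluded from fits);
  `original` keeps the recorded baseline. The pipeline default is
  `original`, because the synthetic registry records a genuine week-0
  baseline; `first_surviving` is for sources whose pre-censoring baseline
  is not usable.
* **Odds weighting** (`fit_propensity()`, `compute_odds_weights()`): a
  logistic model of trial membership on baseline MG-ADL and QMG gives
  each external patient the weight $w_i = p_i/(1-p_i)$, re-targeting the
  external pool at the trial population; trial patients keep weight 1.
  Weights are used unnormalised (rescaling would not change weighted
  means) and the Kish effective sample size $(\sum w)^2/\sum w^2$ is
  reported. Patients missing either baseline are excluded and counted.
* **Weighted MMRM** (`fit_weighted_mmrm()`): CFB on categorical visit
  plus centred baseline with an unstructured visit covariance; each
  patient's multivariate-normal log-likelihood is multiplied by $w_i$,
  and patients missing visits contribute the marginal of their observed
  visits (monotone missingness, missing at random). The optimizer is
  quasi-Newton (L-BFGS-B) on the Cholesky factor of the covariance with
  log diagonal, fixed effects profiled out by weighted GLS at each step,
  relative tolerance `1e-8`, at most 500 iterations, and diagonal floor
  `1e-4` so degenerate (noise-free) inputs stop cleanly at the boundary.
  Maximum likelihood is the default — REML's implicit degrees-of-freedom
  correction is not well defined under non-integer weights — with a
  REML-style adjustment available. Standard errors are model-based
  (information matrix), because Part 1 consumes them as measurement-error
  SDs. `aggregate_from_fit()` emits one aggregate row per visit up to
  week 28, with the ESS as the row's `n`.

## The borrowing prior

`moment_match_prior()` converts Part-1 draws of $(\mu_0, \mu_1)$ into a
bivariate normal. `downweight_prior()` implements the normal-theory power
prior: borrowing weight $w \in (0, 1]$ inflates the covariance by $1/w$
with the mean unchanged, so the main analysis' "30% down-weighting"
multiplies every covariance entry by $10/7$. Weight 0 returns the
configured vague prior — mean zero, independent components with variance
$10^4$ — which corresponds to discarding the external information
entirely. Down-weighting composes multiplicatively ($w_1$ then $w_2$
equals $w_1 w_2$), which the tipping-point machinery relies on.

## Part 2: combined individual-patient model

With $z_i$ the treated indicator, $b_i$ baseline score and
$\mathrm{period}_{ij}$ the open-label flag,

$$\mathrm{cfb}_{ij} \sim N\!\big(\beta_{0c} + \beta_{1c}\ln t_{ij}
  + z_i(\delta_0 + \delta_1 \ln t_{ij}) + \gamma (b_i - \bar b)
  + \eta\,\mathrm{period}_{ij} + u_i,\; \sigma_e^2\big), \quad
  u_i \sim N(0, \sigma_u^2).$$

The Part-1 prior lands on $(\beta_{0c}, \beta_{1c})$; the remaining fixed
effects get $N(0, 10^2)$ and the two SDs half-normal$(0, 5)$ — weakly
informative on scales where scores span at most 39 points. The week-24
control prediction $\beta_{0c} + \beta_{1c}\ln 24$ rests on the log-time
extrapolation plus the prior, which is exactly the design intent: control
data stop at week 12.

Sampling is Gibbs (JAGS) with the random intercepts hierarchically
centred — the naive parameterization left the intercept-like parameters
with split-$\hat R$ near 1.4 at practical chain lengths, while centring
brings all monitored parameters near 1. Defaults are 4 chains of 1000
warmup plus 1000 kept draws; every chain's RNG stream is derived from the
configured seed, so all fits are exactly reproducible. Convergence is
flagged from split-$\hat R$ (classic Gelman–Rubin on split half-chains,
floored at 1 since values below 1 are estimator noise) at 1.01 for the
Part-1 parameters and 1.05 for the larger Part-2 models, with
`mcmc_diagnostics()` reporting per-parameter values and effective draws.

**Intercurrent events.** Before fitting, `impute_intercurrent()` applies
the trial estimand: rescue therapy, myasthenic crisis and death are
treatment failures, and every visit at or after the first event is set to
the worse of the baseline and the last pre-event score (so imputed CFB is
never an improvement). A post-hoc conservative variant imputes death as
the instrument maximum (24 or 39). All other monotone missingness is left
to the likelihood under missing at random.

**Emax variant.** `fit_combined_emax()` swaps the log-linear mean for a
per-arm saturating curve $E_{\max,g}\, t/(t_{50,g} + t)$, used to check
that an early response plateau does not distort the week-24 contrast. An
informative prior cannot be placed on $(E_{\max}, t_{50})$ directly, so
it is transferred by two-point matching: the control curve evaluated at
weeks 1 and 24 receives the bivariate normal implied by the Part-1 prior
under the linear map $A = \binom{1\ \ 0}{1\ \ \ln 24}$, entering the
model as a pseudo-likelihood. Weeks 1 and 24 were chosen because they are
the anchor of the intercept's interpretation and the estimand week;
$t_{50}$ is constrained positive.

## Estimands

`predict_trajectory()` evaluates the arm mean functions per draw at the
pooled mean baseline and the double-blind period reference, summarised by
the posterior mean and an equal-tailed 95% credible interval — the
conventional reading of a two-sided interval; highest-density intervals
differ only for skewed posteriors and are not used.
`treatment_effect_summary()` reports, at an assessment week (12 and 24 by
convention), the posterior mean difference, its interval, the probability
of improvement $P(\Delta < 0)$ (strict inequality; the boundary has
measure zero under a continuous posterior), the probability of a
clinically meaningful effect $P(\Delta \le -2)$ for MG-ADL or
$P(\Delta \le -3)$ for QMG, and $p = P(\Delta \ge 0)$, the posterior
probability of a worsened-or-similar effect. `tipping_point_sweep()`
refits Part 2 along a borrowing-weight grid (0 to 1) with identical
sampler settings and seed, so the weight that would overturn a conclusion
is directly visible and the weight-0 row equals a vague-prior run
exactly.

## The synthetic-data generator

No individual patient data from the underlying trials or registries are
public, so `sim_config()` / `simulate_trial_ipd()` /
`simulate_external_ipd()` / `simulate_aggregate_sources()` generate data
with the structure the analysis assumes, and their defaults are the
package's fixed emulation of the study conditions:

* trial baseline MG-ADL $\sim N(10.6, 3.5^2)$ (placebo-arm moments) and
  QMG $N(19.3, 4.4^2)$; the registry-like external population is milder,
  $N(8.2, 2.4^2)$ MG-ADL and $N(14.8, 4.4^2)$ QMG, giving the
  baseline-distribution shift that the odds weighting must correct;
* control trajectory $\mu_0 = -1.0$, $\mu_1 = -0.31$ points per log week,
  reproducing the published predicted control CFB scale (about $-1.8$ at
  week 12 and $-2.0$ at week 24); treatment contrasts
  $\delta_0 = -1.5$, $\delta_1 = -0.33$, giving latent differences of
  about $-2.3$ and $-2.55$ points at weeks 12 and 24;
* random-intercept SD 2.5 and residual SD 2.0 points, a marginal CFB SD
  near the 3.7 points used in the published power calculation;
  baseline-covariate coefficient 0.1; per-week intercurrent-event and
  dropout hazards 0.005 each, small but non-zero so the estimand
  machinery is always exercised; 100 patients per arm, visits at weeks
  1, 2, 4, 8, 12, 16, 20, 24 with the open-label switch after week 12.

Scores are continuous Gaussians clamped to the instrument range, with CFB
recomputed after clamping so `cfb = score - baseline` always holds.
Control trial patients contribute nothing after week 12, post-event trial
visits are retained with missing scores for the imputation rule, and
registry rescue events keep their scores (censoring, not imputation,
handles them).

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: integer-valued item-sum
scores and their floor effects; visit-window jitter and irregular
registry schedules; informative (non-MAR) dropout; correlation between
the two instruments beyond a single shared baseline factor; secular or
centre effects in registry data; and any deviation of the true control
trajectory from log-linearity, which is precisely the assumption the
borrowing rests on. One consequence worth noting: the treatment-policy
imputation genuinely attenuates the week-24 difference relative to the
latent $-2.55$ (failure visits revert toward baseline), so pipeline
estimates at the default hazards sit nearer $-2$; with hazards at zero
the model recovers the latent contrast without bias, which the test suite
checks.

## Numerical and design choices

* Natural log of time throughout; week 0 is baseline, response visits
  start at week 1 so $\ln t \ge 0$.
* Power-prior down-weighting by covariance inflation $1/w$ — for normal
  likelihoods this is exactly the power prior, and it keeps the tipping
  grid interpretable as a fraction of external information retained.
* Part-2 informative prior placed on (intercept, slope) rather than on
  predicted means at reference weeks; the two are linearly equivalent
  for the log-linear model, and the chosen form keeps the prior's
  parameters interpretable.
* MMRM: ML default, model-based SEs, Cholesky parameterization,
  boundary-stop treated as convergence only when covariance diagonals pin
  at the floor (degenerate data).
* Single-arm Part-2 input drops the treatment contrasts automatically,
  enabling the reduced conjugate settings used for validation.
* CSV dialect: comma-separated UTF-8, header required, empty string for
  absent values; instrument ranges enforced at I/O.

## Validation strategy and problem sizes

The test suite validates every stage against an independent route:
weighted least-squares normal equations for single-visit MMRM fits,
noise-free exact recovery for the generators and the MMRM, closed-form
Bayesian linear-regression posteriors for both MCMC stages in reduced
conjugate settings (within Monte Carlo standard error), parameter
recovery and interval coverage on replicated synthetic data, and exact
worked fixtures for the imputation rule. Simulation sizes were chosen as
the smallest that make each check statistically sharp: n = 2000 per arm
for law-of-large-numbers checks on the generator, n = 500 per arm over
10 replicates for effect recovery (±0.4 points), n = 150 per arm over 20
replicates for 95%-interval coverage (≥16/20), and 4 × 1000 draws for
the conjugate-equivalence checks.

## Limitations

The exact likelihoods of the original two-part analysis are described
only at the level reconstructed here; residual covariance in Part 2 is
compound-symmetric (random intercept), with unstructured alternatives
left to the MMRM stage. The odds-weighting estimand matches the textbook
treat-the-trial-as-target formulation, which need not equal every
variant in use. Tipping results are Monte Carlo quantities: at short
chain lengths adjacent grid points can cross within simulation error even
though the underlying map is monotone.
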