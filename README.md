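# mgborrow

Bayesian borrowing and extrapolation of treatment effects in myasthenia
gravis trials.

## What problem this solves

Placebo-controlled trials in generalised myasthenia gravis run a 12-week
double-blind period; control patients then cross over to active drug.
Treated patients are followed to week 24, but no randomised control data
exist past week 12, so a 24-week placebo-controlled treatment effect on
the MG-ADL (0–24) or QMG (0–39) scale cannot be estimated from the trial
alone. `mgborrow` is for trial statisticians and methods researchers who
need that late contrast: it borrows external control information through
a two-part Bayesian model and quantifies how much the conclusion depends
on the borrowing.

**Part 1** — control meta-regression on aggregate external summaries
$y_{st}$ (mean change from baseline of source $s$ at week $t$, with
standard error):

$$y_{st} \sim N(\mu_0 + a_s + \mu_1 \ln t,\ \mathrm{se}_{st}^2),
\qquad a_s \sim N(0, \tau^2).$$

The posterior of $(\mu_0, \mu_1)$ is moment-matched to a bivariate
normal and down-weighted as a normal power prior: borrowing weight $w$
inflates the covariance by $1/w$ (the default $w = 0.7$ is a 30%
down-weighting; $w = 0$ is the vague prior).

**Part 2** — combined individual-patient model with that prior on the
control trajectory:

$$\mathrm{cfb}_{ij} \sim N\big(\beta_{0c} + \beta_{1c}\ln t_{ij}
 + z_i(\delta_0 + \delta_1\ln t_{ij}) + \gamma(b_i-\bar b)
 + \eta\,\mathrm{period}_{ij} + u_i,\ \sigma_e^2\big),
 \qquad u_i \sim N(0,\sigma_u^2).$$

Intercurrent events (rescue, myasthenic crisis, death) are imputed as
treatment failure first — the worse of baseline and the last pre-event
score. The package reports predicted trajectories with 95% credible
intervals, the week-12/24 treated-minus-control difference
$\Delta = \delta_0 + \delta_1 \ln t$, the posterior probabilities
$P(\Delta<0)$, $P(\Delta \le -2)$ (MG-ADL; $-3$ for QMG) and
$p = P(\Delta \ge 0)$, and a tipping-point sweep of the borrowing weight
from 0 to 1. External individual-patient sources are prepared by
censoring rules (post-thymectomy, post-rescue, source lead-in), logistic
propensity odds weighting on baseline MG-ADL and QMG, and an
IPTW-weighted MMRM with unstructured covariance that converts them into
aggregate Part-1 rows. Because no patient-level data from the underlying
trials and registries are public, a synthetic-data module generates
trial, registry and aggregate inputs with the assumed structure.

## Worked example

```r
library(mgborrow)

# design power for the pivotal-trial assumptions
p <- power_two_arm(n_total = 156, delta = 2.3, sd = 3.7)
sprintf("power: %.3f (n per arm after attrition: %.1f)", p, attr(p, "n_per_arm"))
#> "power: 0.944 (n per arm after attrition: 66.3)"

# full two-part analysis on synthetic data at the default study conditions
cfg <- sim_config(n_per_arm = 100, seed = 1)
res <- run_pipeline(cfg, weight = 0.7,
                    mcmc = mcmc_control(chains = 2, warmup = 500,
                                        draws = 800, seed = 1))
res$prior
#> Control-trajectory prior (borrowing weight 0.7)
#>   mean: mu0 = -0.7307, mu1 = -0.4296
#>   SDs:  0.2608, 0.0763; corr -0.728
res$effects
#> Week 12 treatment difference (treated - control):
#>   mean -1.69 (95% CrI -2.32, -1.02)
#>   P(improvement) = 1.0000; P(>= 2.0-point reduction) = 0.1737; p = 0.0000
#> Week 24 treatment difference (treated - control):
#>   mean -1.76 (95% CrI -2.47, -1.04)
#>   P(improvement) = 1.0000; P(>= 2.0-point reduction) = 0.2575; p = 0.0000
res$tipping
#> Tipping-point sweep over the borrowing weight (week 24)
#>   weight    mean   lower   upper prob_favourable p
#> 1    0.0 -1.8994 -2.8409 -0.9859               1 0
#> 2    0.3 -1.7309 -2.5135 -0.9825               1 0
#> 3    0.7 -1.7576 -2.4681 -1.0376               1 0
#> 4    1.0 -1.6931 -2.3889 -0.9719               1 0
```

Reading the output: the Part-1 prior says external controls improve by
about 0.73 points by week 1 and a further 0.43 per log-week. At the main
borrowing weight the week-24 difference is −1.76 points in favour of
treatment (95% CrI −2.47 to −1.04); the posterior probability of any
improvement is ≈ 1 and of a ≥ 2-point improvement 0.26. The sweep shows
the conclusion is stable for every borrowing weight from 0 (vague prior)
to 1 (full borrowing). Estimates sit nearer −2 than the generator's
latent −2.55 because failure imputation pulls post-event visits back
toward baseline — the intended behaviour of the treatment-policy
estimand.

`predict(res$fit, weeks = 1:24)` returns the per-arm trajectories;
`mcmc_diagnostics(res$fit)` reports split R-hat and effective draws.

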