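---
title: "Comparing digital CBT module topics from daily drinking calendars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing digital CBT module topics from daily drinking calendars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Modular digital cognitive-behavioral therapy (CBT) programs for alcohol
use disorder deliver distinct skill topics — functional analysis,
assertive communication, coping with craving, cognitive restructuring,
problem solving, decision making — one module at a time over an 8-week
outpatient course. Because every participant works through (most of) the
same topics, asking *which topic is followed by the least drinking* and
*which topic patients like best* is a within-person comparison: each
participant serves as their own control. `modulewise` implements that
comparison end to end for two outcome streams:

* a **timeline-followback (TLFB) calendar** of daily drinking (1 = any
  drinking, 0 = abstinent, or missing), and
* **patient feedback forms** with six 0–4 Likert items (effectiveness,
  novelty, applicability, navigation, enjoyability, relatability) rated
  after each completed module.

## Structuring calendars into module windows

Each module completion anchors a window of the completion day plus the
six following days, mirroring the weekly rhythm of outpatient care. Three
rules keep the attribution unambiguous:

* days on or after the *next* module's completion date are not attributed
  (their outcome is set missing), so no day informs two modules;
* when two or more modules are completed on the same date, all of their
  windows are excluded outright;
* every non-excluded window keeps exactly 7 day slots — slots absent from
  the calendar, or removed by truncation, are retained as missing-outcome
  rows and imputed inside the sampler rather than dropped.

Days are classed **high-risk** when they fall on Friday–Sunday, on a
configured holiday, or the day before one. Any run of 7 consecutive days
contains exactly three weekend days, so every window carries at least 3
high-risk slots regardless of the holiday list. The holiday list itself
is configurable; the default covers the U.S. drinking-associated holidays
(New Year's Day and Eve, Memorial Day, Independence Day, Labor Day,
Thanksgiving, Christmas). The default list is a documented choice for
U.S. trial settings, and all risk classification flows through one
function (`classify_risk_day()`).

Each window also carries an indicator of **any drinking in the 7 days
before completion**, the model's autocorrelation control. When that week
is only partially observed, the default treats "observed, no drinking
seen" as 0 — discarding those windows (the strict reading) would lose
most of the sample. Both behaviours are implemented; `strict_prior_week =
TRUE` returns missing unless all 7 days are observed abstinent, and the
permissive default is the package's documented choice.

`days_since_randomization` is 0-based (0 = randomization day), a
documented origin convention.

## The two models

Both outcomes are analyzed with Bayesian mixed models for repeated
measures, sampled by MCMC (JAGS via `rjags`; the model specification —
priors, structure, missing-data handling — lives in this package, the
engine only draws samples).

**Daily drinking** (unit of analysis: one calendar day):

$$\mathrm{logit}\,P(y_{ij}=1) = \beta_0 + \beta_1 \tilde a_i + \beta_2
s_i + \beta_3 c_i + \beta_4 t_i + \beta_5 \tilde d_{ij} + \beta_6 r_{ij}
+ \beta_7 w_{ij} + u_i + a_{m(ij)} + v_{m(ij), r_{ij}}$$

with scaled age $\tilde a = (\text{age}-21)/10$, male sex $s$, ASI
alcohol composite $c$, second-trial indicator $t$, scaled time
$\tilde d = \text{days}/28$, high-risk indicator $r$, prior-week-use
indicator $w$; random intercepts $u_i$ per participant, $a_m$ per module
topic (6 levels) and $v_{m,r}$ per module-by-risk cell (12 levels).

**Feedback ratings** (unit of analysis: one item rating, treated as
continuous): the same fixed covariates without the two day-level
indicators, plus random effects for participant, module, item (6 levels)
and module-by-item cell (36 levels), with normal residuals. The analysis
grid is the *complete* participant × module × item cross; ratings never
given (module skipped, form skipped, item skipped) are missing outcomes
imputed by the sampler.

### Priors

Fixed effects get normal(0, 10^6); the linear model's residual variance
gets inverse-gamma(0.01, 0.01); every random-effect standard deviation
gets a half-t(0, 10, 3) *shrinkage* prior, one scale per grouping factor.
The shrinkage prior is what tempers multiplicity: six one-vs-rest module
hypotheses (per stratum) are tested without any post-hoc correction, and
pooling the module levels toward zero is the mechanism that keeps false
positives rare (the null-calibration test checks exactly this). Inside
the sampler the half-t is expressed as the exactly equivalent
gamma–gamma scale mixture (precision $\tau \mid a \sim$
Gamma$(\nu/2, \nu a)$, $a \sim$ Gamma$(1/2, A^{-2})$), which gives the
precision a conjugate full conditional; sampling the half-t scale
directly produced a funnel that left the module-by-risk scale with an
effective sample size well under the gate. A prior-only sampling test
confirms the mixture reproduces the half-t(0, 10, 3) margin
(Kolmogorov–Smirnov, n = 4000 draws).

### Missing data

All missingness is assumed missing-at-random and modelled jointly inside
the sampler (re-drawn every iteration, never singly imputed):

* missing binary outcomes from the Bernoulli likelihood; missing ratings
  from the normal likelihood;
* missing ASI scores from a zero-or-one inflated beta: point masses at 0
  and 1 with a beta body, mixture weights uniform on the simplex
  (Dirichlet(1,1,1)) and diffuse normals on the log beta parameters —
  the minimal standard parameterization of that family, configurable;
* missing days-since-randomization (which arise for feedback rows of
  never-completed modules) from a half-normal whose scale is fixed at
  the empirical SD of the observed scaled times;
* missing prior-week indicators from a Bernoulli with a uniform prior on
  its rate; missing age/sex (rare) from normal/Bernoulli baseline models.

### Sampling and convergence

Defaults: 4 chains with distinct seeds and initial values, 1000 warmup
iterations, 2000 retained draws per chain at thinning interval 3 —
chosen so the slowest parameter (the module-by-risk scale) clears the
convergence gate. The gate follows the rank-normalization standard:
rank-normalized split R-hat < 1.01 and bulk *and* 5%/95% tail effective
sample sizes > 400 for every monitored parameter; the pipeline withholds
contrast tables when the gate fails. The R-hat/ESS formulas (Blom-offset
fractional ranks, folded statistic, FFT autocovariances with Geyer's
initial positive/monotone sequence rules) are implemented in the package
and pinned to an independent reference implementation by fixed-array
oracle tests at 1e-6.

## One-vs-rest contrasts

For stratum $r$ (risk level, or feedback item $k$) the module marginal
mean per draw is $\hat\mu_{m,r} = a_m + v_{m,r}$ — fixed-effect terms are
shared by all modules and cancel in contrasts. Per draw,

$$\delta_m = \hat\mu_m - \tfrac{1}{5}\sum_{m' \ne m} \hat\mu_{m'},$$

and $\sum_m \delta_m = 0$ identically (asserted to 1e-12). The
rest-average is taken on the linear-predictor scale *before*
exponentiation, a documented choice that makes the odds ratio exactly
$e^{\delta}$ and covariate-free (averaging on the probability scale
would entangle the contrast with the covariate values). Drinking effects are odds ratios $e^{\delta}$ summarized
by the posterior median (coherent with quantile-based equal-tailed 95%
intervals; configurable to the mean) with the posterior probability of
*less* drinking, $P(\delta < 0)$; feedback effects are raw mean
differences with $P(\delta > 0)$. Exact ties count against the
hypothesis — conservative, and measure-zero under continuous posteriors.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions so that every stage is
testable with known ground truth: ~43 participants over two trials
(47/53 split), age truncated-normal (mean 42.6, SD 11.4, ≥ 18), 79%
male, ASI from a beta with mean 0.35 / SD 0.19, weekly module
completions with jittered dates (83% on Mon–Thu, matching the reported
preponderance of low-risk completion days), fixed topic order in trial 1
and free order in trial 2, per-module skip probability 0.075 (≈ 61%
complete all six), and daily drinking from the same logistic model the
fit assumes — the active window's module offset, the day's risk class,
the *window-level* prior-week indicator, scaled time and a participant
intercept. The calendar covers the week before randomization so the
first window's prior-week indicator is derivable.

The default truth is calibrated to the reported study quantities:
high-risk odds ratio 3.83, prior-week odds ratio 3.17, one-vs-rest
module odds ratios 0.48 / 0.75 / 0.80 for coping with craving, cognitive
restructuring and problem solving (the other three modules share the
equal positive contrast that makes the six contrasts sum to zero), and
feedback contrasts +0.14 / +0.09 for cognitive restructuring and
decision making. Offsets are stored as $a_m = \tfrac{5}{6}\delta^*_m$ so
the generative one-vs-rest contrasts equal those targets exactly.
Remaining generative constants are not published and were set once to
reproduce the reported descriptive ranges (intercept −3.9 and
participant SD 1.0 give low-risk drinking proportions ≈ 0.09 and
high-risk ≈ 0.22; time slope −0.11 per 28 days encodes a mild decline
over treatment). Missingness is completely at random at rates 0.30
(calendar days) and 0.21 (ratings) — MCAR is the special case of the
MAR assumption the models make; an optional covariate-dependent MAR
mechanism (`mar_missingness = TRUE`, more gaps on weekends) exists for
robustness checks. Note that window truncation adds structural
missingness on top of the 0.30, so the *analyzed* slot missingness runs
nearer 38%.

What the generator deliberately does not emulate: outcome-dependent
(MNAR) dropout, within-day drinking episodes, treatment-as-usual-only
arms, and any real-data quirks of form administration. Passing tests
therefore demonstrate correctness of the machinery under the assumed
model, not robustness to violations of it.

## Numerical and design choices collected

* Quantiles are type-7 (linear interpolation) everywhere.
* Point summaries of odds ratios use the posterior median.
* Same-date module completions exclude all windows on that date;
  repeated topics keep the first completion with a warning.
* Constant MCMC draws define R-hat = 1 and ESS = the nominal draw count.
* Per-chain seeds are derived deterministically from one master seed;
  identical seeds give byte-identical simulations and fits.
* The convergence gate applies to all monitored structural parameters
  (fixed effects, module and cell effects, scales); participant
  intercepts and imputation nuisance parameters are not monitored by
  default.

## Problem sizes used by the test suite

Oracle and invariant tests run on micro datasets (2–4 participants) and
fixed small arrays. Recovery and calibration checks simulate cohorts of
50 participants × 8 weeks and fit reduced runs (2 chains × 1000 draws,
1000 warmup); across 20 replicates the 95% interval for the high-risk
odds ratio and the coping-with-craving one-vs-rest odds ratio must each
cover their generative values in at least 17, and under a null truth
(all module offsets zero) at most 10% of contrasts may reach 95%
posterior superiority. These sizes are the package's standing choice for
its own regression suite.

## Limitations

The one-vs-rest contrast inherits the design's central caveat: module
order is not randomized in this kind of study, so contrasts are
associational, and the time covariate only partially de-confounds order
effects. Posterior medians of contrasts are shrunk toward the null by
design — at n ≈ 43 a generative odds ratio of 0.48 typically posts a
posterior median nearer 0.6–0.75 with a wide interval; interval coverage,
not point agreement, is the meaningful recovery statement at this sample
size. Likert items are modelled as continuous, not ordinal — a
deliberate simplification; an ordinal cumulative-logit treatment is out
of scope.
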