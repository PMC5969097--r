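---
title: "Methods: preference instruments for prescribing cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preference instruments for prescribing cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(prefiv)
```

## Scope and estimands

`prefiv` compares health outcomes between patients started on varenicline
and patients started on nicotine-replacement therapy (NRT) in
prescription-level primary-care data. The exposure is the *first*
prescription — an intention-to-treat, new-user contrast: later switching is
deliberately ignored, because switching is strongly related to patient
characteristics and modelling it reintroduces confounding. Estimands are
per-horizon absolute risk differences per 100 patients treated (with odds
ratios as a secondary scale) for binary outcomes, and mean differences for
weight and consultation frequency. Survival models are out of scope by
design: with these outcomes proportional hazards does not hold over a
four-year horizon, and the per-horizon binary formulation is what the
additive structural mean model identifies anyway.

Three confounding-control strategies are implemented against the same
cohort: multivariable regression, propensity-score matching, and
physician-preference instrumental variables. The first two assume
conditional exchangeability (no unmeasured confounding); the third replaces
that assumption with the instrument conditions and is therefore the only
strategy robust to *healthy-user bias* — the systematic channelling of the
newer drug to healthier patients.

## The synthetic world

Real prescribing data of this kind is access-controlled, so the package
ships a generator whose output has the same shape and the same confounding
structure, making every downstream stage testable.

### Physicians and preference

Each of `n_physicians` prescribers receives a latent preference
$p_g \in (0,1)$ drawn from a Beta distribution — their propensity to issue
varenicline to an exchangeable patient. Preference is continuous, not a
two-class label: the binary "prefers varenicline / prefers NRT"
classification is recovered downstream from the extremes of the proxy
(`encoding = "binary"`), while the graded latent keeps first stages
realistic. The default `Beta(1.02, 2.06)` was calibrated a priori to two
published prescribing statistics: a marginal varenicline share of about
33%, and a lag-1 prescriber persistence of about 24.5 percentage points
via $\mathrm{Var}(p)/(\mathbb{E}[p](1-\mathbb{E}[p]))$. An optional secular
trend shifts preference log-odds per calendar year; it is off by default.

### Treatment assignment

Patient $i$ of physician $g$ receives varenicline with probability

$$\operatorname{logit} \Pr(X_i = 1) = \operatorname{logit}(p_g)
  + \textstyle\sum_c \beta_c (C_{ic} - \bar C_c) + \beta_U U_i,$$

where $C$ are the observed baseline covariates (centred so the marginal
share stays at $\mathbb{E}[p_g]$) and $U_i \sim N(0,1)$ is the unobserved
healthy-user axis. The default covariate set mirrors a published baseline
table for this prescribing contrast — sex, age, BMI, deprivation fifth,
consultation frequency, alcohol/drug misuse, six prior-medication flags,
five prior-diagnosis flags — with whole-cohort prevalences as margins and
$\beta_c$ signed so the varenicline arm comes out healthier on every flag.
Covariates are conditionally independent given $U$ unless a correlation
structure is added; published tables report only margins, so any joint
structure would be invented — this is the main respect in which the
synthetic world is simpler than real data, along with the absence of
diagnostic-coding noise and of over-the-counter NRT use.

### Outcomes

Binary outcomes are generated *risk-difference-natively*. Each patient
carries a structural shift on the absolute-risk scale at the reference
horizon (24 months by default):

$$s_i = \delta X_i + \textstyle\sum_c \gamma_c (C_{ic} - \bar C_c)
        + \gamma_U U_i + e_g, \qquad e_g \sim N(0, \sigma^2_{\text{phys}}),$$

and the per-horizon cumulative event probability is

$$p_{it} = b_t \cdot \max\!\big(0,\; 1 + s_i / b_{\text{ref}}\big)
  \quad (\text{capped at } 1),$$

with $b_t$ the non-decreasing baseline cumulative risk. At the reference
horizon this makes the configured $\delta$ and $\gamma$ exactly absolute
risk differences, while short-horizon probabilities stay in $[0,1]$ and
cumulative risks stay monotone. A literal constant-shift variant
($p_{it} = b_t + s_i$, clipped) is available as
`effect_scaling = "constant"` for stress tests; it was not made the default
because any realistic age effect on mortality drives a large share of
3-month probabilities below zero, and mass clipping silently distorts the
very effects the scenario is supposed to encode. If more than 1% of
probability draws are clipped under either scaling the generator warns —
the scenario is mis-parameterised.

Event *days* are drawn uniformly within the horizon bucket the event falls
into, so the cohort builder can recompute indicators from raw event dates.
The physician-level intercept $e_g$ is drawn independently of $p_g$, so it
induces intra-practice outcome correlation (what clustered standard errors
must absorb) without violating instrument validity.

Weight at one year is Gaussian with a treated-arm mean shift (+1.14 kg by
default); the two-year consultation count is negative-binomial with a
treated-arm log-rate shift (−0.217, about 19.5% fewer visits). Deaths are
recorded up to the linked follow-up end even after deregistration,
mirroring national mortality linkage; hospitalisations and measurements
stop at deregistration or death.

### Observation process

Index dates are uniform over the prescription window (September 2006 to
March 2014), with linked follow-up to March 2016. A configurable fraction
of patients deregisters at a uniform time (15% by default), exercising
censoring. Missingness is completely at random: 13.6% of BMI and 0.1% of
deprivation, matching the rates the package's imputation machinery is
designed around. Small fractions of patients receive records that violate
each eligibility rule — recent registration, a prescription inside the
washout window, same-day dual prescriptions — so cohort construction is
exercised realistically.

## Cohort construction conventions

Several conventions are undefined in common usage and fixed here
explicitly:

* **Month length**: 30.4375 days (the mean Gregorian month); the 3-month
  cutoff is 91.3125 days.
* **Windows**: half-open, $(\text{index}, \text{index} + t \cdot
  30.4375\,\text{d}]$; an event on the boundary day counts.
* **Washout boundary**: a patient is retained only with at least 548
  prescription-free days before index (a prior script exactly 548 days
  earlier retains; 547 excludes).
* **Same-day dual prescribing** is checked on the calendar date.
* **Censoring**: a patient-horizon is censored when available follow-up is
  shorter than the window and no event was observed inside it. Fatal
  outcomes censor against the linkage end only — never against practice
  deregistration; non-fatal outcomes censor at deregistration or death.
* **Exclusion precedence**: duplicates removed first (record level), then
  same-day dual, washout, recent registration — each patient counted once,
  and the ledger sums to the patient count.

## Missing data

Two strategies mirror the two analysis tracks:

* `impute_chained()` — chained-equation MI: Bayesian linear regression for
  BMI, proportional-odds ordinal logit for deprivation fifths, iterated
  over the conditional models. Defaults: m = 5 imputations, 5 iterations —
  conventional values, configurable. Predictors are the exposure, all other
  baseline covariates and a primary outcome indicator (congenial
  imputation; censored horizons enter as 0 — the alternative of omitting
  outcomes biases coefficient estimates toward the null). One pragmatic
  simplification: the ordinal draw uses fitted category probabilities
  rather than a full parameter draw; with 0.1% missing deprivation the
  between-imputation variance this ignores is negligible, and the
  continuous draw is fully Bayesian. Pooling follows Rubin's rules with the
  classic degrees of freedom.
* `mean_indicator_impute()` — mean replacement plus a binary missingness
  indicator per variable, the standard companion to propensity matching.
  After mean replacement, deprivation is no longer integer-valued and
  enters models linearly rather than as a factor.

## The instrument

`build_preference_proxy()` counts varenicline among each physician's $k=7$
most recent *prior* eligible first prescriptions. Three design choices:

* The window is defined over eligible first prescriptions only — the same
  patients that enter the cohort — because "the previous seven patients"
  refers to study-type patients, not all scripts.
* Rows whose physician has not yet issued $k$ scripts are dropped from the
  instrumented sample (keeping $Z$ on a fixed 0–7 scale) but retained for
  the regression and propensity tracks; physicians with ten or fewer
  eligible scripts are dropped entirely.
* The proxy is strictly past — the current and later prescriptions never
  contribute — and order-invariant: rows are sorted internally by
  physician, index date and patient id (same-day ties broken by id, which
  is arbitrary but deterministic).

The count encoding (0–7) is the default; the binary-extremes encoding
(all-seven vs none, the "prefers varenicline / prefers NRT"
classification) is provided for sensitivity analyses. Strength is
reported as the partial $F$ — for a single instrument, exactly the squared
cluster-robust $t$ of $Z$ in the first stage — plus the lag-1 persistence
statistic with a physician-clustered CI.

## Estimators and uncertainty

* **Multivariable regression**: basic adjustment is sex, age and year of
  first prescription; full adjustment adds every baseline covariate. The
  logit link reports odds ratios; the linear link reports risk differences
  per 100 — the estimand the horizon curves plot.
* **Propensity matching**: logistic score on the full covariate set plus
  missingness indicators; greedy 1:1 nearest-neighbour matching without
  caliper and without replacement, treated patients processed in a seeded
  random order (which also breaks exact-score ties reproducibly); outcome
  models on the matched sample include the score as a covariate. Common
  support is checked and reported.
* **Instrumental variables**: linear 2SLS with the basic covariate set
  (the adjustment set is configurable). For binary outcomes the 2SLS point
  estimate coincides with the additive structural mean model risk
  difference, so no separate SMM fit is needed; there is deliberately no
  logistic second stage. With no covariates the estimate reduces exactly
  to the covariance ratio $\operatorname{cov}(Z,Y) /
  \operatorname{cov}(Z,X)$ (the Wald ratio for binary $Z$), which the test
  suite verifies to $10^{-10}$.

All variances are cluster-robust sandwiches aggregated at the prescribing
physician (practice-level clustering is a one-argument change), with the
small-sample factor $\tfrac{G}{G-1}\cdot\tfrac{N-1}{N-K}$ so values are
comparable with mainstream econometrics software; the 2SLS meat uses
structural residuals (actual exposure, not its first-stage fit). IV
intervals use normal critical values — adequate at the panel sizes the
package targets (hundreds of physicians).

## Diagnostics

`bias_components()` contrasts, per covariate, the imbalance across actual
treatment, $B_X(c)$, with the imbalance across the instrument scaled by
instrument strength, $B_Z(c)$. The hi/lo instrument groups default to
$Z=7$ vs $Z=0$ — the preference classification; a regression-flavoured
scaling (reduced-form covariance ratio, using every row) is provided
because the published form of the plot is ambiguous between the two, and
both are labelled in output. Intervals come from a seeded physician-level
bootstrap (resampling clusters, not rows). A calibration note: with a few
hundred clusters the percentile cluster bootstrap undercovers mildly
(z-scores spread ~1.14 rather than 1), so the package's own null checks
use 99% intervals; the guard on the first-stage denominator refuses to
scale components by a near-zero treatment difference.

`cohort_summary()` produces the per-arm baseline table; percentages are
$100 \cdot \text{count}/n_{\text{arm}}$ rounded half *up* to one decimal
(`round_half_up()`), matching how published tables round, not banker's
rounding.

## Validation strategy and problem sizes

The test suite validates the science, not just the code paths:

* parameter recovery on the unmeasured-confounding stress scenario
  (`scenario_confounded()`: $\beta_U = 0.5$, $\gamma_U = -2/100$ per SD,
  true $\delta = 0$, ~20,000 patients, 200 replicates): the IV mean sits
  within 0.1 per 100 of the null while the fully adjusted regression is
  displaced by the omitted-variable bias computed from an independent
  brute-force simulation of the structural equations (2 million draws);
* interval calibration: 95% cluster-robust IV intervals over 500
  replicates of a 5,000-patient scenario;
* first-stage scaling: partial $F$ doubles (within 10%) when the panel
  doubles at fixed preference dispersion, 50 replicates per size;
* algebraic identities (2SLS vs covariance ratio, partial $F$ vs squared
  $t$, Rubin pooling by hand) at machine precision, and cluster-robust
  OLS against the `sandwich` reference implementation;
* descriptive arithmetic against printed cohort percentages.

The stress scenario raises baseline 24-month mortality to 6 per 100 —
higher than the default world's 2.9 — so that a 2-per-100 latent shift
leaves fewer than 1% of probability draws clipped; its missingness is
zero because it isolates confounding, not incomplete data. These choices
are part of the scenario definitions, made before the validation runs and
not revisited.

## Known limitations

* The generator draws covariates conditionally independent given $U$;
  real baseline tables have richer joint structure, so propensity-score
  behaviour on real data may differ in detail.
* No diagnostic-coding noise, no over-the-counter NRT, no
  practice-quality strata: passing tests demonstrate estimator
  correctness under the modelled data-generating process, not robustness
  to recording artefacts.
* The ordinal imputation draw omits parameter uncertainty (see above).
* The matching implementation is greedy sequential nearest-neighbour —
  the standard behaviour of the field's tooling — not optimal matching.
* Just-identified 2SLS has heavy tails when the first stage is weak; the
  weak-instrument guard errors rather than returning an estimate when the
  first-stage coefficient vanishes, and the strength report flags
  $F < 10$.
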