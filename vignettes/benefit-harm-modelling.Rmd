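---
title: "Modelling individualized benefit and harm of intensive blood pressure treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling individualized benefit and harm of intensive blood pressure treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpbenefit)
```

## The problem

Intensive blood pressure treatment (targeting systolic BP < 120 mm Hg rather
than < 140 mm Hg) lowers cardiovascular event rates on average but raises the
rate of serious adverse events — hypotension, syncope, electrolyte
abnormalities, bradycardia, acute kidney injury. Averages hide heterogeneity:
the participants who stand to gain the most cardiovascular protection are not
necessarily the ones who bear the adverse-event risk. `bpbenefit` implements a
counterfactual modelling strategy for quantifying that heterogeneity from a
two-arm randomized trial, and for carrying the resulting scores to an
external population.

Two composite outcomes are modelled separately, each with a Cox
proportional-hazards model censored at a 5-year horizon:

* **CVD events/deaths** — the *benefit* outcome; intensive treatment is
  protective on average.
* **Serious adverse events** — the *harm* outcome; intensive treatment is
  harmful on average.

Each model contains a main effect for every candidate predictor (age, sex,
black race, Hispanic ethnicity, systolic and diastolic BP, number of BP
agents, current and former smoking, aspirin, statin, serum creatinine, total
and HDL cholesterol, triglycerides, BMI, urine albumin/creatinine ratio), an
intensive-treatment indicator, and a treatment-by-covariate interaction for
every predictor. The interactions are the scientific payload: they encode
who responds differently.

## From a Cox model to a personal risk difference

A fitted model is reduced to three ingredients: the coefficient vector, the
baseline 5-year event-free probability $S_0$, and the cohort mean linear
predictor $\bar L$ (participants evaluated under their randomized arm). The
predicted 5-year risk for a patient with linear predictor $LP$ is the
centered survival transformation

$$\; p = 1 - S_0^{\exp(LP - \bar L)} .$$

Because the model contains the treatment indicator and its interactions,
each patient has two counterfactual linear predictors — one per arm — and
therefore two risks. Their difference is the quantity of clinical interest:

* **benefit** $= p_\text{standard} - p_\text{intensive}$ for the CVD model
  (positive when intensive treatment prevents events), and
* **harm** $= p_\text{intensive} - p_\text{standard}$ for the adverse-event
  model (positive when intensive treatment causes events).

`published_score()` ships the four published coefficient sets
(SPRINT-derived benefit and harm scores, plus their ACCORD-BP
recalibrations) as JSON fixtures, in both conventional (mg/dl) and SI units.
The conventional system is canonical internally because the published
worked-example arithmetic is reproduced exactly by the per-mg/dl
coefficients; SI values are accepted at the boundary through
`convert_units()` (creatinine × 88.4, cholesterol ÷ 38.67, triglycerides
÷ 88.57). The harm table's printed 3-decimal coefficients do not exactly
reproduce its own printed per-row products (they were rounded from
higher-precision values that are not recoverable), so exactness checks for
the harm score go through its printed raw scores rather than coefficient
sums; the fixture documents this.

```{r worked-example}
benefit <- published_score("sprint_benefit")
patient <- example_patient()
risk_difference(benefit, patient)
```

## Fitting: elastic net versus backwards selection

Systolic and diastolic pressure, and the lipid panel, are collinear;
stepwise selection is unstable in that setting. The package implements both
selection strategies behind one interface so they can be compared:

* `fit_penalized_cox()` maximizes the Breslow partial likelihood minus an
  elastic-net penalty over all main effects and interactions. The treatment
  main effect is never penalized and always retained, since every published
  model keeps it. Covariates are standardized internally; coefficients are
  returned on the original scale. The penalty strength is chosen by
  R-times-repeated K-fold cross-validation minimizing held-out
  partial-likelihood deviance, averaging the deviance curves over fold
  assignments. Defaults: mixing $\alpha = 0.5$ (both penalties active, which
  is what "elastic net" asserts; the mixing value used in the original
  analysis is not published), $K = 10$, $R = 10$, penalty rule = deviance
  minimum; all configurable through `penalty_config()`. A one-standard-error
  rule is available. The coordinate-descent solver is glmnet; the chosen
  penalty and the averaged CV curve are stored in the model's metadata.
* `fit_backwards_aic()` starts from the full model (fit by
  `survival::coxph`) and repeatedly considers the eligible term with the
  largest Wald p-value, removing it when removal lowers the partial
  likelihood AIC ($-2\,pl + 2k$), stopping at a local minimum. Hierarchy is
  enforced: an interaction must leave before its main effect becomes
  eligible, and the treatment term is never eligible.

Ties are handled with the Breslow approximation throughout (likelihood,
penalized fit, and baseline estimator) for internal consistency; Efron
weighting is available by flag in the backwards fit. An independent
Newton–Raphson maximizer of the same partial likelihood
(`cox_newton_raphson()`, with analytic gradient and Hessian from
`cox_partial_loglik()`) serves as the reference implementation: the
penalized path at zero penalty must agree with it to four decimals, and its
observed information supplies Wald intervals for `hazard_ratio_table()`.

The baseline constants come from `breslow_baseline()`: $\hat H_0$ is the
Breslow cumulative baseline hazard at the horizon, $\bar L$ the mean linear
predictor under the randomized arms, and
$S_0 = \exp(-\hat H_0)^{\exp(\bar L)}$, so that mean predicted risk
reproduces the cohort's observed risk. $\bar L$ uses participants'
*as-randomized* arms; whether the published centering constants were
computed that way or under a fixed arm is not stated in the source, so the
as-randomized convention is the default and the alternative is a one-line
change at scoring time (the constants enter only through $LP - \bar L$).

External validation keeps every coefficient untouched and recomputes only
$(S_0, \bar L)$ on the validation cohort (`recalibrate_baseline()`),
matching the recalibration the published ACCORD-BP constants encode.

## Evaluation: discrimination and calibration

`evaluate_model()` reports three things, each computed from the model's
absolute risk under the participant's actual randomized arm:

* **Harrell's C** (`concordance_index()`), with a seeded bootstrap
  percentile CI. The outcome is right-censored survival, so a
  censoring-aware concordance is used where the source describes an ROC
  AUC; any strictly monotone transform of the predictions leaves it
  unchanged. The CI method is recorded in the output since the published
  interval construction is unstated.
* **Decile calibration** (`calibration_deciles()`): groups by quantiles of
  predicted risk, Kaplan–Meier observed risk at the horizon per group with
  Greenwood variance, adjacent groups merged until every retained group has
  at least 5 observed events (the merge log is kept), and an unweighted
  least-squares line of observed on predicted group risks (slope 1,
  intercept 0 = perfect; inverse-variance weighting by option).
* **The GND test** (`gnd_test()`):
  $\chi^2 = \sum_g (\mathrm{KM}_g - \bar p_g)^2 / v_g$ with $v_g$ the
  Greenwood variance, referred to $\chi^2_{G-1}$.

A note on the GND reference distribution, because it shapes how the test's
operating characteristics should be checked. The $G-1$ degrees of freedom
follow the Hosmer–Lemeshow convention and presume that the predictions were
estimated from data — which is how the test is used here (a fitted model
checked on its cohort, or a recalibrated model on a validation cohort). If
instead the predictions are fixed externally and exactly true, the $G$
group discrepancies are independent and the statistic is stochastically
larger than $\chi^2_{G-1}$; simulations with known-true predictions
therefore over-reject at about 10% regardless of event counts. The
operating-characteristic suite consequently simulates the realistic
situation: each replicate cohort (n = 5,000) gets the correctly-specified
Cox model fit to it by the package's own Newton–Raphson and Breslow
estimators before testing, which is also the only situation the package
ever puts the test in. Under that design the measured size at the 0.05
level sits within the expected Monte-Carlo band, and the test has
essentially full power against a cohort whose baseline hazard is double
what the model assumes.

## Subgroups, NNT/NNH, and cross-classification

Predicted benefit and harm are cut into tertiles (`tertile_cutpoints()`,
linear-interpolation quantiles — the convention is fixed and documented
since the source does not state one) of the *pooled* derivation +
validation distribution; per-cohort cut points are the sensitivity variant.
For each subgroup, `subgroup_table()` reports arm sizes, event counts, the
expected risk difference (mean of members' predicted differences, with a
2.5–97.5 percentile band of the individual predictions), the observed
Kaplan–Meier risk difference with a Greenwood-variance normal CI and a
log-rank p, expected minus observed, and NNT/NNH. Differences are tabulated
as intensive minus standard for both outcomes.

NNT/NNH is the reciprocal of the absolute risk difference. The unrounded
reciprocal is the primary output: published NNT/NNH values are not always
consistent with reciprocals of the rounded differences printed beside them
(1/0.038 = 26.3, for instance, can print as 27 when computed from the
unrounded input), so rounding is left to the caller. A zero difference is
flagged not estimable.

The trend across ordered subgroups is tested with a Wald test for a
treatment-by-ordinal-subgroup interaction in a Cox model stratified by
subgroup — an implementation of the stratified log-rank trend whose exact
published construction is ambiguous; the construction used is recorded in
the output. Degenerate subgroups (one arm, or no events) are excluded with
a warning. `cross_classify()` tabulates benefit-by-harm subgroup membership
with the two headline cells (high benefit/low harm and low benefit/high
harm) named explicitly.

## The synthetic trial generator

Individual participant data from the source trials are available only by
application, so the package carries a first-class generator
(`sprint_like_scenario()`, `accord_like_scenario()`) whose defaults *are*
the study conditions, and which provides closed-form ground truth for
recovery testing.

* **Covariates** follow a Gaussian copula over the published marginal
  moments: truncated normals for symmetric measurements, moment-matched
  lognormals for the right-skewed labs (triglycerides, urine
  albumin/creatinine ratio), a binomial for the medication count, and
  binaries at the published prevalences. Current/former smoking comes from
  a single three-level latent variable, so the two indicators are mutually
  exclusive by construction. The published correlation evidence is
  graphical only, so the latent correlations default to a small plausible
  set (SBP–DBP 0.5, total cholesterol–triglycerides 0.3, total–HDL −0.1,
  age–creatinine 0.2, all else 0), fully overridable.
* **Randomization** is a permuted 1:1 assignment (`assign_treatment()`).
* **Outcomes** are drawn from proportional-hazards models
  $h(t \mid X, T) = h_0(t)\exp(\beta'X + \theta T + \gamma'(T X))$ with a
  Weibull cumulative baseline $H_0(t) = \lambda t^k$ (shape 1 — exponential
  — by default so every oracle is closed-form). The two outcomes are
  conditionally independent given covariates and arm: the source models
  them separately, so no shared frailty is introduced — a documented
  simplification. Continuous covariates enter standardized by the spec
  mean/SD, so interaction coefficients read as per-SD log-hazards.
* **Follow-up**: uniform accrual over 2 years, administrative censoring
  when the study closes (placed so the median administrative follow-up is
  3.3 years), a 5-year cap, and non-informative exponential dropout at
  2%/year (independence of dropout from covariates and arm matches the Cox
  assumptions).
* **Calibration of the truth**: the baseline rates (CVD 0.0168/y, SAE
  0.0198/y; ACCORD-like 0.047/0.023) and treatment main effects
  ($\theta_\text{CVD} = -0.45$, $\theta_\text{SAE} = 0.31$; ACCORD-like
  CVD $-0.10$) were calibrated once so the standard-arm observed event
  fractions sit near the published 6.3% (CVD) and 7.2% (SAE), with the
  validation preset materially higher in both, and then frozen. Interaction
  signs match the published direction of effect modification (more CVD
  benefit with older age, black race, higher diastolic BP and higher
  lipids, less for current smokers; more adverse-event harm with male sex,
  smoking, statin use, higher creatinine and lipids). Four CVD interactions
  are deliberately strong (at or above 0.3 in absolute log-hazard:
  treatment × age, black race, diastolic BP, current smoking) so that
  recovery of known heterogeneity is a falsifiable property.

What the generator does **not** emulate: the exact joint covariate
distribution of the trials, competing risks, outcome components (MI versus
stroke), informative dropout, or between-outcome dependence. Passing
recovery and calibration tests on this generator therefore demonstrates
that the estimation machinery is correct under the model class it assumes —
not that the published coefficient values would be re-derived from the real
data, which remain access-restricted.

## Numerical choices

* Risk probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$ so
  downstream logarithms stay finite; the transformation is computed on the
  log-survival scale to avoid overflow for extreme scores.
* Penalized fits use the solver's standard convergence threshold along the
  cross-validation path and a $10^{-12}$ threshold when solving at a fixed
  user-supplied penalty (where oracle-level accuracy matters).
  Newton–Raphson uses step-halving and a $10^{-10}$ relative likelihood
  tolerance, 100 iterations cap.
* A requested horizon beyond the last observed time returns the baseline at
  the last event time and records the truncation.
* Quantile-based grouping uses type-7 (linear interpolation) quantiles
  everywhere; duplicate quantile breaks collapse groups; an all-equal
  prediction vector yields a flagged single group with undefined slope.
* Serialized models round-trip through JSON at full precision.

## Problem sizes in the test suite

The property suites run at sizes chosen to keep Monte-Carlo error
comfortably below the asserted tolerances: copula marginals at n = 50,000
and 100,000, closed-form survival checks at n = 40,000–100,000, GND size at
500 replicate cohorts of n = 5,000 and power at 200 replicates,
interaction-term recovery over 20 generator seeds at the full preset size
n = 9,069 (cross-validation with 5 folds and 1 repeat there; the default
10 × 10 scheme is for analyses, not for replicated simulation), and CI
coverage at 120 replicates of n = 800.

## Known limitations

* The harm-score fixture cannot reproduce its printed per-row products at
  coefficient level (rounded source coefficients); raw-score level checks
  are exact.
* Penalized-fit hazard-ratio intervals are descriptive (observed
  information at shrunken estimates), not post-selection inference.
* The generator's lognormal marginals match the first two moments of the
  skewed labs but not their full shape; the urine albumin/creatinine ratio
  in particular is heavier-tailed in real cohorts.
* No competing-risks treatment: death from non-CVD causes censors rather
  than competes.
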