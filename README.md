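# bpbenefit

Individualized benefit and harm prediction for intensive blood pressure
treatment.

Intensive BP treatment (systolic target < 120 mm Hg instead of < 140 mm Hg)
prevents cardiovascular (CVD) events on average but causes serious adverse
events (SAEs) — hypotension, syncope, electrolyte abnormalities, bradycardia,
acute kidney injury — and the people who gain the most protection are not
necessarily the ones who bear the harm. `bpbenefit` is for biostatisticians
and clinical-trial methodologists who want to derive, validate, and apply
*counterfactual risk-difference scores* from two-arm randomized trial data:
per-patient estimates of the 5-year absolute risk reduction in CVD events
(benefit) and absolute risk increase in SAEs (harm) from treating
intensively.

## The model

For each composite outcome a Cox proportional-hazards model with
treatment–covariate interactions is fit, censored at t* = 5 years:

    h(t | X, T) = h0(t) · exp(β′X + θT + γ′(T·X)),   T ∈ {0 standard, 1 intensive}

A fitted model is summarized by its coefficients, the baseline 5-year
event-free probability S0, and the cohort mean linear predictor L̄, giving
the absolute risk

    p = 1 − S0^exp(LP − L̄)

Each patient has two counterfactual linear predictors (one per arm), hence
two risks; the benefit score is p_standard − p_intensive for the CVD model
and the harm score is p_intensive − p_standard for the SAE model. Reciprocals
give per-patient NNT/NNH.

The package provides:

* **Published score fixtures** — the SPRINT-derived benefit and harm
  coefficient sets and their ACCORD-BP (type 2 diabetes) baseline
  recalibrations, in conventional and SI units (`published_score()`).
* **Model derivation** — elastic-net penalized Cox fitting with repeated
  internal cross-validation (`fit_penalized_cox()`) and a backwards-AIC
  comparator with interaction hierarchy (`fit_backwards_aic()`), both on top
  of a Breslow partial likelihood with analytic derivatives and an
  independent Newton–Raphson reference fit.
* **Evaluation** — Harrell's C with bootstrap CI, decile calibration
  tables with Greenwood variances, and the Greenwood–Nam–D'Agostino
  chi-square calibration test (`evaluate_model()`).
* **External validation** — baseline-only recalibration with coefficients
  frozen (`recalibrate_baseline()`).
* **Subgroup reporting** — tertile cut points on pooled predicted values,
  observed vs expected risk differences with CIs and log-rank p, NNT/NNH,
  trend tests, benefit-by-harm cross-classification (`subgroup_table()`,
  `cross_classify()`).
* **A synthetic trial generator** — Gaussian-copula covariates matching the
  published baseline characteristics, 1:1 randomization, proportional-hazards
  outcomes with known treatment-effect heterogeneity, staggered accrual,
  dropout, and administrative censoring (`sprint_like_scenario()`,
  `accord_like_scenario()`), with closed-form ground truth for recovery
  testing.

## Worked example

Score the published example patient — a 65-year-old non-Hispanic black man,
BP 140/90 mm Hg, one BP medication, former smoker, on a statin, creatinine
1.1 mg/dl, total cholesterol 190 mg/dl, HDL 50 mg/dl, triglycerides
120 mg/dl, BMI 30 — with the published SPRINT-derived scores:

```r
library(bpbenefit)

benefit <- published_score("sprint_benefit")
patient <- example_patient()
risk_difference(benefit, patient)
#>   raw_standard raw_intensive risk_standard risk_intensive difference
#> 1       6.7041        6.2511    0.05367224     0.03446238 0.01920986
```

The raw scores 6.704 (standard) and 6.251 (intensive) transform to 5-year
CVD risks of 5.37% and 3.45%: an absolute risk reduction of 1.92 percentage
points, i.e. a personal NNT of `1/0.0192 = 52` to prevent one CVD
event/death over 5 years. The same patient's predicted harm:

```r
harm <- published_score("sprint_harm")
risk_difference(harm, patient)
#>   raw_standard raw_intensive risk_standard risk_intensive difference
#> 1        3.092        3.4957    0.03063279     0.04551692 0.01488414
```

a predicted 1.49-point increase in 5-year SAE risk (NNH ≈ 67). Weighing
2 CVD events prevented against 1.5 SAEs caused per 100 patients treated is a
clinical judgment the package deliberately leaves to the user.

A full derivation–validation round on synthetic data:

```r
sc  <- sprint_like_scenario(seed = 1)          # n = 9,069 synthetic cohort
run <- run_derivation(sc$data)                  # elastic net + backwards AIC,
                                                # both outcomes, internal eval
ext <- accord_like_scenario(seed = 2)$data      # diabetic-like validation set
run <- run_external_validation(run, ext)        # recalibrate, evaluate, subgroup
compare_selection_methods(run)                  # C / slope / intercept / GND p
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/bpbenefit_pipeline.R` (subcommands `simulate`, `derive`,
`validate`, `score`).

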