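#' Preset synthetic trial scenarios
#'
#' `sprint_like_scenario()` builds a complete synthetic two-arm trial shaped
#' like the derivation cohort: n = 9,069 participants with
#' [sprint_covariate_spec()] covariates, 1:1 permuted randomization,
#' and proportional-hazards outcomes whose ground truth encodes
#' heterogeneous treatment effects with the qualitative signs reported for
#' the derivation cohort (greater CVD benefit with older age, black race,
#' higher diastolic BP and higher lipids; less benefit for current smokers;
#' greater adverse-event harm with male sex, current smoking, statin use,
#' higher creatinine and higher lipids). Baseline hazard rates are tuned so
#' the standard-arm observed event fractions sit near 6.3% (CVD
#' events/deaths) and 7.2% (serious adverse events) under the default
#' follow-up design (2-year accrual, 5-year horizon, median administrative
#' follow-up 3.3 years, 2%/year dropout).
#'
#' `accord_like_scenario()` is the external-validation analogue: n = 4,498,
#' [accord_covariate_spec()] covariates (a type 2 diabetes population),
#' materially higher baseline hazards for both outcomes, and a weaker
#' average CVD treatment effect.
#'
#' Continuous covariates enter the ground-truth linear predictor
#' standardized by the spec mean and SD, so interaction coefficients read as
#' per-SD log-hazard shifts; binary and count covariates are centered only.
#' The interaction terms with absolute log-hazard at or above 0.3
#' (treatment x age, black race, diastolic BP, current smoking in the CVD
#' model) are the "strong" heterogeneity the recovery suite expects a
#' selection method to find.
#'
#' @param seed integer seed controlling covariates, randomization and
#'   outcomes.
#' @param n cohort size.
#' @return list with elements `covariate_spec`, `true_model`, `follow_up`,
#'   and `data` (the simulated [simulate_outcomes()] dataset).
#' @export
sprint_like_scenario <- function(seed = 1, n = 9069) {
  spec <- sprint_covariate_spec()
  tm <- sprint_true_model(spec)
  fu <- follow_up_spec(accrual = 2, horizon = 5, dropout_rate = 0.02,
                       target_median = 3.3)
  build_scenario(spec, tm, fu, seed = seed, n = n)
}

#' @rdname sprint_like_scenario
#' @export
accord_like_scenario <- function(seed = 1, n = 4498) {
  spec <- accord_covariate_spec()
  tm <- accord_true_model(spec)
  fu <- follow_up_spec(accrual = 2, horizon = 5, dropout_rate = 0.02,
                       target_median = 3.3)
  build_scenario(spec, tm, fu, seed = seed, n = n)
}

build_scenario <- function(spec, tm, fu, seed, n) {
  seeds <- derive_seeds(seed, 3)
  covariates <- generate_covariates(spec, n, seed = seeds[1])
  arms <- assign_treatment(n, seed = seeds[2])
  data <- simulate_outcomes(covariates, arms, tm, fu, seed = seeds[3])
  list(covariate_spec = spec, true_model = tm, follow_up = fu, data = data)
}

# centering/scaling vectors from a covariate spec: continuous and lognormal
# variables are standardized to spec mean/SD, binary and count centered only
spec_center_scale <- function(spec) {
  ctr <- scl <- numeric()
  for (nm in names(spec$variables)) {
    v <- spec$variables[[nm]]
    if (v$kind %in% c("continuous", "lognormal")) {
      ctr[nm] <- v$mean; scl[nm] <- v$sd
    } else if (v$kind == "binary") {
      ctr[nm] <- v$p; scl[nm] <- 1
    } else {
      ctr[nm] <- v$mean; scl[nm] <- 1
    }
  }
  list(center = ctr, scale = scl)
}

sprint_true_model <- function(spec = sprint_covariate_spec()) {
  cs <- spec_center_scale(spec)
  cvd <- true_outcome_model(
    coef = c(age = 0.40, female = -0.10, black = 0.05, hispanic = -0.15,
             sbp = 0.15, dbp = 0.00, n_bp_agents = 0.15,
             current_smoker = 0.70, former_smoker = 0.10, aspirin = 0.10,
             statin = 0.10, creatinine = 0.25, total_chol = 0.10,
             hdl = -0.20, triglycerides = 0.05, bmi = 0.05,
             urine_albumin_creatinine = 0.15),
    treatment = -0.45,
    interaction = c(age = -0.35, black = -0.55, dbp = -0.30,
                    current_smoker = 0.90, hdl = -0.12,
                    triglycerides = -0.10),
    baseline_rate = 0.0168)
  sae <- true_outcome_model(
    coef = c(age = 0.30, female = 0.10, sbp = 0.10, dbp = -0.05,
             n_bp_agents = 0.20, current_smoker = 0.45,
             former_smoker = 0.08, aspirin = 0.05, statin = -0.10,
             creatinine = 0.35, total_chol = -0.05, hdl = 0.05,
             triglycerides = 0.05, urine_albumin_creatinine = 0.20),
    treatment = 0.31,
    interaction = c(female = -0.20, current_smoker = 0.30, statin = 0.30,
                    creatinine = 0.30, total_chol = 0.20,
                    triglycerides = 0.10),
    baseline_rate = 0.0198)
  true_model(cvd = cvd, sae = sae, center = cs$center, scale = cs$scale)
}

accord_true_model <- function(spec = accord_covariate_spec()) {
  base <- sprint_true_model(spec)  # same effect structure
  cs <- spec_center_scale(spec)
  cvd <- base$outcomes$cvd
  sae <- base$outcomes$sae
  cvd$treatment <- -0.10           # weaker average CVD benefit
  cvd$baseline_rate <- 0.0470      # diabetic cohort: higher event rates
  sae$baseline_rate <- 0.0230
  true_model(cvd = cvd, sae = sae, center = cs$center, scale = cs$scale)
}
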