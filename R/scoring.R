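#' Linear predictor (raw score) for a patient under a treatment arm
#'
#' Sums coefficient times covariate value over the model's main-effect terms;
#' under the intensive arm the treatment main effect and every
#' treatment-by-covariate interaction contribution are added. This is the
#' "raw score" of the published score tables.
#'
#' @param model a [bp_risk_model].
#' @param patient data frame of patient records (one row per patient) whose
#'   columns cover every model term, or a named list for a single patient.
#' @param arm 0 for standard, 1 for intensive treatment; scalar or one value
#'   per row.
#' @param units unit system of the supplied values, `"conventional"` or
#'   `"si"`. Defaults to the model's native system. When the model carries a
#'   parallel SI coefficient set that set is used directly; otherwise values
#'   are converted with [convert_units()].
#' @return numeric vector of linear predictors, one per row.
#' @export
raw_score <- function(model, patient, arm, units = model$units) {
  stopifnot(inherits(model, "bp_risk_model"))
  units <- match.arg(units, c("conventional", "si"))
  patient <- as.data.frame(patient)
  coefs <- model_coefs_for_units(model, units)
  if (is.null(coefs)) {            # no parallel set: convert the values
    patient <- convert_units(patient, from = units)
    coefs <- list(main = model$coef_main, interaction = model$coef_interaction)
  }
  missing <- setdiff(names(coefs$main), names(patient))
  if (length(missing))
    stop("patient record is missing required fields: ",
         paste(missing, collapse = ", "))
  arm <- as.numeric(arm)
  if (!all(arm %in% c(0, 1))) stop("arm must be 0 (standard) or 1 (intensive)")
  x_main <- as.matrix(patient[names(coefs$main)])
  lp <- drop(x_main %*% coefs$main)
  if (length(coefs$interaction)) {
    x_int <- as.matrix(patient[names(coefs$interaction)])
    lp <- lp + arm * (model$coef_treatment + drop(x_int %*% coefs$interaction))
  } else {
    lp <- lp + arm * model$coef_treatment
  }
  unname(lp)
}

# pick the coefficient set matching the requested unit system, or NULL when
# the model has no set on that scale
model_coefs_for_units <- function(model, units) {
  if (units == model$units)
    return(list(main = model$coef_main, interaction = model$coef_interaction))
  if (units == "si" && !is.null(model$coef_main_si))
    return(list(main = model$coef_main_si,
                interaction = model$coef_interaction_si))
  NULL
}

#' Transform a raw score into an absolute risk
#'
#' Applies the centered survival transformation
#' `risk = 1 - s0^exp(raw - lbar)` with the model's baseline survival `s0`
#' and mean linear predictor `lbar`. The result is clamped to the open
#' interval (1e-12, 1 - 1e-12) so downstream logarithms stay finite.
#'
#' @param model a [bp_risk_model].
#' @param raw numeric vector of linear predictors.
#' @return predicted event probabilities at the model horizon.
#' @export
absolute_risk <- function(model, raw) {
  stopifnot(inherits(model, "bp_risk_model"))
  # on the log scale: log(1 - risk) = exp(raw - lbar) * log(s0)
  log_surv <- exp(raw - model$lbar) * log(model$s0)
  risk <- -expm1(log_surv)
  pmin(pmax(risk, 1e-12), 1 - 1e-12)
}

#' Counterfactual risk difference for patient records
#'
#' Predicts the absolute event probability under each arm and differences
#' them with the model's sign convention: benefit models report
#' `risk_standard - risk_intensive` (positive when intensive treatment
#' prevents events), harm models report `risk_intensive - risk_standard`
#' (positive when intensive treatment causes events).
#'
#' @inheritParams raw_score
#' @return data frame with one row per patient: `raw_standard`,
#'   `raw_intensive`, `risk_standard`, `risk_intensive`, and `difference`
#'   (signed per the model's direction).
#' @export
risk_difference <- function(model, patient, units = model$units) {
  patient <- as.data.frame(patient)
  raw_std <- raw_score(model, patient, arm = 0, units = units)
  raw_int <- raw_score(model, patient, arm = 1, units = units)
  p_std <- absolute_risk(model, raw_std)
  p_int <- absolute_risk(model, raw_int)
  diff <- if (model$direction == "benefit") p_std - p_int else p_int - p_std
  data.frame(raw_standard = raw_std, raw_intensive = raw_int,
             risk_standard = p_std, risk_intensive = p_int,
             difference = diff)
}

#' Score a whole cohort
#'
#' Row-wise [risk_difference()] over a trial dataset, with distribution
#' summaries (quartiles and interquartile range of the predicted
#' difference) attached as attributes.
#'
#' @param model a [bp_risk_model].
#' @param data trial dataset (complete cases) whose columns cover the model
#'   terms.
#' @param units unit system of the dataset values.
#' @return the [risk_difference()] data frame with attributes `summary`
#'   (named quantiles) and `iqr`.
#' @export
score_cohort <- function(model, data, units = model$units) {
  scores <- risk_difference(model, data, units = units)
  qs <- stats::quantile(scores$difference, c(0, 0.25, 0.5, 0.75, 1))
  attr(scores, "summary") <- qs
  attr(scores, "iqr") <- unname(qs["75%"] - qs["25%"])
  attr(scores, "model") <- model$name
  scores
}

#' Joint summary of predicted benefit and harm
#'
#' Pairs a benefit score table and a harm score table for the same cohort
#' (aligned rows) and reports their Pearson correlation together with the
#' marginal quartiles, mirroring the benefit-versus-harm scatter summaries.
#'
#' @param benefit,harm score tables from [score_cohort()] for the same rows.
#' @return list with `correlation`, `benefit_quartiles`, `harm_quartiles`.
#' @export
benefit_harm_summary <- function(benefit, harm) {
  if (nrow(benefit) != nrow(harm))
    stop("benefit and harm tables must describe the same cohort")
  list(correlation = stats::cor(benefit$difference, harm$difference,
                                method = "pearson"),
       benefit_quartiles = stats::quantile(benefit$difference, c(0.25, 0.5, 0.75)),
       harm_quartiles = stats::quantile(harm$difference, c(0.25, 0.5, 0.75)))
}

#' Recalibrate a model's baseline on an external cohort
#'
#' Keeps every coefficient untouched and recomputes only the baseline
#' survival `s0` and centering constant `lbar` on the external dataset: the
#' linear predictor is evaluated for each participant under their actual
#' randomized arm, `lbar` is its cohort mean, and `s0` comes from the
#' Breslow cumulative baseline hazard at the horizon. This is the external
#' validation adjustment for cohorts with different baseline event rates.
#'
#' @param model a [bp_risk_model].
#' @param data external trial dataset containing the model covariates, an
#'   `arm` column, and the outcome's time/event columns.
#' @param horizon recalibration horizon in years; defaults to the model's.
#' @return the model with new `s0` and `lbar` (coefficients bitwise equal).
#' @export
recalibrate_baseline <- function(model, data, horizon = model$horizon) {
  stopifnot(inherits(model, "bp_risk_model"))
  cols <- outcome_columns(model$outcome)
  need <- c(names(model$coef_main), "arm", cols)
  missing <- setdiff(need, names(data))
  if (length(missing))
    stop("external dataset is missing columns: ", paste(missing, collapse = ", "))
  lp <- raw_score(model, data, arm = data$arm)
  H0 <- breslow_cumhaz(data[[cols["time"]]], data[[cols["event"]]], lp, horizon)
  lbar <- mean(lp)
  s0 <- exp(-H0 * exp(lbar))
  model$lbar <- lbar
  model$s0 <- min(max(s0, 1e-12), 1 - 1e-12)
  model$meta$recalibrated <- TRUE
  model
}

#' Convert lab values between unit systems
#'
#' Converts the laboratory fields of a patient record between conventional
#' (mg/dl) and SI units: serum creatinine by a factor of 88.4
#' (mg/dl to umol/l), total and HDL cholesterol by 38.67 (mg/dl to mmol/l),
#' and triglycerides by 88.57 (mg/dl to mmol/l). All other fields pass
#' through unchanged; the round trip is stable to well below 1e-9.
#'
#' @param patient data frame (or named list) of patient records.
#' @param from unit system of the input, `"conventional"` or `"si"`.
#' @return data frame in the other unit system.
#' @export
convert_units <- function(patient, from = c("conventional", "si")) {
  from <- match.arg(from)
  patient <- as.data.frame(patient)
  # multiplier taking a conventional value to SI
  to_si <- c(creatinine = 88.4, total_chol = 1 / 38.67,
             hdl = 1 / 38.67, triglycerides = 1 / 88.57)
  for (field in intersect(names(to_si), names(patient))) {
    patient[[field]] <- if (from == "conventional")
      patient[[field]] * to_si[[field]]
    else
      patient[[field]] / to_si[[field]]
  }
  patient
}
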