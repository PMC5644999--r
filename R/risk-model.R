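#' Risk-difference model objects
#'
#' A `bp_risk_model` holds everything needed to turn a patient record into a
#' predicted 5-year absolute risk difference between intensive and standard
#' blood pressure treatment: Cox log-hazard coefficients split into main
#' effects, the intensive-treatment main effect, and treatment-by-covariate
#' interactions, together with the baseline 5-year survival `s0` and the
#' cohort mean linear predictor `lbar` that center the risk transformation
#' `risk = 1 - s0^exp(lp - lbar)`.
#'
#' Models come from two places: fitted from trial data (see
#' [fit_penalized_cox()] and [fit_backwards_aic()]) or loaded as published
#' score fixtures (see [published_score()]). Both share this container so the
#' scoring, evaluation and subgroup code treats them identically.
#'
#' @param name short identifier, e.g. `"sprint_benefit"`.
#' @param outcome `"cvd"` or `"sae"` (selects the `time_*`/`event_*` columns).
#' @param direction `"benefit"` (risk reduction reported positive when
#'   intensive treatment lowers risk) or `"harm"` (risk increase reported
#'   positive when intensive treatment raises risk).
#' @param coef_main named numeric vector of main-effect log-hazard
#'   coefficients (natural covariate units).
#' @param coef_treatment scalar log-hazard for the intensive-treatment
#'   indicator.
#' @param coef_interaction named numeric vector of treatment-by-covariate
#'   interaction log-hazards; may be empty.
#' @param s0 baseline probability of remaining event free at the horizon,
#'   in (0, 1).
#' @param lbar cohort mean linear predictor used to center the transform.
#' @param horizon prediction horizon in years (default 5).
#' @param units unit system the coefficients expect: `"conventional"`
#'   (mg/dl) or `"si"`.
#' @param coef_main_si,coef_interaction_si optional parallel coefficient sets
#'   on the SI scale (published fixtures carry both).
#' @param meta free-form list of provenance (selection method, lambda, ...).
#'
#' @return an object of class `bp_risk_model`.
#' @export
bp_risk_model <- function(name, outcome, direction,
                          coef_main, coef_treatment, coef_interaction = numeric(),
                          s0, lbar, horizon = 5, units = "conventional",
                          coef_main_si = NULL, coef_interaction_si = NULL,
                          meta = list()) {
  outcome <- match.arg(outcome, c("cvd", "sae"))
  direction <- match.arg(direction, c("benefit", "harm"))
  units <- match.arg(units, c("conventional", "si"))
  stopifnot(is.numeric(coef_main), !is.null(names(coef_main)),
            length(coef_treatment) == 1L, is.finite(coef_treatment))
  if (length(coef_interaction) && is.null(names(coef_interaction)))
    stop("interaction coefficients must be named")
  if (!is.numeric(s0) || length(s0) != 1L || s0 <= 0 || s0 >= 1)
    stop("s0 must be a single probability strictly inside (0, 1)")
  if (!is.numeric(lbar) || length(lbar) != 1L || !is.finite(lbar))
    stop("lbar must be a single finite number")
  unknown <- setdiff(names(coef_interaction), names(coef_main))
  if (length(unknown))
    stop("interaction terms without a known covariate: ",
         paste(unknown, collapse = ", "))
  structure(
    list(name = name, outcome = outcome, direction = direction,
         coef_main = coef_main, coef_treatment = unname(coef_treatment),
         coef_interaction = coef_interaction,
         s0 = s0, lbar = lbar, horizon = horizon, units = units,
         coef_main_si = coef_main_si, coef_interaction_si = coef_interaction_si,
         meta = meta),
    class = "bp_risk_model")
}

#' @exportS3Method base::print
print.bp_risk_model <- function(x, ...) {
  cat(sprintf("<bp_risk_model> %s (%s, %s)\n", x$name, x$outcome, x$direction))
  cat(sprintf("  %d main terms, treatment %.4g, %d interaction terms\n",
              length(x$coef_main), x$coef_treatment, length(x$coef_interaction)))
  cat(sprintf("  s0 = %.4g, lbar = %.4g, horizon = %g y\n",
              x$s0, x$lbar, x$horizon))
  invisible(x)
}

#' Load a published risk-score fixture
#'
#' The package ships the four published SPRINT-derived score fixtures as
#' versioned JSON files: `sprint_benefit` (CVD events/deaths),
#' `sprint_harm` (serious adverse events), and their ACCORD-BP
#' recalibrations `accord_benefit` and `accord_harm`, which reuse the SPRINT
#' coefficients with the baseline survival and centering constant recomputed
#' on the diabetic validation cohort.
#'
#' @param name one of `"sprint_benefit"`, `"sprint_harm"`,
#'   `"accord_benefit"`, `"accord_harm"`.
#' @return a [bp_risk_model] with both conventional and SI coefficient sets;
#'   the worked-example values printed in the source tables are attached
#'   under `meta$example`.
#' @export
published_score <- function(name = c("sprint_benefit", "sprint_harm",
                                     "accord_benefit", "accord_harm")) {
  name <- match.arg(name)
  raw <- read_score_fixture(name)
  base <- raw
  if (!is.null(raw$inherits)) {
    base <- read_score_fixture(raw$inherits)
    for (field in c("name", "s0", "lbar", "outcome", "direction", "horizon"))
      base[[field]] <- raw[[field]]
    base$example <- NULL  # worked example belongs to the derivation cohort
  }
  bp_risk_model(
    name = base$name, outcome = base$outcome, direction = base$direction,
    coef_main = unlist(base$coef_main),
    coef_treatment = base$coef_treatment,
    coef_interaction = unlist(base$coef_interaction),
    s0 = base$s0, lbar = base$lbar, horizon = base$horizon,
    units = base$units,
    coef_main_si = unlist(base$coef_main_si),
    coef_interaction_si = unlist(base$coef_interaction_si),
    meta = list(source = "published fixture", version = base$version,
                example = base$example, notes = base$notes))
}

read_score_fixture <- function(name) {
  path <- system.file("extdata", "scores", paste0(name, ".json"),
                      package = "bpbenefit")
  if (!nzchar(path)) stop("no fixture named ", name)
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' The published worked-example patient
#'
#' One-row data frame with the example patient used alongside the published
#' scores: a 65-year-old non-Hispanic black man with BP 140/90 mm Hg on one
#' BP medication and a statin, a former smoker, labs in conventional units.
#'
#' @return one-row `data.frame` of covariates (conventional units).
#' @export
example_patient <- function() {
  path <- system.file("extdata", "example_patient.json", package = "bpbenefit")
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE)$patient)
}

#' Serialize / restore a risk model as JSON
#'
#' Round-trips all fields of a [bp_risk_model] losslessly (numbers written at
#' full precision).
#'
#' @param model a [bp_risk_model].
#' @param path file to write / read.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns the restored model.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "bp_risk_model"))
  payload <- unclass(model)
  # named coefficient vectors must serialize as objects, not bare arrays
  for (f in c("coef_main", "coef_interaction", "coef_main_si",
              "coef_interaction_si"))
    if (!is.null(payload[[f]])) payload[[f]] <- as.list(payload[[f]])
  payload$meta <- NULL  # provenance (fold curves, vcov) is not part of the score
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bp_risk_model(
    name = x$name, outcome = x$outcome, direction = x$direction,
    coef_main = unlist(x$coef_main),
    coef_treatment = x$coef_treatment,
    coef_interaction = if (length(x$coef_interaction)) unlist(x$coef_interaction) else numeric(),
    s0 = x$s0, lbar = x$lbar, horizon = x$horizon, units = x$units,
    coef_main_si = if (length(x$coef_main_si)) unlist(x$coef_main_si),
    coef_interaction_si = if (length(x$coef_interaction_si)) unlist(x$coef_interaction_si),
    meta = if (is.null(x$meta)) list() else x$meta)
}

# time/event column names for a composite outcome
outcome_columns <- function(outcome) {
  outcome <- match.arg(outcome, c("cvd", "sae"))
  c(time = paste0("time_", outcome), event = paste0("event_", outcome))
}
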