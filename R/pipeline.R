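#' Derive benefit and harm models from a trial dataset
#'
#' End-to-end derivation stage: complete-case filtering (dropped-row count
#' logged), fitting of the CVD (benefit) and serious-adverse-event (harm)
#' Cox models by both selection methods — elastic-net penalized likelihood
#' with repeated internal cross-validation, and backwards AIC selection —
#' baseline calibration, internal evaluation (discrimination, calibration,
#' GND), and cohort scoring with the elastic-net models.
#'
#' @param data trial dataset (covariates, `arm`, outcome columns).
#' @param design a [design_spec()]; defaults to every covariate as main
#'   effect and interaction.
#' @param penalty a [penalty_config()].
#' @param horizon risk horizon in years.
#' @param eval_B bootstrap replicates for C-statistic CIs.
#' @param seed master seed for evaluation bootstraps.
#' @param methods selection methods to run.
#' @return object of class `bp_run`: `models[[method]][[outcome]]`,
#'   `evaluation[[method]][[outcome]]`, `scores[[outcome]]` (elastic net),
#'   `benefit_harm` summary, `data`, `log`.
#' @export
run_derivation <- function(data, design = NULL, penalty = penalty_config(),
                           horizon = 5, eval_B = 200, seed = 1,
                           methods = c("elastic_net", "backwards_aic")) {
  if (is.null(design)) {
    covs <- setdiff(names(data),
                    c("arm", "time_cvd", "event_cvd", "time_sae", "event_sae"))
    design <- design_spec(covs)
  }
  need <- c(design$main, design$treatment,
            outcome_columns("cvd"), outcome_columns("sae"))
  data_cc <- complete_cases(data, intersect(need, names(data)))
  if (!nrow(data_cc)) stop("no complete cases left after filtering")
  methods <- match.arg(methods, several.ok = TRUE)
  models <- evaluation <- list()
  seeds <- derive_seeds(seed, 4)
  i <- 0
  for (method in methods) {
    models[[method]] <- list()
    evaluation[[method]] <- list()
    for (outcome in c("cvd", "sae")) {
      i <- i + 1
      fit <- if (method == "elastic_net")
        fit_penalized_cox(data_cc, design, penalty, outcome = outcome,
                          horizon = horizon)
      else
        fit_backwards_aic(data_cc, design, outcome = outcome,
                          horizon = horizon)
      models[[method]][[outcome]] <- fit
      evaluation[[method]][[outcome]] <-
        evaluate_model(fit, data_cc, label = paste("derivation", method, outcome),
                       B = eval_B, seed = seeds[i])
    }
  }
  primary <- if ("elastic_net" %in% methods) "elastic_net" else methods[1]
  scores <- list(cvd = score_cohort(models[[primary]]$cvd, data_cc),
                 sae = score_cohort(models[[primary]]$sae, data_cc))
  structure(list(
    models = models, evaluation = evaluation, scores = scores,
    benefit_harm = benefit_harm_summary(scores$cvd, scores$sae),
    design = design, data = data_cc,
    log = list(n_input = nrow(data), n_complete = nrow(data_cc),
               n_dropped = attr(data_cc, "n_dropped"),
               methods = methods, primary = primary, seed = seed,
               horizon = horizon)),
    class = "bp_run")
}

#' Externally validate derived models on a second cohort
#'
#' Applies every derived model to the validation cohort with the baseline
#' survival and centering constant recomputed there (coefficients untouched),
#' evaluates discrimination and calibration, computes tertile cut points
#' from the pooled derivation + validation predicted values, and builds
#' subgroup tables for both cohorts using those common cut points, plus the
#' benefit-by-harm cross-classification.
#'
#' @param run a [run_derivation()] result.
#' @param ext_data validation trial dataset.
#' @param eval_B,seed evaluation bootstrap controls.
#' @return the `bp_run` augmented with `validation` (recalibrated models,
#'   evaluations, scores, cut points, subgroup tables, cross-classification).
#' @export
run_external_validation <- function(run, ext_data, eval_B = 200, seed = 2) {
  stopifnot(inherits(run, "bp_run"))
  need <- c(run$design$main, run$design$treatment,
            outcome_columns("cvd"), outcome_columns("sae"))
  ext_cc <- complete_cases(ext_data, intersect(need, names(ext_data)))
  models <- evaluation <- list()
  seeds <- derive_seeds(seed, 4)
  i <- 0
  for (method in names(run$models)) {
    models[[method]] <- list()
    evaluation[[method]] <- list()
    for (outcome in c("cvd", "sae")) {
      i <- i + 1
      recal <- recalibrate_baseline(run$models[[method]][[outcome]], ext_cc)
      models[[method]][[outcome]] <- recal
      evaluation[[method]][[outcome]] <-
        evaluate_model(recal, ext_cc, label = paste("validation", method, outcome),
                       B = eval_B, seed = seeds[i])
    }
  }
  primary <- run$log$primary
  scores <- list(cvd = score_cohort(models[[primary]]$cvd, ext_cc),
                 sae = score_cohort(models[[primary]]$sae, ext_cc))
  cutpoints <- list(
    cvd = tertile_cutpoints(c(run$scores$cvd$difference, scores$cvd$difference)),
    sae = tertile_cutpoints(c(run$scores$sae$difference, scores$sae$difference)))
  subgroup_tables <- list(
    derivation = list(
      cvd = subgroup_table(run$scores$cvd, run$data,
                           run$models[[primary]]$cvd, cutpoints$cvd),
      sae = subgroup_table(run$scores$sae, run$data,
                           run$models[[primary]]$sae, cutpoints$sae)),
    validation = list(
      cvd = subgroup_table(scores$cvd, ext_cc, models[[primary]]$cvd,
                           cutpoints$cvd),
      sae = subgroup_table(scores$sae, ext_cc, models[[primary]]$sae,
                           cutpoints$sae)))
  cross <- list(
    derivation = cross_classify(
      assign_subgroups(run$scores$cvd$difference, cutpoints$cvd),
      assign_subgroups(run$scores$sae$difference, cutpoints$sae)),
    validation = cross_classify(
      assign_subgroups(scores$cvd$difference, cutpoints$cvd),
      assign_subgroups(scores$sae$difference, cutpoints$sae)))
  run$validation <- list(
    models = models, evaluation = evaluation, scores = scores,
    cutpoints = cutpoints, subgroup_tables = subgroup_tables,
    cross_classification = cross, data = ext_cc,
    log = list(n_input = nrow(ext_data), n_complete = nrow(ext_cc),
               n_dropped = attr(ext_cc, "n_dropped"), seed = seed))
  run
}

#' Side-by-side comparison of selection methods
#'
#' Collects discrimination, calibration slope/intercept and GND p for every
#' method, outcome, and cohort present in a run, flagging models that fail
#' the GND calibration test at the 0.05 level.
#'
#' @param run a [run_derivation()] result, optionally with validation.
#' @return data frame with one row per cohort x outcome x method.
#' @export
compare_selection_methods <- function(run) {
  stopifnot(inherits(run, "bp_run"))
  collect <- function(evals, cohort) {
    do.call(rbind, lapply(names(evals), function(method) {
      do.call(rbind, lapply(names(evals[[method]]), function(outcome) {
        ev <- evals[[method]][[outcome]]
        data.frame(cohort = cohort, outcome = outcome, method = method,
                   c_statistic = ev$c_statistic$c,
                   slope = ev$calibration$slope,
                   intercept = ev$calibration$intercept,
                   gnd_p = ev$gnd$p,
                   gnd_fail = ev$gnd$p < 0.05)
      }))
    }))
  }
  out <- collect(run$evaluation, "derivation")
  if (!is.null(run$validation))
    out <- rbind(out, collect(run$validation$evaluation, "validation"))
  rownames(out) <- NULL
  out
}

#' Write the main run outputs to a directory
#'
#' Emits the comparison table and subgroup tables as CSV, the fitted models
#' as JSON, and a small JSON run log. Only plain-text formats are written.
#'
#' @param run a `bp_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(compare_selection_methods(run),
                   file.path(dir, "method_comparison.csv"), row.names = FALSE)
  for (method in names(run$models))
    for (outcome in names(run$models[[method]]))
      write_model_json(run$models[[method]][[outcome]],
                       file.path(dir, sprintf("model_%s_%s.json", method, outcome)))
  if (!is.null(run$validation)) {
    for (cohort in names(run$validation$subgroup_tables))
      for (outcome in names(run$validation$subgroup_tables[[cohort]]))
        utils::write.csv(
          as.data.frame(run$validation$subgroup_tables[[cohort]][[outcome]]),
          file.path(dir, sprintf("subgroups_%s_%s.csv", cohort, outcome)),
          row.names = FALSE)
  }
  jsonlite::write_json(run$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
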