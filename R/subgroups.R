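#' Tertile cut points of predicted benefit or harm
#'
#' Empirical 1/3 and 2/3 quantiles of the supplied predicted values, by the
#' linear-interpolation quantile convention (type 7). The main analysis
#' pools predicted values from the derivation and validation cohorts before
#' cutting; per-cohort cut points are the sensitivity alternative — pass one
#' cohort's values instead.
#'
#' @param values numeric predicted benefit or harm values (one or more
#'   cohorts concatenated).
#' @return named numeric vector `c(c1, c2)`.
#' @export
tertile_cutpoints <- function(values) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 3)
    stop("need at least 3 distinct values to form tertiles")
  stats::setNames(stats::quantile(values, c(1, 2) / 3, type = 7, names = FALSE),
                  c("c1", "c2"))
}

#' @rdname tertile_cutpoints
#' @param cutpoints output of `tertile_cutpoints()`.
#' @return `assign_subgroups()` returns integer labels 1 (lowest predicted
#'   value), 2, 3 (highest).
#' @export
assign_subgroups <- function(values, cutpoints) {
  findInterval(values, cutpoints) + 1L
}

#' Observed between-arm risk difference at a horizon
#'
#' Kaplan-Meier risk in each arm at `tstar`, differenced as intensive minus
#' standard; the confidence interval is the normal interval with the sum of
#' the two Greenwood variances, and the p-value comes from the two-arm
#' log-rank test within the subset.
#'
#' @param data trial dataset subset (both arms must be present).
#' @param outcome `"cvd"` or `"sae"`.
#' @param tstar horizon in years.
#' @param level confidence level.
#' @return list with `difference`, `lower`, `upper`, `p`, per-arm `risk`,
#'   `n`, `events`.
#' @export
observed_risk_difference <- function(data, outcome = "cvd", tstar = 5,
                                     level = 0.95) {
  cols <- outcome_columns(outcome)
  arms <- data$arm
  if (length(unique(arms)) < 2) stop("both arms must be present in the subset")
  km <- lapply(c(standard = 0, intensive = 1), function(a) {
    sel <- arms == a
    km_risk(data[[cols["time"]]][sel], data[[cols["event"]]][sel], tstar)
  })
  diff <- km$intensive$risk - km$standard$risk
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(km$intensive$variance + km$standard$variance)
  sd_fit <- survival::survdiff(
    survival::Surv(data[[cols["time"]]], data[[cols["event"]]]) ~ arms)
  p <- stats::pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)
  list(difference = diff, lower = diff - z * se, upper = diff + z * se, p = p,
       risk = c(standard = km$standard$risk, intensive = km$intensive$risk),
       n = c(standard = sum(arms == 0), intensive = sum(arms == 1)),
       events = c(standard = km$standard$n_events,
                  intensive = km$intensive$n_events))
}

#' Number needed to treat / harm
#'
#' Reciprocal of an absolute risk difference. The unrounded reciprocal is
#' the primary output (printed NNT/NNH values elsewhere are not always
#' consistent with reciprocals of rounded risk differences); the
#' nearest-integer value is secondary. A zero difference is flagged as not
#' estimable.
#'
#' @param difference absolute risk difference (ARR or ARI).
#' @return list with `unrounded`, `rounded`, `estimable`, and `sign` of the
#'   input difference.
#' @export
nnt_nnh <- function(difference) {
  if (!is.finite(difference) || difference == 0)
    return(list(unrounded = NA_real_, rounded = NA_integer_,
                estimable = FALSE, sign = 0))
  list(unrounded = 1 / abs(difference),
       rounded = as.integer(round(1 / abs(difference))),
       estimable = TRUE, sign = sign(difference))
}

#' Trend in treatment effect across ordered subgroups
#'
#' Score-type test for a treatment-by-ordinal-subgroup interaction in a Cox
#' model stratified by subgroup: `Surv ~ arm + arm:ordinal + strata(group)`,
#' an implementation of the stratified log-rank trend test. The p-value is
#' the Wald p for the interaction coefficient; the construction is recorded
#' in the output.
#'
#' @param data trial dataset.
#' @param subgroup ordered integer subgroup labels (1, 2, 3, ...).
#' @param outcome `"cvd"` or `"sae"`.
#' @return list with `p`, `coef` (interaction log-hazard per subgroup step),
#'   `method`.
#' @export
trend_test <- function(data, subgroup, outcome = "cvd") {
  cols <- outcome_columns(outcome)
  keep <- rep(TRUE, nrow(data))
  for (gid in unique(subgroup)) {
    sel <- subgroup == gid
    if (length(unique(data$arm[sel])) < 2 ||
        sum(data[[cols["event"]]][sel]) == 0) {
      warning("subgroup ", gid, " is degenerate (single arm or no events); excluded")
      keep[sel] <- FALSE
    }
  }
  d <- data[keep, , drop = FALSE]
  g <- subgroup[keep]
  if (length(unique(g)) < 2) stop("trend test needs at least 2 ordered subgroups")
  df <- data.frame(time = d[[cols["time"]]], event = d[[cols["event"]]],
                   arm = d$arm, ord = as.numeric(g), g = factor(g))
  fit <- survival::coxph(
    survival::Surv(time, event) ~ arm + arm:ord + survival::strata(g),
    data = df, ties = "breslow")
  sm <- summary(fit)$coefficients
  row <- grep("arm:ord", rownames(sm))
  list(p = sm[row, "Pr(>|z|)"], coef = sm[row, "coef"],
       method = "Wald test for treatment x ordinal-subgroup interaction in a subgroup-stratified Cox model")
}

#' Subgroup table of expected and observed risk differences
#'
#' For each predicted benefit/harm tertile: arm sizes, event counts by `tstar`,
#' the expected risk difference (mean of the members' predicted
#' intensive-minus-standard differences, with the 2.5-97.5 percentile band
#' of the individual predictions), the observed Kaplan-Meier risk difference
#' with Greenwood CI and log-rank p, expected minus observed, and NNT/NNH
#' computed from the observed difference. Differences are reported as
#' intensive minus standard for both outcomes, so negative values in a
#' benefit (CVD) table mean risk reduction and positive values in a harm
#' (adverse event) table mean risk increase.
#'
#' @param scores [score_cohort()] table for the cohort being tabulated.
#' @param data matching trial dataset (aligned rows).
#' @param model the [bp_risk_model] that produced the scores (supplies the
#'   outcome and sign convention).
#' @param cutpoints tertile cut points, typically from the pooled cohorts.
#' @param tstar horizon.
#' @return data frame of class `bp_subgroup_table`, one row per subgroup,
#'   with the trend-test p-value in attribute `trend_p`.
#' @export
subgroup_table <- function(scores, data, model, cutpoints,
                           tstar = model$horizon) {
  stopifnot(nrow(scores) == nrow(data))
  # predicted difference on the intensive-minus-standard scale
  pred_diff <- if (model$direction == "benefit") -scores$difference
               else scores$difference
  g <- assign_subgroups(scores$difference, cutpoints)
  rows <- lapply(sort(unique(g)), function(gid) {
    sel <- g == gid
    sub <- data[sel, , drop = FALSE]
    # degenerate cells (an arm absent, as can happen in tiny extreme
    # subgroups) get NA observations rather than aborting the table
    obs <- tryCatch(
      observed_risk_difference(sub, outcome = model$outcome, tstar = tstar),
      error = function(e) list(
        difference = NA_real_, lower = NA_real_, upper = NA_real_,
        p = NA_real_,
        n = c(standard = sum(sub$arm == 0), intensive = sum(sub$arm == 1)),
        events = c(standard = NA_integer_, intensive = NA_integer_)))
    exp_mean <- mean(pred_diff[sel])
    exp_band <- stats::quantile(pred_diff[sel], c(0.025, 0.975), names = FALSE)
    nn <- nnt_nnh(obs$difference)
    data.frame(
      subgroup = gid,
      n_intensive = obs$n[["intensive"]], n_standard = obs$n[["standard"]],
      events_intensive = obs$events[["intensive"]],
      events_standard = obs$events[["standard"]],
      expected = exp_mean, expected_lower = exp_band[1],
      expected_upper = exp_band[2],
      observed = obs$difference, observed_lower = obs$lower,
      observed_upper = obs$upper, p = obs$p,
      expected_minus_observed = exp_mean - obs$difference,
      nnt_nnh = nn$unrounded, nnt_nnh_rounded = nn$rounded)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  tr <- tryCatch(trend_test(data, g, outcome = model$outcome),
                 error = function(e) list(p = NA_real_))
  attr(out, "trend_p") <- tr$p
  attr(out, "outcome") <- model$outcome
  attr(out, "direction") <- model$direction
  class(out) <- c("bp_subgroup_table", class(out))
  out
}

#' Cross-classification of benefit and harm subgroups
#'
#' 3 x 3 contingency table of predicted-benefit by predicted-harm subgroup
#' membership, with percentages and the two headline combinations: members
#' of the upper two benefit subgroups who fall in the lowest harm subgroup,
#' and members of the lowest benefit subgroup who fall in the upper two harm
#' subgroups.
#'
#' @param benefit_groups,harm_groups aligned integer subgroup labels from
#'   [assign_subgroups()].
#' @return list with `counts` (matrix, benefit rows x harm columns),
#'   `percent`, `n`, `high_benefit_low_harm` and `low_benefit_high_harm`
#'   (each a list with `n` and `percent`).
#' @export
cross_classify <- function(benefit_groups, harm_groups) {
  if (length(benefit_groups) != length(harm_groups))
    stop("benefit and harm subgroup labels must have the same length")
  n <- length(benefit_groups)
  counts <- table(factor(benefit_groups, levels = 1:3),
                  factor(harm_groups, levels = 1:3))
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = list(benefit = 1:3, harm = 1:3))
  hb_lh <- sum(counts[2:3, 1])
  lb_hh <- sum(counts[1, 2:3])
  list(counts = counts, percent = 100 * counts / n, n = n,
       high_benefit_low_harm = list(n = hb_lh, percent = 100 * hb_lh / n),
       low_benefit_high_harm = list(n = lb_hh, percent = 100 * lb_hh / n))
}
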