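#' Kaplan-Meier risk at a horizon with Greenwood variance
#'
#' Product-limit estimate of the event probability by `tstar` and the
#' Greenwood variance of the survival estimate (which equals the variance of
#' the risk). Computed directly from the risk-set counts so the same
#' quantities feed the calibration table and the GND statistic.
#'
#' @param time,event outcome columns.
#' @param tstar horizon (> 0).
#' @return list with `risk`, `variance`, and `n_events` (events by `tstar`).
#' @export
km_risk <- function(time, event, tstar) {
  stopifnot(tstar > 0)
  if (!length(time)) stop("no subjects at risk")
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]
  n <- length(t_s)
  first <- match(t_s, t_s)          # first index of each tie group
  sel <- e_s == 1 & t_s <= tstar
  if (!any(sel)) return(list(risk = 0, variance = 0, n_events = 0L))
  d <- tapply(rep(1L, sum(sel)), first[sel], sum)
  idx <- as.integer(names(d))
  n_at <- n - idx + 1               # at risk at each distinct event time
  d <- as.numeric(d)
  surv <- prod(1 - d / n_at)
  gw <- sum(ifelse(n_at > d, d / (n_at * (n_at - d)), 0))
  variance <- if (surv == 0) 0 else surv^2 * gw
  list(risk = 1 - surv, variance = variance, n_events = sum(sel))
}

#' Harrell's concordance for predicted risks
#'
#' Concordance between predicted risk ordering and observed survival for
#' right-censored data (higher predicted risk should mean earlier events),
#' with a seeded bootstrap percentile confidence interval.
#'
#' @param pred predicted risks (any strictly monotone transform of the
#'   linear predictor gives the same value).
#' @param time,event outcome columns.
#' @param ci compute a bootstrap CI.
#' @param B bootstrap replicates (default 1000).
#' @param level confidence level.
#' @param seed integer seed for the resampling.
#' @return list with `c`, `lower`, `upper`, `method`.
#' @export
concordance_index <- function(pred, time, event, ci = TRUE, B = 1000,
                              level = 0.95, seed = 1) {
  stopifnot(length(pred) == length(time), length(time) >= 2)
  if (sum(event) < 1) stop("concordance needs at least one event")
  cstat <- function(p, t, e) {
    fit <- survival::concordance(survival::Surv(t, e) ~ p, reverse = TRUE)
    if (sum(fit$count[c("concordant", "discordant", "tied.x")]) == 0)
      stop("no comparable pairs")
    unname(fit$concordance)
  }
  est <- cstat(pred, time, event)
  out <- list(c = est, lower = NA_real_, upper = NA_real_,
              method = "bootstrap percentile")
  if (ci) {
    boots <- with_rng_seed(seed, {
      vapply(seq_len(B), function(b) {
        idx <- sample.int(length(pred), replace = TRUE)
        if (sum(event[idx]) == 0) return(NA_real_)
        cstat(pred[idx], time[idx], event[idx])
      }, numeric(1))
    })
    qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE)
    out$lower <- unname(qs[1]); out$upper <- unname(qs[2])
    out$B <- B
  }
  out
}

#' Decile calibration table
#'
#' Groups subjects by quantiles of predicted risk (deciles by default),
#' computes each group's mean predicted risk and Kaplan-Meier observed risk
#' at the horizon with Greenwood variance, merges adjacent groups until
#' every retained group has at least `min_events` observed events, and fits
#' the calibration line (observed on predicted group risks) by unweighted
#' least squares (inverse-variance weighting by option).
#'
#' @param pred predicted risks.
#' @param time,event outcome columns.
#' @param tstar horizon.
#' @param groups number of quantile groups (default 10).
#' @param min_events minimum observed events per retained group (default 5);
#'   sparser groups are merged into their upper neighbor (lower neighbor for
#'   the last group) and the merges logged.
#' @param weighted use inverse-variance weights for the calibration line.
#' @return object of class `bp_calibration`: list with `table` (n, events,
#'   predicted, observed, variance per group), `slope`, `intercept`,
#'   `merge_log`, `degenerate` (TRUE when all predictions were equal).
#' @export
calibration_deciles <- function(pred, time, event, tstar, groups = 10,
                                min_events = 5, weighted = FALSE) {
  stopifnot(length(pred) == length(time), length(pred) >= groups)
  breaks <- unique(stats::quantile(pred, seq(0, 1, length.out = groups + 1),
                                   type = 7))
  degenerate <- length(breaks) < 3
  g <- if (degenerate) rep(1L, length(pred))
       else as.integer(cut(pred, breaks, include.lowest = TRUE))
  merge_log <- character()
  repeat {
    ids <- sort(unique(g))
    ev_by_g <- vapply(ids, function(i)
      sum(event[g == i] == 1 & time[g == i] <= tstar), integer(1))
    short <- ids[ev_by_g < min_events]
    if (!length(short) || length(ids) == 1) break
    i <- short[1]
    target <- if (i == max(ids)) max(ids[ids < i]) else min(ids[ids > i])
    merge_log <- c(merge_log,
                   sprintf("merged group %d (%d events) into group %d",
                           i, ev_by_g[match(i, ids)], target))
    g[g == i] <- target
  }
  ids <- sort(unique(g))
  tab <- do.call(rbind, lapply(ids, function(i) {
    sel <- g == i
    km <- km_risk(time[sel], event[sel], tstar)
    data.frame(group = i, n = sum(sel), events = km$n_events,
               predicted = mean(pred[sel]), observed = km$risk,
               variance = km$variance)
  }))
  rownames(tab) <- NULL
  slope <- intercept <- NA_real_
  if (nrow(tab) >= 2 && stats::sd(tab$predicted) > 0) {
    w <- if (weighted) ifelse(tab$variance > 0, 1 / tab$variance, 0) else NULL
    fit <- stats::lm(observed ~ predicted, data = tab, weights = w)
    intercept <- unname(stats::coef(fit)[1])
    slope <- unname(stats::coef(fit)[2])
  }
  structure(list(table = tab, slope = slope, intercept = intercept,
                 merge_log = merge_log, degenerate = degenerate,
                 tstar = tstar),
            class = "bp_calibration")
}

#' Greenwood-Nam-D'Agostino calibration test
#'
#' Chi-square statistic comparing the Kaplan-Meier observed risk with the
#' mean predicted risk in each calibration group, each squared discrepancy
#' scaled by the group's Greenwood variance:
#' `chi2 = sum_g (observed_g - predicted_g)^2 / variance_g`, referred to a
#' chi-square distribution with G - 1 degrees of freedom.
#'
#' @param calibration a [calibration_deciles()] result (groups already
#'   merged to the event minimum).
#' @return list with `chi2`, `df`, `p`, `groups`.
#' @export
gnd_test <- function(calibration) {
  stopifnot(inherits(calibration, "bp_calibration"))
  tab <- calibration$table
  if (nrow(tab) < 2) stop("GND test needs at least 2 retained groups")
  if (any(tab$variance <= 0))
    stop("GND test undefined with a zero-variance group; lower the group ",
         "count or raise min_events so every group has events")
  chi2 <- sum((tab$observed - tab$predicted)^2 / tab$variance)
  df <- nrow(tab) - 1
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       groups = nrow(tab))
}

#' Discrimination and calibration report for one model on one cohort
#'
#' Predicted risk is the model's absolute risk under each participant's
#' actual randomized arm (the full functional form of the model). Reports
#' Harrell's C with bootstrap CI, the decile calibration slope and
#' intercept, and the GND test.
#'
#' @param model a [bp_risk_model].
#' @param data trial dataset.
#' @param label cohort label carried into the report.
#' @param B bootstrap replicates for the C-statistic CI.
#' @param seed seed for the bootstrap.
#' @param groups,min_events calibration grouping controls.
#' @return list of class `bp_evaluation` with `c_statistic`, `calibration`,
#'   `gnd`, `label`, `n`, `events`.
#' @export
evaluate_model <- function(model, data, label = "", B = 200, seed = 1,
                           groups = 10, min_events = 5) {
  cols <- outcome_columns(model$outcome)
  pred <- absolute_risk(model, raw_score(model, data, arm = data$arm))
  time <- data[[cols["time"]]]
  event <- data[[cols["event"]]]
  cs <- concordance_index(pred, time, event, B = B, seed = seed)
  cal <- calibration_deciles(pred, time, event, tstar = model$horizon,
                             groups = groups, min_events = min_events)
  structure(list(c_statistic = cs, calibration = cal, gnd = gnd_test(cal),
                 label = label, n = nrow(data), events = sum(event)),
            class = "bp_evaluation")
}

#' @exportS3Method base::print
print.bp_evaluation <- function(x, ...) {
  cat(sprintf("Evaluation%s (n = %d, events = %d)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$n, x$events))
  cat(sprintf("  Discrimination        %.3f (95%% CI %.3f, %.3f)\n",
              x$c_statistic$c, x$c_statistic$lower, x$c_statistic$upper))
  cat(sprintf("  Calibration slope     %.3f\n", x$calibration$slope))
  cat(sprintf("  Calibration intercept %.4f\n", x$calibration$intercept))
  cat(sprintf("  GND P value           %.3f (chi2 = %.2f, df = %d)\n",
              x$gnd$p, x$gnd$chi2, x$gnd$df))
  invisible(x)
}
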