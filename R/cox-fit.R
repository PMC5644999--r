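#' Model design: main effects and treatment interactions
#'
#' Declares the term structure of the benefit/harm Cox models: one main
#' effect per candidate predictor, an intensive-treatment indicator (always
#' present, never penalized), and a treatment-by-covariate interaction for
#' each covariate in `interaction`. Every interaction's covariate must also
#' appear as a main effect.
#'
#' @param main character vector of main-effect covariate names.
#' @param interaction covariates receiving a treatment interaction term
#'   (default: all main effects).
#' @param treatment name of the 0/1 treatment column (default `"arm"`).
#' @return object of class `bp_design`.
#' @export
design_spec <- function(main, interaction = main, treatment = "arm") {
  stopifnot(is.character(main), length(main) > 0)
  orphan <- setdiff(interaction, main)
  if (length(orphan))
    stop("interaction terms need a matching main effect: ",
         paste(orphan, collapse = ", "))
  if (treatment %in% main)
    stop("the treatment indicator cannot also be a main-effect covariate")
  structure(list(main = main, interaction = interaction,
                 treatment = treatment),
            class = "bp_design")
}

#' @rdname design_spec
#' @param spec a [covariate_spec]; convenience builder using every variable
#'   as both main effect and interaction, as in the candidate-predictor set.
#' @export
design_from_spec <- function(spec, treatment = "arm") {
  design_spec(names(spec$variables), treatment = treatment)
}

# expand a dataset into the model design matrix; interaction columns are
# named "<treatment>:<covariate>"
build_design_matrix <- function(data, design) {
  missing <- setdiff(c(design$main, design$treatment), names(data))
  if (length(missing))
    stop("dataset is missing design columns: ", paste(missing, collapse = ", "))
  tr <- data[[design$treatment]]
  x_main <- as.matrix(data[design$main])
  x_int <- matrix(numeric(0), nrow(x_main), 0)
  if (length(design$interaction)) {
    x_int <- x_main[, design$interaction, drop = FALSE] * tr
    colnames(x_int) <- paste0(design$treatment, ":", design$interaction)
  }
  x <- cbind(x_main, matrix(tr, ncol = 1, dimnames = list(NULL, design$treatment)), x_int)
  penalty <- c(rep(1, length(design$main)), 0, rep(1, length(design$interaction)))
  list(x = x, penalty = penalty)
}

#' Elastic-net cross-validation settings
#'
#' @param alpha elastic-net mixing parameter in \[0, 1\] (1 = lasso,
#'   0 = ridge); default 0.5 so both penalties are active.
#' @param lambda optional decreasing penalty grid. `NULL` lets the solver
#'   choose; a single value skips cross-validation and fits at that penalty
#'   (0 gives the unpenalized fit).
#' @param nfolds number of cross-validation folds K (>= 2), default 10.
#' @param repeats number of independent fold assignments R whose deviance
#'   curves are averaged, default 10.
#' @param rule penalty choice: `"min"` (minimum mean held-out
#'   partial-likelihood deviance) or `"1se"` (largest penalty within one
#'   standard error of the minimum).
#' @param seed integer seed for the fold assignments.
#' @return object of class `bp_penalty`.
#' @export
penalty_config <- function(alpha = 0.5, lambda = NULL, nfolds = 10,
                           repeats = 10, rule = c("min", "1se"), seed = 1) {
  rule <- match.arg(rule)
  stopifnot(alpha >= 0, alpha <= 1, nfolds >= 2, repeats >= 1)
  if (!is.null(lambda)) {
    stopifnot(all(lambda >= 0))
    lambda <- sort(unique(lambda), decreasing = TRUE)
  }
  structure(list(alpha = alpha, lambda = lambda, nfolds = nfolds,
                 repeats = repeats, rule = rule, seed = seed),
            class = "bp_penalty")
}

#' Fit a penalized Cox model with internal cross-validation
#'
#' Elastic-net penalized partial likelihood over the design's penalized
#' terms (all main effects and interactions; the treatment main effect is
#' never penalized and is always retained). Covariates are standardized
#' internally and coefficients returned on the original scale. The penalty
#' strength is chosen by R-times-repeated K-fold cross-validation minimizing
#' the held-out partial-likelihood deviance, averaging the deviance curves
#' over fold assignments. After fitting, the baseline survival `s0` and
#' centering constant `lbar` are computed on the derivation data by
#' [breslow_baseline()].
#'
#' @param data complete-case trial dataset.
#' @param design a [design_spec()].
#' @param penalty a [penalty_config()].
#' @param outcome `"cvd"` or `"sae"`.
#' @param horizon risk horizon in years.
#' @param units unit system of the dataset (recorded in the model).
#' @return a fitted model of class `c("bp_cox_fit", "bp_risk_model")`; the
#'   chosen penalty, mixing parameter and averaged CV curve are in `meta`.
#' @export
fit_penalized_cox <- function(data, design, penalty = penalty_config(),
                              outcome = c("cvd", "sae"), horizon = 5,
                              units = "conventional") {
  outcome <- match.arg(outcome)
  cols <- outcome_columns(outcome)
  dm <- build_design_matrix(data, design)
  time <- data[[cols["time"]]]
  event <- data[[cols["event"]]]
  if (sum(event) < 2) stop("need at least 2 events to fit")
  y <- survival::Surv(time, event)
  maxit <- 1e6
  cv_mean <- cv_se <- grid <- NULL
  if (!is.null(penalty$lambda) && length(penalty$lambda) == 1) {
    # fixed penalty: solve tightly along a path ending at the requested
    # value so the solution there is exact (0 gives the unpenalized fit)
    chosen <- penalty$lambda
    auto <- glmnet::glmnet(dm$x, y, family = "cox", alpha = penalty$alpha,
                           penalty.factor = dm$penalty, nlambda = 30,
                           standardize = TRUE)$lambda
    path <- sort(unique(c(auto[auto > chosen], chosen)), decreasing = TRUE)
    base_fit <- glmnet::glmnet(dm$x, y, family = "cox", alpha = penalty$alpha,
                               penalty.factor = dm$penalty, lambda = path,
                               standardize = TRUE, thresh = 1e-12,
                               maxit = maxit)
  } else {
    base_fit <- glmnet::glmnet(dm$x, y, family = "cox", alpha = penalty$alpha,
                               penalty.factor = dm$penalty,
                               lambda = penalty$lambda, standardize = TRUE,
                               maxit = maxit)
    grid <- base_fit$lambda
    cvms <- matrix(NA_real_, length(grid), penalty$repeats)
    cvsds <- matrix(NA_real_, length(grid), penalty$repeats)
    with_rng_seed(penalty$seed, {
      for (r in seq_len(penalty$repeats)) {
        foldid <- sample(rep_len(seq_len(penalty$nfolds), nrow(dm$x)))
        cv <- glmnet::cv.glmnet(dm$x, y, family = "cox",
                                alpha = penalty$alpha,
                                penalty.factor = dm$penalty,
                                lambda = grid, foldid = foldid,
                                type.measure = "deviance",
                                standardize = TRUE, maxit = maxit)
        m <- match(cv$lambda, grid)
        cvms[m, r] <- cv$cvm
        cvsds[m, r] <- cv$cvsd
      }
    })
    cv_mean <- rowMeans(cvms, na.rm = TRUE)
    cv_se <- rowMeans(cvsds, na.rm = TRUE)
    ok <- which(is.finite(cv_mean))
    if (!length(ok)) stop("cross-validation produced no usable deviance values")
    i_min <- ok[which.min(cv_mean[ok])]
    chosen <- if (penalty$rule == "min") grid[i_min] else {
      within_se <- cv_mean[ok] <= cv_mean[i_min] + cv_se[i_min]
      max(grid[ok][within_se])
    }
  }
  cf <- stats::coef(base_fit, s = chosen)
  beta <- stats::setNames(as.numeric(cf), rownames(cf))
  new_cox_fit(beta, design, data, outcome, horizon, units,
              meta = list(selection = "elastic_net", alpha = penalty$alpha,
                          lambda = chosen, cv_rule = penalty$rule,
                          cv_lambda = grid, cv_deviance = cv_mean,
                          cv_se = cv_se, ties = "breslow",
                          n = nrow(data), events = sum(event)))
}

#' Backwards AIC model selection
#'
#' Starts from the full design fitted by [survival::coxph()] and repeatedly
#' considers the eligible term with the largest Wald p-value, removing it if
#' the removal lowers the AIC (`-2 pl + 2k`), stopping at a local minimum.
#' Interactions are eligible immediately; a main effect only becomes
#' eligible once its interaction has been removed (hierarchy), and the
#' treatment main effect is never removed.
#'
#' @inheritParams fit_penalized_cox
#' @param ties tie handling passed to [survival::coxph()] (`"breslow"`, the
#'   package default for internal consistency with the penalized fit and the
#'   baseline estimator, or `"efron"`).
#' @return a fitted `c("bp_cox_fit", "bp_risk_model")`; removed terms keep
#'   exact zero coefficients. `meta$aic_trace` records each removal.
#' @export
fit_backwards_aic <- function(data, design, outcome = c("cvd", "sae"),
                              horizon = 5, units = "conventional",
                              ties = c("breslow", "efron")) {
  outcome <- match.arg(outcome)
  ties <- match.arg(ties)
  cols <- outcome_columns(outcome)
  dm <- build_design_matrix(data, design)
  n_events <- sum(data[[cols["event"]]])
  if (n_events <= ncol(dm$x))
    stop("fewer events (", n_events, ") than model terms (", ncol(dm$x), ")")
  df <- as.data.frame(dm$x)
  df$.time <- data[[cols["time"]]]
  df$.event <- data[[cols["event"]]]
  int_terms <- paste0(design$treatment, ":", design$interaction)
  fit_terms <- function(terms) {
    fml <- stats::as.formula(paste(
      "survival::Surv(.time, .event) ~",
      paste(sprintf("`%s`", terms), collapse = " + ")))
    survival::coxph(fml, data = df, ties = ties)
  }
  terms <- colnames(dm$x)
  fit <- fit_terms(terms)
  if (any(is.na(stats::coef(fit))))
    stop("full model is singular; collinear terms: ",
         paste(names(which(is.na(stats::coef(fit)))), collapse = ", "))
  trace <- data.frame(step = 0L, dropped = NA_character_, aic = stats::AIC(fit))
  step_i <- 0L
  repeat {
    present_int <- intersect(int_terms, terms)
    protected_main <- design$interaction[paste0(design$treatment, ":",
                                                design$interaction) %in% present_int]
    eligible <- setdiff(terms, c(design$treatment, protected_main))
    if (!length(eligible)) break
    ptab <- summary(fit)$coefficients
    pvals <- ptab[gsub("`", "", rownames(ptab)) %in% eligible, "Pr(>|z|)"]
    names(pvals) <- gsub("`", "", rownames(ptab))[gsub("`", "", rownames(ptab)) %in% eligible]
    candidate <- names(which.max(pvals))
    reduced <- fit_terms(setdiff(terms, candidate))
    if (stats::AIC(reduced) < stats::AIC(fit)) {
      terms <- setdiff(terms, candidate)
      fit <- reduced
      step_i <- step_i + 1L
      trace <- rbind(trace, data.frame(step = step_i, dropped = candidate,
                                       aic = stats::AIC(fit)))
    } else break
  }
  beta <- stats::setNames(rep(0, ncol(dm$x)), colnames(dm$x))
  kept <- gsub("`", "", names(stats::coef(fit)))
  beta[kept] <- as.numeric(stats::coef(fit))
  vc <- stats::vcov(fit)
  dimnames(vc) <- list(kept, kept)
  new_cox_fit(beta, design, data, outcome, horizon, units,
              meta = list(selection = "backwards_aic", ties = ties,
                          aic = stats::AIC(fit), aic_trace = trace,
                          vcov = vc, n = nrow(data), events = n_events))
}

# assemble the shared model container from a named coefficient vector over
# the design-matrix columns
new_cox_fit <- function(beta, design, data, outcome, horizon, units, meta) {
  meta$treatment <- design$treatment
  int_prefix <- paste0(design$treatment, ":")
  is_int <- startsWith(names(beta), int_prefix)
  coef_main <- beta[names(beta) %in% design$main]
  coef_treatment <- beta[[design$treatment]]
  coef_interaction <- beta[is_int]
  names(coef_interaction) <- sub(int_prefix, "", names(coef_interaction), fixed = TRUE)
  model <- bp_risk_model(
    name = paste(outcome, meta$selection, sep = "_"),
    outcome = outcome,
    direction = if (outcome == "cvd") "benefit" else "harm",
    coef_main = coef_main, coef_treatment = coef_treatment,
    coef_interaction = coef_interaction,
    s0 = 0.5, lbar = 0,  # placeholders, replaced below
    horizon = horizon, units = units, meta = meta)
  cols <- outcome_columns(outcome)
  lp <- raw_score(model, data, arm = data[[design$treatment]])
  bl <- breslow_baseline(data[[cols["time"]]], data[[cols["event"]]], lp, horizon)
  model$s0 <- min(max(bl$s0, 1e-12), 1 - 1e-12)
  model$lbar <- bl$lbar
  model$meta$baseline_truncated <- bl$truncated
  class(model) <- c("bp_cox_fit", class(model))
  model
}

#' Hazard-ratio reporting table
#'
#' Exponentiated coefficients with Wald 95% confidence intervals for every
#' retained (nonzero) term of a fitted model; dropped terms are omitted.
#' Backwards-selected fits reuse the stored model-based covariance; for
#' penalized fits standard errors come from the observed information of the
#' unpenalized partial likelihood evaluated at the (shrunken) estimates, a
#' descriptive rather than inferential quantity.
#'
#' @param model a fitted `bp_cox_fit`.
#' @param data the dataset the model was fit to (needed to rebuild the
#'   design matrix when no covariance is stored).
#' @return data frame with `term`, `coef`, `hr`, `lower`, `upper`.
#' @export
hazard_ratio_table <- function(model, data) {
  stopifnot(inherits(model, "bp_cox_fit"))
  tr <- if (!is.null(model$meta$treatment)) model$meta$treatment else "arm"
  ints <- model$coef_interaction
  if (length(ints)) names(ints) <- paste0(tr, ":", names(ints))
  beta <- c(model$coef_main, stats::setNames(model$coef_treatment, tr), ints)
  nz <- beta[beta != 0 | names(beta) == tr]
  if (!is.null(model$meta$vcov)) {
    se <- sqrt(diag(as.matrix(model$meta$vcov)))[names(nz)]
  } else {
    design <- design_spec(names(model$coef_main),
                          interaction = names(model$coef_interaction),
                          treatment = tr)
    dm <- build_design_matrix(data, design)
    cols <- outcome_columns(model$outcome)
    x <- dm$x[, names(nz), drop = FALSE]
    pl <- cox_partial_loglik(x, data[[cols["time"]]], data[[cols["event"]]],
                             unname(nz), hessian = TRUE)
    se <- sqrt(diag(solve(-pl$hessian)))
    names(se) <- names(nz)
  }
  z <- stats::qnorm(0.975)
  data.frame(term = names(nz), coef = unname(nz), hr = exp(unname(nz)),
             lower = exp(unname(nz) - z * se[names(nz)]),
             upper = exp(unname(nz) + z * se[names(nz)]),
             row.names = NULL)
}
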