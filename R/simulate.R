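#' 1:1 permuted treatment assignment
#'
#' Randomizes `n` participants to standard (0) or intensive (1) treatment by
#' permuting a perfectly balanced vector, so arm counts are `ceiling(n/2)`
#' and `floor(n/2)` exactly. Deterministic given `seed`.
#'
#' @param n number of participants.
#' @param seed integer seed.
#' @return integer vector of 0/1 arms.
#' @export
assign_treatment <- function(n, seed = NULL) {
  stopifnot(n >= 0)
  if (n == 0) return(integer(0))
  with_rng_seed(seed, sample(rep_len(c(0L, 1L), n)))
}

#' Ground-truth data-generating model for synthetic trials
#'
#' Holds, for each composite outcome, the generator-side proportional-hazards
#' truth: main-effect log-hazard coefficients, the intensive-treatment main
#' effect, treatment-by-covariate interaction log-hazards, and a closed-form
#' baseline cumulative hazard `H0(t) = rate * t^shape` (shape 1 is the
#' exponential special case used by the closed-form oracles). Covariates may
#' be centered/scaled before entering the linear predictor via the `center`
#' and `scale` vectors (the presets use spec means and, for continuous
#' variables, spec SDs, so their coefficients read as per-SD log-hazards).
#'
#' @param cvd,sae outcome components from [true_outcome_model()]; either may
#'   be omitted.
#' @param center,scale optional named vectors applied as `(x - center)/scale`
#'   to every covariate named in them before multiplying by coefficients.
#' @return object of class `bp_true_model`.
#' @export
true_model <- function(cvd = NULL, sae = NULL, center = NULL, scale = NULL) {
  outcomes <- Filter(Negate(is.null), list(cvd = cvd, sae = sae))
  if (!length(outcomes)) stop("at least one outcome model is required")
  structure(list(outcomes = outcomes, center = center, scale = scale),
            class = "bp_true_model")
}

#' @rdname true_model
#' @param coef named main-effect log-hazard coefficients.
#' @param treatment intensive-treatment main-effect log-hazard.
#' @param interaction named treatment-by-covariate interaction log-hazards.
#' @param baseline_rate,baseline_shape Weibull baseline cumulative hazard
#'   parameters, `H0(t) = rate * t^shape`; both must be positive.
#' @export
true_outcome_model <- function(coef = numeric(), treatment = 0,
                               interaction = numeric(),
                               baseline_rate, baseline_shape = 1) {
  stopifnot(baseline_rate >= 0, baseline_shape > 0)
  if (length(coef) && is.null(names(coef))) stop("coefficients must be named")
  if (length(interaction) && is.null(names(interaction)))
    stop("interaction coefficients must be named")
  list(coef = coef, treatment = treatment, interaction = interaction,
       baseline_rate = baseline_rate, baseline_shape = baseline_shape)
}

#' Follow-up design for the synthetic trial
#'
#' Staggered accrual over `accrual` years, administrative censoring when the
#' study closes (`target_median + accrual/2` years after the first entry, so
#' the median administrative follow-up equals `target_median`), a hard
#' per-participant horizon of `horizon` years, and non-informative random
#' dropout with a per-year exponential rate.
#'
#' @param accrual accrual window in years (0 = simultaneous entry).
#' @param horizon administrative horizon in years (maximum follow-up).
#' @param dropout_rate per-year exponential dropout rate (0 = none).
#' @param target_median target median administrative follow-up in years.
#' @return object of class `bp_follow_up`.
#' @export
follow_up_spec <- function(accrual = 2, horizon = 5, dropout_rate = 0.02,
                           target_median = 3.3) {
  stopifnot(horizon > 0, dropout_rate >= 0, accrual >= 0)
  if (target_median < accrual / 2)
    stop("target median follow-up shorter than half the accrual window")
  structure(list(accrual = accrual, horizon = horizon,
                 dropout_rate = dropout_rate, target_median = target_median,
                 total_duration = target_median + accrual / 2),
            class = "bp_follow_up")
}

# centered/scaled linear predictor for one outcome; arm enters through the
# treatment main effect and interactions
true_linear_predictor <- function(tm, om, covariates, arm) {
  scale_cov <- function(names_needed) {
    if (!length(names_needed)) return(matrix(0, nrow(covariates), 0))
    unknown <- setdiff(names_needed, names(covariates))
    if (length(unknown))
      stop("unknown covariate in true model coefficients: ",
           paste(unknown, collapse = ", "))
    X <- as.matrix(covariates[names_needed])
    for (nm in names_needed) {
      ctr <- if (!is.null(tm$center) && nm %in% names(tm$center)) tm$center[[nm]] else 0
      scl <- if (!is.null(tm$scale) && nm %in% names(tm$scale)) tm$scale[[nm]] else 1
      X[, nm] <- (X[, nm] - ctr) / scl
    }
    X
  }
  lp <- rep(0, nrow(covariates))
  if (length(om$coef))
    lp <- lp + drop(scale_cov(names(om$coef)) %*% om$coef)
  if (length(om$interaction))
    lp <- lp + arm * drop(scale_cov(names(om$interaction)) %*% om$interaction)
  lp + arm * om$treatment
}

#' Simulate censored outcomes for a randomized cohort
#'
#' Draws event times for each outcome from the proportional-hazards model
#' `hazard(t | X, T) = h0(t) * exp(beta'X + theta*T + gamma'(T*X))` by
#' inverting the closed-form cumulative hazard, then applies random dropout
#' and administrative censoring from the follow-up design. Outcomes are
#' generated conditionally independently given covariates and arm. The
#' observed time is the minimum of event, dropout, and administrative
#' censoring times; the event indicator records which came first.
#'
#' @param covariates covariate data frame (one row per participant).
#' @param arms 0/1 arm vector from [assign_treatment()].
#' @param true_model a [true_model()].
#' @param follow_up a [follow_up_spec()].
#' @param seed integer seed.
#' @return data frame: covariates, `arm`, and `time_<outcome>` /
#'   `event_<outcome>` for each outcome in the model; times in years, capped
#'   at the horizon.
#' @export
simulate_outcomes <- function(covariates, arms, true_model, follow_up,
                              seed = NULL) {
  stopifnot(inherits(true_model, "bp_true_model"),
            inherits(follow_up, "bp_follow_up"),
            nrow(covariates) == length(arms))
  n <- nrow(covariates)
  out <- cbind(covariates, arm = as.integer(arms))
  with_rng_seed(seed, {
    entry <- if (follow_up$accrual > 0) stats::runif(n, 0, follow_up$accrual) else rep(0, n)
    admin <- pmin(follow_up$horizon, follow_up$total_duration - entry)
    dropout <- if (follow_up$dropout_rate > 0)
      stats::rexp(n, follow_up$dropout_rate) else rep(Inf, n)
    censor <- pmin(admin, dropout)
    for (label in names(true_model$outcomes)) {
      om <- true_model$outcomes[[label]]
      lp <- true_linear_predictor(true_model, om, covariates, arms)
      t_event <- if (om$baseline_rate == 0) rep(Inf, n) else {
        e <- stats::rexp(n)  # unit exponential; H(T) = E inverts the c.h.
        (e / (om$baseline_rate * exp(lp)))^(1 / om$baseline_shape)
      }
      obs <- pmin(t_event, censor)
      out[[paste0("time_", label)]] <- pmax(obs, .Machine$double.eps)
      out[[paste0("event_", label)]] <- as.integer(t_event <= censor)
    }
  })
  out
}

#' Ground-truth counterfactual risk difference
#'
#' Closed-form 5-year risk under each arm from the generator's known hazards:
#' `risk(t*, T) = 1 - exp(-H0(t*) * exp(lp(X, T)))`, returned as
#' `risk(intensive) - risk(standard)` (negative values mean intensive
#' treatment reduces risk). The benefit/harm sign conventions of the scoring
#' module are applied by the caller per outcome.
#'
#' @param true_model a [true_model()].
#' @param covariates covariate rows to evaluate.
#' @param horizon horizon in years.
#' @param outcome which outcome's truth to use.
#' @return numeric vector of signed risk differences.
#' @export
true_risk_difference <- function(true_model, covariates, horizon = 5,
                                 outcome = "cvd") {
  stopifnot(inherits(true_model, "bp_true_model"))
  om <- true_model$outcomes[[outcome]]
  if (is.null(om)) stop("true model has no outcome ", outcome)
  covariates <- as.data.frame(covariates)
  H0 <- om$baseline_rate * horizon^om$baseline_shape
  risk_for <- function(arm) {
    lp <- true_linear_predictor(true_model, om, covariates,
                                rep(arm, nrow(covariates)))
    -expm1(-H0 * exp(lp))
  }
  risk_for(1) - risk_for(0)
}
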