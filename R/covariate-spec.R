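#' Covariate specification for the synthetic trial generator
#'
#' Describes the marginal distribution of every candidate predictor together
#' with a latent (Gaussian-copula scale) correlation matrix. Marginals are:
#' `continuous` (truncated normal; `mean`, `sd`, optional `lower`/`upper`),
#' `lognormal` (moment-matched to `mean`/`sd`, for right-skewed positive
#' labs such as triglycerides and the urine albumin/creatinine ratio),
#' `binary` (probability `p`), and `count` (binomial with `max` trials and
#' success probability `mean/max`, so the expectation equals `mean`).
#'
#' Smoking status is a special case: `current_smoker` and `former_smoker`
#' are generated from a single three-level latent variable
#' (never/former/current), which enforces that a participant is never both a
#' current and a former smoker. They therefore share one latent column named
#' `"smoking"` in the correlation matrix.
#'
#' @param variables named list of marginal definitions, each a list with a
#'   `kind` field and the parameters above.
#' @param correlation latent correlation matrix over the latent variable
#'   names ([latent_names()]); `NULL` means independence. Must be symmetric
#'   positive semi-definite with unit diagonal.
#' @return object of class `bp_covariate_spec`.
#' @export
covariate_spec <- function(variables, correlation = NULL) {
  stopifnot(is.list(variables), !is.null(names(variables)))
  for (nm in names(variables)) {
    v <- variables[[nm]]
    kind <- match.arg(v$kind, c("continuous", "lognormal", "binary", "count"))
    if (kind %in% c("continuous", "lognormal")) {
      if (is.null(v$mean) || is.null(v$sd) || v$sd <= 0)
        stop(nm, ": continuous marginals need mean and sd > 0")
    } else if (kind == "binary") {
      if (is.null(v$p) || v$p < 0 || v$p > 1)
        stop(nm, ": binary marginals need p in [0, 1]")
    } else {
      if (is.null(v$mean) || is.null(v$max) || v$mean < 0 || v$mean > v$max)
        stop(nm, ": count marginals need 0 <= mean <= max")
    }
    variables[[nm]]$kind <- kind
  }
  if (all(c("current_smoker", "former_smoker") %in% names(variables))) {
    p_tot <- variables$current_smoker$p + variables$former_smoker$p
    if (p_tot >= 1)
      stop("current_smoker and former_smoker probabilities must sum to < 1")
  }
  spec <- structure(list(variables = variables, correlation = correlation),
                    class = "bp_covariate_spec")
  lat <- latent_names(spec)
  if (is.null(correlation)) {
    correlation <- diag(length(lat))
    dimnames(correlation) <- list(lat, lat)
    spec$correlation <- correlation
  } else {
    if (!is.matrix(correlation) || !setequal(rownames(correlation), lat))
      stop("correlation matrix must be named over the latent variables: ",
           paste(lat, collapse = ", "))
    correlation <- correlation[lat, lat]
    if (max(abs(correlation - t(correlation))) > 1e-10)
      stop("correlation matrix must be symmetric")
    if (any(abs(diag(correlation) - 1) > 1e-10))
      stop("correlation matrix must have unit diagonal")
    if (min(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("correlation matrix is not positive semi-definite")
    spec$correlation <- correlation
  }
  spec
}

#' @rdname covariate_spec
#' @param spec a `bp_covariate_spec`.
#' @return `latent_names()` returns the latent column names: one per
#'   variable, with the smoking pair collapsed to `"smoking"`.
#' @export
latent_names <- function(spec) {
  nm <- names(spec$variables)
  if (all(c("current_smoker", "former_smoker") %in% nm)) {
    nm <- nm[!nm %in% c("current_smoker", "former_smoker")]
    nm <- append(nm, "smoking")
  }
  nm
}

# default latent correlations: plausible clinical structure, overridable
default_latent_correlation <- function(lat) {
  R <- diag(length(lat))
  dimnames(R) <- list(lat, lat)
  set_cor <- function(R, a, b, r) {
    if (all(c(a, b) %in% lat)) { R[a, b] <- r; R[b, a] <- r }
    R
  }
  R <- set_cor(R, "sbp", "dbp", 0.5)
  R <- set_cor(R, "total_chol", "triglycerides", 0.3)
  R <- set_cor(R, "total_chol", "hdl", -0.1)
  R <- set_cor(R, "age", "creatinine", 0.2)
  R
}

#' SPRINT-like and ACCORD-like covariate specifications
#'
#' Preset marginals emulating the pooled baseline characteristics of the two
#' trial populations: a hypertensive non-diabetic cohort (SPRINT-like; mean
#' age 67.9 y, SBP 139.6 mm Hg, 35.4% female) and a younger, heavier type 2
#' diabetes cohort (ACCORD-like; mean age 63.2 y, 48.9% female, higher
#' triglycerides and statin use, almost no current smokers). Right-skewed
#' labs (triglycerides, urine albumin/creatinine ratio) use moment-matched
#' lognormal marginals; the rest are truncated normals with bounds far
#' enough out that the specified means are preserved.
#'
#' @return a [covariate_spec].
#' @export
sprint_covariate_spec <- function() {
  vars <- list(
    age           = list(kind = "continuous", mean = 67.9, sd = 9.4,  lower = 35,  upper = 110),
    female        = list(kind = "binary", p = 0.354),
    black         = list(kind = "binary", p = 0.315),
    hispanic      = list(kind = "binary", p = 0.106),
    sbp           = list(kind = "continuous", mean = 139.6, sd = 15.6, lower = 80, upper = 220),
    dbp           = list(kind = "continuous", mean = 78.2,  sd = 11.9, lower = 35, upper = 135),
    n_bp_agents   = list(kind = "count", mean = 1.8, max = 6),
    current_smoker = list(kind = "binary", p = 0.134),
    former_smoker  = list(kind = "binary", p = 0.426),
    aspirin       = list(kind = "binary", p = 0.511),
    statin        = list(kind = "binary", p = 0.438),
    creatinine    = list(kind = "continuous", mean = 1.1, sd = 0.3, lower = 0.3, upper = 4),
    total_chol    = list(kind = "continuous", mean = 190.1, sd = 41.2, lower = 70, upper = 400),
    hdl           = list(kind = "continuous", mean = 52.8, sd = 14.4, lower = 15, upper = 130),
    triglycerides = list(kind = "lognormal", mean = 126.1, sd = 90.3, lower = 0, upper = 1500),
    bmi           = list(kind = "continuous", mean = 29.9, sd = 5.8, lower = 8, upper = 65),
    urine_albumin_creatinine = list(kind = "lognormal", mean = 42.5, sd = 166, lower = 0, upper = 20000)
  )
  spec <- covariate_spec(vars)
  covariate_spec(vars, default_latent_correlation(latent_names(spec)))
}

#' @rdname sprint_covariate_spec
#' @export
accord_covariate_spec <- function() {
  vars <- list(
    age           = list(kind = "continuous", mean = 63.2, sd = 6.7, lower = 35, upper = 100),
    female        = list(kind = "binary", p = 0.489),
    black         = list(kind = "binary", p = 0.236),
    hispanic      = list(kind = "binary", p = 0.071),
    sbp           = list(kind = "continuous", mean = 139.5, sd = 15.7, lower = 80, upper = 220),
    dbp           = list(kind = "continuous", mean = 75.9,  sd = 10.3, lower = 35, upper = 135),
    n_bp_agents   = list(kind = "count", mean = 1.7, max = 6),
    current_smoker = list(kind = "binary", p = 0.011),
    former_smoker  = list(kind = "binary", p = 0.484),
    aspirin       = list(kind = "binary", p = 0.524),
    statin        = list(kind = "binary", p = 0.647),
    creatinine    = list(kind = "continuous", mean = 0.9, sd = 0.2, lower = 0.3, upper = 4),
    total_chol    = list(kind = "continuous", mean = 192.8, sd = 43.7, lower = 70, upper = 400),
    hdl           = list(kind = "continuous", mean = 46.7, sd = 13.5, lower = 15, upper = 130),
    triglycerides = list(kind = "lognormal", mean = 186.9, sd = 164.5, lower = 0, upper = 2500),
    bmi           = list(kind = "continuous", mean = 32.2, sd = 5.5, lower = 8, upper = 65),
    urine_albumin_creatinine = list(kind = "lognormal", mean = 88.2, sd = 308, lower = 0, upper = 20000)
  )
  spec <- covariate_spec(vars)
  covariate_spec(vars, default_latent_correlation(latent_names(spec)))
}

#' Generate covariates from a specification
#'
#' Draws `n` rows by the Gaussian copula: correlated standard normals over
#' the latent variables, mapped through each marginal's quantile function.
#' Truncation is applied on the quantile scale (the uniform is compressed
#' into the admissible probability band), so truncated marginals remain
#' exact distributions rather than clamped ones. Deterministic given `seed`.
#'
#' @param spec a [covariate_spec].
#' @param n number of rows (0 gives an empty table with all columns).
#' @param seed integer seed.
#' @return data frame with one column per variable in specification order.
#' @export
generate_covariates <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "bp_covariate_spec"), n >= 0)
  lat <- latent_names(spec)
  out_names <- names(spec$variables)
  if (n == 0) {
    empty <- as.data.frame(matrix(numeric(0), nrow = 0, ncol = length(out_names)))
    names(empty) <- out_names
    return(empty)
  }
  U <- with_rng_seed(seed, {
    Z <- matrix(stats::rnorm(n * length(lat)), nrow = n)
    # eigenvalue clipping keeps the factor well-defined at the PSD boundary
    ev <- eigen(spec$correlation, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(lat))
    stats::pnorm(Z %*% t(L))
  })
  colnames(U) <- lat
  out <- vector("list", length(out_names))
  names(out) <- out_names
  has_smoking <- "smoking" %in% lat
  for (nm in out_names) {
    v <- spec$variables[[nm]]
    if (has_smoking && nm %in% c("current_smoker", "former_smoker")) next
    u <- U[, nm]
    out[[nm]] <- marginal_quantile(v, u)
  }
  if (has_smoking) {
    u <- U[, "smoking"]
    p_cur <- spec$variables$current_smoker$p
    p_for <- spec$variables$former_smoker$p
    current <- u > 1 - p_cur
    former <- !current & u > 1 - p_cur - p_for
    out$current_smoker <- as.integer(current)
    out$former_smoker <- as.integer(former)
  }
  as.data.frame(out[out_names])
}

marginal_quantile <- function(v, u) {
  lower <- if (is.null(v$lower)) -Inf else v$lower
  upper <- if (is.null(v$upper)) Inf else v$upper
  switch(v$kind,
    continuous = {
      pa <- stats::pnorm(lower, v$mean, v$sd)
      pb <- stats::pnorm(upper, v$mean, v$sd)
      stats::qnorm(pa + u * (pb - pa), v$mean, v$sd)
    },
    lognormal = {
      sdlog <- sqrt(log1p((v$sd / v$mean)^2))
      meanlog <- log(v$mean) - sdlog^2 / 2
      pa <- stats::plnorm(max(lower, 0), meanlog, sdlog)
      pb <- stats::plnorm(upper, meanlog, sdlog)
      stats::qlnorm(pa + u * (pb - pa), meanlog, sdlog)
    },
    binary = as.integer(u > 1 - v$p),
    count = stats::qbinom(u, size = v$max, prob = v$mean / v$max)
  )
}
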