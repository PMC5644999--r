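# Small randomized survival dataset with two covariates and an arm column,
# exponential event times, uniform censoring. Used across the Cox and
# pipeline tests.
tiny_trial <- function(n = 200, seed = 1, beta_x1 = 0.5, theta = -0.3,
                       gamma_x1 = 0, lam0 = 0.1, outcome = "cvd",
                       cens_min = 1, cens_max = 8) {
  set.seed(seed)
  d <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4),
                  arm = sample(rep_len(0:1, n)))
  lp <- beta_x1 * d$x1 + theta * d$arm + gamma_x1 * d$arm * d$x1
  t_ev <- rexp(n, lam0 * exp(lp))
  cens <- runif(n, cens_min, cens_max)
  d[[paste0("time_", outcome)]] <- pmin(t_ev, cens)
  d[[paste0("event_", outcome)]] <- as.integer(t_ev <= cens)
  d
}

# a minimal hand-built risk model for scoring tests
toy_model <- function(treatment = -0.5, interaction = c(x1 = 0.2),
                      s0 = 0.9, lbar = 0, direction = "benefit",
                      outcome = if (direction == "benefit") "cvd" else "sae") {
  bp_risk_model(
    name = "toy", outcome = outcome, direction = direction,
    coef_main = c(x1 = 0.5, x2 = -0.3),
    coef_treatment = treatment, coef_interaction = interaction,
    s0 = s0, lbar = lbar)
}
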