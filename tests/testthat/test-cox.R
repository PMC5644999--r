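test_that("partial log-likelihood at zero coefficients has its closed form", {
  d <- tiny_trial(n = 40, seed = 2)
  x <- as.matrix(d[c("x1", "x2")])
  pl <- cox_partial_loglik(x, d$time_cvd, d$event_cvd, c(0, 0))
  # at beta = 0 each event contributes -log(risk set size)
  ord <- order(d$time_cvd)
  t_s <- d$time_cvd[ord]; e_s <- d$event_cvd[ord]
  expected <- -sum(vapply(which(e_s == 1),
                          function(i) log(sum(t_s >= t_s[i])), numeric(1)))
  expect_equal(pl$loglik, expected, tolerance = 1e-12)
})

test_that("analytic gradient matches central finite differences", {
  d <- tiny_trial(n = 50, seed = 3)
  x <- as.matrix(d[c("x1", "x2", "arm")])
  set.seed(4)
  beta <- rnorm(3, 0, 0.4)
  pl <- cox_partial_loglik(x, d$time_cvd, d$event_cvd, beta)
  h <- 1e-6
  fd <- vapply(1:3, function(j) {
    e <- rep(0, 3); e[j] <- h
    (cox_partial_loglik(x, d$time_cvd, d$event_cvd, beta + e)$loglik -
       cox_partial_loglik(x, d$time_cvd, d$event_cvd, beta - e)$loglik) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(pl$gradient - fd) / pmax(abs(fd), 1)), 1e-6)
})

test_that("duplicating every subject transforms the likelihood exactly", {
  # risk-set sums double under duplication, so the Breslow partial
  # log-likelihood satisfies ll_dup = 2*ll - 2*D*log(2) exactly
  d <- tiny_trial(n = 60, seed = 5)
  x <- as.matrix(d[c("x1", "x2")])
  beta <- c(0.3, -0.2)
  ll <- cox_partial_loglik(x, d$time_cvd, d$event_cvd, beta)$loglik
  D <- sum(d$event_cvd)
  x2 <- rbind(x, x)
  ll2 <- cox_partial_loglik(x2, rep(d$time_cvd, 2), rep(d$event_cvd, 2),
                            beta)$loglik
  expect_equal(ll2, 2 * ll - 2 * D * log(2), tolerance = 1e-10)
})

test_that("zero events is an error", {
  expect_error(cox_partial_loglik(matrix(rnorm(10)), runif(10), rep(0, 10),
                                  0),
               "without events")
})

test_that("huge penalty shrinks everything except the treatment term", {
  d <- tiny_trial(n = 300, seed = 6)
  des <- design_spec(c("x1", "x2"))
  fit <- fit_penalized_cox(d, des, penalty_config(lambda = 1e4),
                           outcome = "cvd")
  expect_true(all(fit$coef_main == 0))
  expect_true(all(fit$coef_interaction == 0))
  uni <- survival::coxph(survival::Surv(time_cvd, event_cvd) ~ arm, data = d,
                         ties = "breslow")
  expect_equal(fit$coef_treatment, unname(coef(uni)), tolerance = 1e-4)
})

test_that("the unpenalized path end matches the Newton-Raphson fit", {
  d <- tiny_trial(n = 120, seed = 7)
  des <- design_spec(c("x1", "x2"))
  fit <- fit_penalized_cox(d, des, penalty_config(lambda = 0),
                           outcome = "cvd")
  dm <- bpbenefit:::build_design_matrix(d, des)
  nr <- cox_newton_raphson(dm$x, d$time_cvd, d$event_cvd)
  got <- c(fit$coef_main, fit$coef_treatment, fit$coef_interaction)
  expect_equal(unname(got), unname(nr$coef), tolerance = 1e-4)
})

test_that("rescaling a covariate rescales its coefficient inversely", {
  d <- tiny_trial(n = 250, seed = 8)
  x <- as.matrix(d[c("x1", "x2")])
  nr1 <- cox_newton_raphson(x, d$time_cvd, d$event_cvd)
  x_scaled <- x; x_scaled[, 1] <- x[, 1] * 10
  nr2 <- cox_newton_raphson(x_scaled, d$time_cvd, d$event_cvd)
  expect_equal(nr2$coef[[1]], nr1$coef[[1]] / 10, tolerance = 1e-8)
  expect_equal(nr2$coef[[2]], nr1$coef[[2]], tolerance = 1e-8)
})

test_that("coefficient paths are continuous in the penalty", {
  d <- tiny_trial(n = 300, seed = 12, beta_x1 = 0.7)
  des <- design_spec(c("x1", "x2"))
  dm <- bpbenefit:::build_design_matrix(d, des)
  y <- survival::Surv(d$time_cvd, d$event_cvd)
  fit <- glmnet::glmnet(dm$x, y, family = "cox", alpha = 0.5,
                        penalty.factor = dm$penalty, nlambda = 80)
  B <- as.matrix(fit$beta)
  steps <- abs(t(diff(t(B))))
  expect_lt(max(steps), 0.2)  # no jumps along a fine path
  # no sign flips without passing through zero
  for (j in seq_len(nrow(B))) {
    s <- sign(B[j, ])
    flips <- which(s[-1] * s[-length(s)] < 0)
    for (k in flips)
      expect_lt(min(abs(B[j, k + 0:1])), 0.02)
  }
})

test_that("backwards AIC keeps a strong true effect and lowers AIC", {
  set.seed(9)
  n <- 2000
  d <- data.frame(x_true = rnorm(n))
  for (j in 1:5) d[[paste0("noise", j)]] <- rnorm(n)
  d$arm <- sample(rep_len(0:1, n))
  t_ev <- rexp(n, 0.08 * exp(log(2) * d$x_true))
  cens <- runif(n, 1, 8)
  d$time_cvd <- pmin(t_ev, cens); d$event_cvd <- as.integer(t_ev <= cens)
  des <- design_spec(c("x_true", paste0("noise", 1:5)),
                     interaction = character(0))
  fit <- fit_backwards_aic(d, des, outcome = "cvd")
  expect_true(fit$coef_main[["x_true"]] != 0)
  expect_equal(fit$coef_main[["x_true"]], log(2), tolerance = 0.15)
  # final AIC no worse than the full model's
  dm <- bpbenefit:::build_design_matrix(d, des)
  full <- survival::coxph(survival::Surv(d$time_cvd, d$event_cvd) ~ dm$x,
                          ties = "breslow")
  expect_lte(fit$meta$aic, stats::AIC(full) + 1e-8)
})

test_that("backwards AIC respects the interaction hierarchy", {
  d <- tiny_trial(n = 500, seed = 10)
  des <- design_spec(c("x1", "x2"))
  fit <- fit_backwards_aic(d, des, outcome = "cvd")
  # no retained interaction may have a dropped main effect
  kept_int <- names(fit$coef_interaction)[fit$coef_interaction != 0]
  expect_true(all(fit$coef_main[kept_int] != 0 | !length(kept_int)))
})

test_that("backwards AIC prunes most pure-noise terms", {
  retained <- numeric(20)
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 600
    d <- data.frame(n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                    arm = sample(rep_len(0:1, n)))
    t_ev <- rexp(n, 0.1)
    cens <- runif(n, 1, 8)
    d$time_cvd <- pmin(t_ev, cens); d$event_cvd <- as.integer(t_ev <= cens)
    des <- design_spec(c("n1", "n2", "n3"), interaction = character(0))
    fit <- fit_backwards_aic(d, des, outcome = "cvd")
    retained[s] <- mean(fit$coef_main != 0)
  }
  expect_lt(mean(retained), 0.5)
})

test_that("breslow baseline agrees with Kaplan-Meier at zero coefficients", {
  set.seed(11)
  n <- 2000
  t_ev <- rexp(n, 0.15); cens <- runif(n, 0.5, 7)
  time <- pmin(t_ev, cens); event <- as.integer(t_ev <= cens)
  bl <- breslow_baseline(time, event, rep(0, n), horizon = 4)
  km <- km_risk(time, event, 4)
  expect_lt(abs((1 - bl$s0) - km$risk), 1e-3)
  # degenerate and monotone horizon behavior
  expect_equal(breslow_baseline(time, event, rep(0, n), horizon = 0)$s0, 1)
  s0s <- vapply(1:5, function(h)
    breslow_baseline(time, event, rep(0, n), horizon = h)$s0, numeric(1))
  expect_true(all(diff(s0s) <= 0))
})

test_that("breslow baseline reproduces the marginal event fraction", {
  d <- tiny_trial(n = 5000, seed = 13, beta_x1 = 0.6, lam0 = 0.08)
  x <- as.matrix(d[c("x1", "x2", "arm")])
  nr <- cox_newton_raphson(x, d$time_cvd, d$event_cvd)
  lp <- drop(x %*% nr$coef)
  bl <- breslow_baseline(d$time_cvd, d$event_cvd, lp, horizon = 5)
  pred <- 1 - bl$s0^exp(lp - bl$lbar)
  km <- km_risk(d$time_cvd, d$event_cvd, 5)
  expect_lt(abs(mean(pred) - km$risk), 5e-3)
})

test_that("hazard ratio table reports retained terms with calibrated CIs", {
  d <- tiny_trial(n = 400, seed = 14)
  des <- design_spec(c("x1", "x2"))
  fit <- fit_penalized_cox(d, des, penalty_config(lambda = 1e4),
                           outcome = "cvd")
  tab <- hazard_ratio_table(fit, d)
  expect_setequal(tab$term, "arm")  # everything else was shrunk to zero
  # CI coverage for a known hazard ratio
  hr_true <- 1.5
  covered <- logical(120)
  for (s in seq_along(covered)) {
    set.seed(1000 + s)
    n <- 800
    dd <- data.frame(x = rnorm(n), arm = sample(rep_len(0:1, n)))
    t_ev <- rexp(n, 0.1 * exp(log(hr_true) * dd$x))
    cens <- runif(n, 1, 9)
    dd$time_cvd <- pmin(t_ev, cens); dd$event_cvd <- as.integer(t_ev <= cens)
    f <- fit_penalized_cox(dd, design_spec("x", interaction = character(0)),
                           penalty_config(lambda = 0), outcome = "cvd")
    tb <- hazard_ratio_table(f, dd)
    row <- tb[tb$term == "x", ]
    covered[s] <- row$lower <= hr_true && hr_true <= row$upper
  }
  expect_gte(mean(covered), 0.89)
  expect_lte(mean(covered), 0.99)
})

test_that("model serialization round-trips losslessly", {
  d <- tiny_trial(n = 300, seed = 15)
  fit <- fit_penalized_cox(d, design_spec(c("x1", "x2")),
                           penalty_config(lambda = 0.01), outcome = "cvd")
  path <- tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_equal(back$coef_main, fit$coef_main)
  expect_equal(back$coef_treatment, fit$coef_treatment)
  expect_equal(back$coef_interaction, fit$coef_interaction)
  expect_equal(back$s0, fit$s0)
  expect_equal(back$lbar, fit$lbar)
})
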