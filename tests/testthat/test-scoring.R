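test_that("published benefit score reproduces the worked example", {
  b <- published_score("sprint_benefit")
  p <- example_patient()
  raw_std <- raw_score(b, p, arm = 0)
  raw_int <- raw_score(b, p, arm = 1)
  expect_lt(abs(raw_std - 6.704), 0.001)
  expect_lt(abs(raw_int - 6.251), 0.001)
  expect_lt(abs(absolute_risk(b, raw_std) - 0.0537), 0.001)
  expect_lt(abs(absolute_risk(b, raw_int) - 0.0345), 0.001)
  rd <- risk_difference(b, p)
  expect_lt(abs(rd$difference - 0.0192), 0.001)
})

test_that("harm transformation reproduces the printed example risks", {
  h <- published_score("sprint_harm")
  # the printed coefficients of the harm table are rounded; its printed raw
  # scores are authoritative for transformation checks
  expect_lt(abs(absolute_risk(h, 3.688) - 0.0549), 0.001)
  expect_lt(abs(absolute_risk(h, 3.213) - 0.0345), 0.001)
  expect_lt(abs(absolute_risk(h, 3.688) - absolute_risk(h, 3.213) - 0.0204),
            0.001)
})

test_that("recalibrated fixtures carry the validation-cohort constants", {
  ab <- published_score("accord_benefit")
  ah <- published_score("accord_harm")
  sb <- published_score("sprint_benefit")
  expect_equal(c(ab$s0, ab$lbar), c(0.881, 2.110))
  expect_equal(c(ah$s0, ah$lbar), c(0.887, 3.980))
  expect_equal(ab$coef_main, sb$coef_main)  # coefficients inherited intact
})

test_that("SI and conventional coefficient sets agree on the raw score", {
  b <- published_score("sprint_benefit")
  p <- example_patient()
  p_si <- convert_units(p, from = "conventional")
  for (arm in 0:1)
    expect_lt(abs(raw_score(b, p, arm) - raw_score(b, p_si, arm, units = "si")),
              0.02)
})

test_that("unit conversion matches published values and round-trips", {
  p <- example_patient()
  si <- convert_units(p, from = "conventional")
  expect_equal(si$creatinine, 97.2, tolerance = 0.1)
  expect_equal(si$total_chol, 4.9, tolerance = 0.02)
  expect_equal(si$triglycerides, 1.4, tolerance = 0.06)
  back <- convert_units(si, from = "si")
  expect_equal(unlist(back), unlist(p), tolerance = 1e-12)
})

test_that("raw score is a plain coefficient sum with arm-gated terms", {
  m <- toy_model()
  zero <- data.frame(x1 = 0, x2 = 0)
  expect_equal(raw_score(m, zero, arm = 0), 0)
  expect_equal(raw_score(m, zero, arm = 1), m$coef_treatment)
  p <- data.frame(x1 = 2, x2 = 1)
  expect_equal(raw_score(m, p, arm = 0), 0.5 * 2 - 0.3)
  expect_equal(raw_score(m, p, arm = 1), 0.5 * 2 - 0.3 - 0.5 + 0.2 * 2)
  expect_error(raw_score(m, data.frame(x1 = 1), arm = 0), "x2")
})

test_that("the risk transformation is centered, monotone, and bounded", {
  b <- published_score("sprint_benefit")
  expect_equal(absolute_risk(b, b$lbar), 1 - b$s0)  # centering identity: 0.057
  raws <- seq(2, 10, by = 0.25)
  risks <- absolute_risk(b, raws)
  expect_true(all(diff(risks) > 0))
  expect_true(all(risks > 0 & risks < 1))
  expect_lt(absolute_risk(b, 1e4), 1)  # overflow guarded
})

test_that("a model with no treatment terms predicts zero difference", {
  m <- toy_model(treatment = 0, interaction = numeric())
  d <- data.frame(x1 = rnorm(20), x2 = rbinom(20, 1, 0.5))
  expect_equal(risk_difference(m, d)$difference, rep(0, 20))
})

test_that("direction convention flips the sign exactly", {
  p <- data.frame(x1 = 1, x2 = 0)
  mb <- toy_model(direction = "benefit")
  mh <- toy_model(direction = "harm")
  expect_equal(risk_difference(mb, p)$difference,
               -risk_difference(mh, p)$difference)
})

test_that("cohort scoring matches row-wise scoring and summarizes", {
  m <- toy_model()
  one <- data.frame(x1 = 0.7, x2 = 1)
  sc <- score_cohort(m, one)
  expect_equal(sc$difference, risk_difference(m, one)$difference)
  d <- data.frame(x1 = rnorm(50), x2 = rbinom(50, 1, 0.5))
  scores <- score_cohort(m, d)
  s <- attr(scores, "summary")
  expect_equal(unname(s["75%"] - s["25%"]), attr(scores, "iqr"))
})

test_that("benefit-harm correlation agrees with a hand computation", {
  bdiff <- c(0.01, 0.03, 0.02, 0.05, 0.04)
  hdiff <- c(0.02, 0.01, 0.04, 0.06, 0.03)
  fake <- function(v) structure(data.frame(difference = v))
  got <- benefit_harm_summary(fake(bdiff), fake(hdiff))$correlation
  # Pearson correlation from first principles
  num <- sum((bdiff - mean(bdiff)) * (hdiff - mean(hdiff)))
  den <- sqrt(sum((bdiff - mean(bdiff))^2) * sum((hdiff - mean(hdiff))^2))
  expect_equal(got, num / den, tolerance = 1e-12)
})

test_that("recalibration is idempotent on the derivation data", {
  d <- tiny_trial(n = 800, seed = 20)
  fit <- fit_penalized_cox(d, design_spec(c("x1", "x2")),
                           penalty_config(lambda = 0.02), outcome = "cvd")
  recal <- recalibrate_baseline(fit, d)
  expect_equal(recal$s0, fit$s0, tolerance = 1e-12)
  expect_equal(recal$lbar, fit$lbar, tolerance = 1e-12)
  expect_identical(recal$coef_main, fit$coef_main)
})

test_that("recalibration fixes the baseline on a higher-hazard cohort", {
  d <- tiny_trial(n = 4000, seed = 21, lam0 = 0.08)
  fit <- fit_penalized_cox(d, design_spec(c("x1", "x2")),
                           penalty_config(lambda = 0.02), outcome = "cvd")
  ext <- tiny_trial(n = 4000, seed = 22, lam0 = 0.16)  # doubled baseline
  km_ext <- km_risk(ext$time_cvd, ext$event_cvd, 5)$risk
  pred_naive <- risk_difference(fit, ext)  # not used; risks below
  naive <- mean(absolute_risk(fit, raw_score(fit, ext, arm = ext$arm)))
  recal <- recalibrate_baseline(fit, ext)
  recal_mean <- mean(absolute_risk(recal, raw_score(recal, ext, arm = ext$arm)))
  expect_lt(naive, km_ext)                      # uncorrected underestimates
  expect_lt(abs(recal_mean - km_ext), 0.01)     # recalibrated matches
  expect_lt(recal$s0, fit$s0)                   # higher hazard, lower s0
  expect_error(recalibrate_baseline(fit, ext[, c("x1", "arm")]), "missing")
})
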