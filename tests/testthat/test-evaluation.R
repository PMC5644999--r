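test_that("km risk equals the event fraction without censoring", {
  set.seed(1)
  time <- rexp(100, 0.3)
  event <- rep(1L, 100)
  k <- km_risk(time, event, 3)
  expect_equal(k$risk, mean(time <= 3), tolerance = 1e-12)
  # no events at all
  k0 <- km_risk(time, rep(0L, 100), 3)
  expect_equal(c(k0$risk, k0$variance), c(0, 0))
})

test_that("km risk matches the hand-worked 6-subject example", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 0, 1, 1, 0, 1)
  k <- km_risk(time, event, 5)
  # product-limit: (5/6)(3/4)(2/3) = 0.41667; Greenwood sum
  s <- (5 / 6) * (3 / 4) * (2 / 3)
  gw <- 1 / (6 * 5) + 1 / (4 * 3) + 1 / (3 * 2)
  expect_equal(k$risk, 1 - s, tolerance = 1e-12)
  expect_equal(k$variance, s^2 * gw, tolerance = 1e-12)
  expect_equal(k$n_events, 3L)
})

test_that("km risk agrees with the survfit estimator on censored data", {
  set.seed(3)
  n <- 500
  t_ev <- rexp(n, 0.2); cens <- runif(n, 0, 8)
  time <- pmin(t_ev, cens); event <- as.integer(t_ev <= cens)
  k <- km_risk(time, event, 4)
  sf <- summary(survival::survfit(survival::Surv(time, event) ~ 1), times = 4)
  expect_equal(k$risk, 1 - sf$surv, tolerance = 1e-12)
  expect_equal(k$variance, sf$std.err^2, tolerance = 1e-12)
})

test_that("concordance is exact for perfect and reversed rankings", {
  # separable: risk order identical to event-time order, no censoring
  time <- c(5, 4, 3, 2, 1)
  event <- rep(1L, 5)
  pred <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  c1 <- concordance_index(pred, time, event, ci = FALSE)$c
  expect_equal(c1, 1)
  c2 <- concordance_index(-pred, time, event, ci = FALSE)$c
  expect_equal(c2, 1 - c1)
})

test_that("concordance matches a brute-force pair count", {
  set.seed(5)
  n <- 60
  t_ev <- rexp(n, 0.3); cens <- runif(n, 0, 6)
  time <- pmin(t_ev, cens); event <- as.integer(t_ev <= cens)
  pred <- rnorm(n)
  conc <- disc <- ties <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    # the earlier observed time must be an event for a comparable pair
    a <- if (time[i] < time[j]) i else j
    b <- if (time[i] < time[j]) j else i
    if (time[i] == time[j]) {
      if (event[i] + event[j] == 0) next
      if (event[i] + event[j] == 2) next  # tied event times: skipped here
      a <- if (event[i] == 1) i else j; b <- setdiff(c(i, j), a)
    }
    if (event[a] == 0) next
    if (pred[a] > pred[b]) conc <- conc + 1
    else if (pred[a] < pred[b]) disc <- disc + 1
    else ties <- ties + 1
  }
  expect_equal(concordance_index(pred, time, event, ci = FALSE)$c,
               (conc + 0.5 * ties) / (conc + disc + ties), tolerance = 1e-12)
})

test_that("random predictions give chance-level concordance", {
  set.seed(6)
  n <- 10000
  t_ev <- rexp(n, 0.2); cens <- runif(n, 0, 8)
  time <- pmin(t_ev, cens); event <- as.integer(t_ev <= cens)
  pred <- runif(n)
  expect_lt(abs(concordance_index(pred, time, event, ci = FALSE)$c - 0.5),
            0.02)
})

test_that("concordance is invariant to monotone transforms of predictions", {
  set.seed(7)
  n <- 300
  t_ev <- rexp(n, 0.3); cens <- runif(n, 0, 6)
  time <- pmin(t_ev, cens); event <- as.integer(t_ev <= cens)
  pred <- runif(n)
  c1 <- concordance_index(pred, time, event, ci = FALSE)$c
  c2 <- concordance_index(stats::qlogis(pred), time, event, ci = FALSE)$c
  expect_equal(c1, c2)
})

# groups with exact event fractions and no censoring before the horizon:
# observed group risk equals the predicted value by construction
exact_calibration_data <- function(p_groups, per_group = 100, tstar = 5) {
  pred <- time <- event <- numeric(0)
  for (p in p_groups) {
    k <- round(per_group * p)
    pred <- c(pred, rep(p, per_group))
    time <- c(time, seq(0.5, 2, length.out = k), rep(tstar + 1, per_group - k))
    event <- c(event, rep(1L, k), rep(0L, per_group - k))
  }
  list(pred = pred, time = time, event = event)
}

test_that("calibration is exact when observed equals predicted", {
  p_groups <- seq(0.1, 0.55, by = 0.05)
  d <- exact_calibration_data(p_groups)
  cal <- calibration_deciles(d$pred, d$time, d$event, tstar = 5)
  expect_equal(cal$slope, 1, tolerance = 1e-10)
  expect_equal(cal$intercept, 0, tolerance = 1e-10)
  expect_equal(gnd_test(cal)$chi2, 0, tolerance = 1e-18)
  expect_equal(gnd_test(cal)$p, 1)
  # halving the predictions doubles the fitted slope on the same outcomes
  cal2 <- calibration_deciles(d$pred / 2, d$time, d$event, tstar = 5)
  expect_equal(cal2$slope, 2, tolerance = 1e-10)
})

test_that("self-consistent predictions calibrate at large n", {
  set.seed(8)
  n <- 60000
  lp <- rnorm(n, 0, 0.5)
  lam0 <- 0.04
  t_ev <- rexp(n, lam0 * exp(lp))
  cens <- pmin(rexp(n, 0.05), 5)
  time <- pmin(t_ev, cens); event <- as.integer(t_ev <= cens)
  pred <- 1 - exp(-lam0 * 5 * exp(lp))
  cal <- calibration_deciles(pred, time, event, tstar = 5)
  expect_lt(abs(cal$slope - 1), 0.05)
  expect_lt(abs(cal$intercept), 0.01)
})

test_that("sparse groups are merged and totals conserved", {
  set.seed(9)
  n <- 400
  pred <- runif(n)
  # almost no events in the lowest half of predictions
  event <- as.integer(runif(n) < ifelse(pred > 0.5, 0.4, 0.005))
  time <- ifelse(event == 1, runif(n, 0, 4), 6)
  cal <- calibration_deciles(pred, time, event, tstar = 5, min_events = 5)
  expect_true(length(cal$merge_log) > 0)
  expect_equal(sum(cal$table$n), n)
  expect_equal(sum(cal$table$events), sum(event))
  expect_true(all(cal$table$events >= 5))
})

test_that("degenerate predictions are flagged", {
  cal <- calibration_deciles(rep(0.2, 50), runif(50, 0, 6),
                             rbinom(50, 1, 0.3), tstar = 5)
  expect_true(cal$degenerate)
  expect_true(is.na(cal$slope))
  expect_error(gnd_test(cal), "at least 2")
})

test_that("the GND statistic grows with any group's discrepancy", {
  d <- exact_calibration_data(seq(0.1, 0.55, by = 0.05))
  cal <- calibration_deciles(d$pred, d$time, d$event, tstar = 5)
  cal$table$observed[3] <- cal$table$predicted[3] + 0.05
  chi_a <- gnd_test(cal)$chi2
  cal$table$observed[3] <- cal$table$predicted[3] + 0.10
  chi_b <- gnd_test(cal)$chi2
  expect_gt(chi_b, chi_a)
  expect_equal(chi_b / chi_a, 4, tolerance = 1e-9)
})
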