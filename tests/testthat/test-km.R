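test_that("product-limit estimate matches hand computation", {
  fit <- km_fit(time = 1:5, event = c(1, 0, 1, 0, 1))
  expect_equal(fit$time, c(1, 3, 5))
  expect_equal(fit$n_risk, c(5L, 3L, 1L))
  expect_equal(fit$survival, c(0.8, 0.8 * 2 / 3, 0))
  expect_equal(survival_at(fit, 4), 0.8 * 2 / 3,
               ignore_attr = TRUE)
})

test_that("edge cohorts behave: all censored, no censoring, ties", {
  # all censored: S identically 1, no event times
  fit <- km_fit(c(1, 2, 3), c(0, 0, 0))
  expect_length(fit$time, 0)
  expect_equal(as.numeric(survival_at(fit, c(0, 2, 10))), c(1, 1, 1))

  # no censoring: KM is one minus the empirical CDF
  set.seed(4)
  x <- round(rexp(40, 0.3), 1)
  fit <- km_fit(x, rep(1, 40))
  for (t in c(0, quantile(x, c(0.2, 0.5, 0.9)), max(x) + 1)) {
    expect_equal(as.numeric(survival_at(fit, t)), mean(x > t))
  }

  # tied events and censorings at the same time: censored still at risk
  fit <- km_fit(c(2, 2, 2, 5), c(1, 1, 0, 1))
  expect_equal(fit$n_risk[1], 4L)
  expect_equal(fit$survival, c(0.5, 0))
})

test_that("km_fit agrees with the brute-force oracle on random cohorts", {
  set.seed(2024)
  for (i in 1:120) {
    co <- random_small_cohort()
    fit <- km_fit(co$time, co$event)
    ora <- km_oracle(co$time, co$event)
    expect_equal(fit$time, ora$time)
    expect_equal(fit$n_risk, ora$n_risk, ignore_attr = TRUE)
    expect_equal(fit$n_event, ora$n_event, ignore_attr = TRUE)
    expect_equal(fit$survival, ora$survival, tolerance = 1e-12)
    expect_equal(fit$variance, ora$variance, tolerance = 1e-12)
  }
})

test_that("km_fit agrees with survival::survfit including log-log intervals", {
  skip_if_not_installed("survival")
  set.seed(99)
  for (i in 1:10) {
    co <- random_small_cohort(25)
    if (sum(co$event) == 0) next
    fit <- km_fit(co$time, co$event)
    sf <- survival::survfit(survival::Surv(co$time, co$event) ~ 1,
                            conf.type = "log-log")
    at_event <- sf$n.event > 0
    expect_equal(fit$survival, sf$surv[at_event], tolerance = 1e-10)
    ok <- fit$survival > 0
    # survfit's std.err is on the log-survival scale
    expect_equal(fit$variance[ok],
                 (fit$survival^2 * sf$std.err[at_event]^2)[ok],
                 tolerance = 1e-10)
    expect_equal(fit$ci_low[ok],
                 ifelse(is.na(sf$lower[at_event]), 0, sf$lower[at_event])[ok],
                 tolerance = 1e-8)
    expect_equal(fit$ci_high[ok],
                 ifelse(is.na(sf$upper[at_event]), 0, sf$upper[at_event])[ok],
                 tolerance = 1e-8)
  }
})

test_that("curve invariants hold on random cohorts", {
  set.seed(31)
  for (i in 1:40) {
    co <- random_small_cohort()
    fit <- km_fit(co$time, co$event)
    expect_true(all(diff(fit$survival) <= 0))
    expect_true(all(fit$survival >= 0 & fit$survival <= 1))
    expect_true(all(fit$variance >= 0))
    expect_true(all(fit$ci_low >= 0 & fit$ci_high <= 1))
    expect_true(all(fit$ci_low <= fit$survival + 1e-12))
    expect_true(all(fit$ci_high >= fit$survival - 1e-12))
    expect_true(all(diff(fit$n_risk) <= 0))
    expect_true(all(fit$n_event <= fit$n_risk))
  }
})

test_that("exact values of censoring times beyond the last event are irrelevant", {
  set.seed(12)
  co <- random_small_cohort(25)
  co$event[co$time == max(co$time)] <- 0  # ensure trailing censorings exist
  fit_full <- km_fit(co$time, co$event)
  last_event <- max(co$time[co$event == 1])
  late <- co$event == 0 & co$time >= last_event
  expect_gt(sum(late), 0)
  shifted <- co$time
  shifted[late] <- shifted[late] + runif(sum(late), 1, 100)
  fit_shift <- km_fit(shifted, co$event)
  expect_equal(fit_shift$survival, fit_full$survival)
  expect_equal(fit_shift$variance, fit_full$variance)
  expect_equal(fit_shift$n_risk, fit_full$n_risk)
})

test_that("landmark evaluation is right-continuous and flags extrapolation", {
  fit <- km_fit(c(1, 2, 3, 4), c(1, 1, 0, 0))
  expect_equal(as.numeric(survival_at(fit, 0)), 1)
  expect_equal(as.numeric(survival_at(fit, c(1, 1.5, 2))),
               c(0.75, 0.75, 0.5))
  s <- survival_at(fit, c(3, 10))
  expect_equal(attr(s, "extrapolated"), c(FALSE, TRUE))
  expect_equal(as.numeric(s), c(0.5, 0.5))
  r <- risk_at(fit, c(0, 10))
  expect_equal(as.numeric(r), c(0, 0.5))
  expect_equal(attr(r, "extrapolated"), c(FALSE, TRUE))
  expect_error(survival_at(fit, -1), "non-negative")
})

test_that("validation rejects empty or malformed inputs", {
  expect_error(km_fit(numeric(0), integer(0)), "at least one record")
  expect_error(km_fit(c(1, -1), c(1, 1)), "non-negative")
  expect_error(km_fit(c(1, Inf), c(1, 1)), "finite")
  expect_error(km_fit(1, 2), "0/1")
  expect_error(km_fit(1, 1, ci_level = 1), "0, 1")
})

test_that("survival table CSV round trip preserves the curve", {
  set.seed(8)
  co <- random_small_cohort(30)
  fit <- km_fit(co$time, co$event)
  path <- withr::local_tempfile(fileext = ".csv")
  write_survival_table(fit, path)
  back <- read_survival_table(path)
  expect_s3_class(back, "km_curve")
  expect_equal(back$time, fit$time)
  expect_equal(back$survival, fit$survival, tolerance = 1e-12)
  expect_equal(back$variance, fit$variance, tolerance = 1e-12)
  expect_equal(as.numeric(survival_at(back, 2)),
               as.numeric(survival_at(fit, 2)))
})
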