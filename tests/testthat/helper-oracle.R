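# Brute-force product-limit oracle: recomputes everything by explicit
# counting and running products/sums, independent of the vectorized
# implementation under test.
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  surv <- var <- numeric(length(ut))
  n_risk <- n_event <- integer(length(ut))
  s <- 1
  gw <- 0
  for (i in seq_along(ut)) {
    ni <- sum(time >= ut[i])
    di <- sum(time == ut[i] & event == 1)
    s <- s * (1 - di / ni)
    gw <- gw + if (ni > di) di / (ni * (ni - di)) else Inf
    surv[i] <- s
    var[i] <- if (s == 0) 0 else s^2 * gw
    n_risk[i] <- ni
    n_event[i] <- di
  }
  list(time = ut, n_risk = n_risk, n_event = n_event,
       survival = surv, variance = var)
}

# small cohorts with frequent ties and a censoring mix
random_small_cohort <- function(n = NULL) {
  if (is.null(n)) n <- sample(1:30, 1)
  list(
    time = sample(seq(0.5, 4, by = 0.5), n, replace = TRUE),
    event = stats::rbinom(n, 1, 0.6)
  )
}

published_pcsm_landmarks <- c(`5` = 0.999, `10` = 0.990, `15` = 0.978)
published_pcsm_risks <- c(`5` = 0.0014, `10` = 0.0099, `15` = 0.0217)
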