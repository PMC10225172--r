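# Product-limit (Kaplan-Meier) estimation, written out in full rather than
# delegated, with the Greenwood variance and complementary log-log pointwise
# confidence intervals. The estimator is the workhorse of the whole
# analysis: landmark risks read off the fitted step function feed the
# counterfactual scaling stage.

#' Kaplan-Meier product-limit fit
#'
#' Estimates the survival function `S(t) = prod_{t_i <= t} (1 - d_i / n_i)`
#' over the distinct event times, with the Greenwood variance
#' `S(t)^2 * sum d_i / (n_i (n_i - d_i))` and pointwise confidence
#' intervals on the complementary log-log scale (which keeps the bounds
#' inside `[0, 1]`). At tied times events are processed before censorings,
#' i.e. subjects censored at `t_i` still count as at risk at `t_i`.
#'
#' @param time numeric vector of non-negative, finite follow-up times in
#'   years.
#' @param event integer/logical vector, 1 = event observed, 0 = censored.
#' @param ci_level confidence level in (0, 1); default 0.95.
#' @return An object of class `km_curve`: a list with `time` (distinct
#'   event times), `n_risk`, `n_event`, `survival`, `variance`, `ci_low`,
#'   `ci_high`, plus `n_total`, `max_time` (largest observed time, event or
#'   censoring) and `ci_level`. Cohorts with no events yield a curve with
#'   zero rows, i.e. `S(t)` identically 1.
#' @examples
#' fit <- km_fit(time = c(1, 2, 3, 4, 5), event = c(1, 0, 1, 0, 1))
#' survival_at(fit, 4)  # 0.8 * (2/3)
#' @export
km_fit <- function(time, event, ci_level = 0.95) {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (length(time) == 0L) stop("need at least one record", call. = FALSE)
  if (length(event) != length(time)) {
    stop("`time` and `event` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("`time` must be finite and non-negative", call. = FALSE)
  }
  if (anyNA(event) || !all(event %in% c(0L, 1L))) {
    stop("`event` must be 0/1", call. = FALSE)
  }
  if (!(ci_level > 0 && ci_level < 1)) {
    stop("`ci_level` must lie in (0, 1)", call. = FALSE)
  }
  n_total <- length(time)

  tt <- sort(unique(time))
  idx <- match(time, tt)
  d <- tabulate(idx[event == 1L], nbins = length(tt))
  leaving <- tabulate(idx, nbins = length(tt))
  n_risk <- n_total - cumsum(c(0, leaving[-length(leaving)]))

  keep <- d > 0L
  surv_all <- cumprod(1 - d / n_risk)
  gw_terms <- ifelse(n_risk > d, d / (n_risk * (n_risk - d)), Inf)
  gw_all <- cumsum(gw_terms)

  s <- surv_all[keep]
  v <- s^2 * gw_all[keep]
  v[s == 0] <- 0  # estimator has collapsed; 0 * Inf convention

  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  ci_low <- ci_high <- numeric(length(s))
  mid <- s > 0 & s < 1
  se_cll <- sqrt(v[mid]) / (s[mid] * abs(log(s[mid])))
  ci_low[mid] <- s[mid]^exp(z * se_cll)
  ci_high[mid] <- s[mid]^exp(-z * se_cll)
  ci_low[s == 0] <- 0
  ci_high[s == 0] <- 0
  ci_low[s == 1] <- 1
  ci_high[s == 1] <- 1

  structure(
    list(
      time = tt[keep],
      n_risk = as.integer(n_risk[keep]),
      n_event = as.integer(d[keep]),
      survival = s,
      variance = v,
      ci_low = ci_low,
      ci_high = ci_high,
      n_total = n_total,
      max_time = max(time),
      ci_level = ci_level
    ),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier fit: n = %d, %d event time%s, %g%% CI\n",
              x$n_total, length(x$time),
              if (length(x$time) == 1) "" else "s", 100 * x$ci_level))
  if (length(x$time)) {
    print(utils::head(as.data.frame(unclass(x)[c("time", "n_risk", "n_event",
                                                 "survival", "ci_low", "ci_high")]),
                      10))
    if (length(x$time) > 10) cat("  ...\n")
  }
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at a landmark time
#'
#' Right-continuous step evaluation: 1 before the first event time, the
#' last estimate beyond the last event time. When `t` exceeds the largest
#' observed time (event or censoring) the value is an extrapolation of the
#' final step and the result carries attribute `extrapolated = TRUE` for
#' that element.
#'
#' @param curve a `km_curve` from [km_fit()].
#' @param t numeric vector of non-negative horizons in years.
#' @return Survival probabilities, with logical attribute `extrapolated`.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and non-negative", call. = FALSE)
  }
  s <- c(1, curve$survival)[findInterval(t, curve$time) + 1L]
  attr(s, "extrapolated") <- t > curve$max_time
  s
}

#' Cumulative risk at a landmark time
#'
#' The complement `1 - S(t)` of [survival_at()]; the baseline quantity the
#' counterfactual scaling model multiplies.
#'
#' @inheritParams survival_at
#' @return Risk probabilities, with logical attribute `extrapolated`.
#' @export
risk_at <- function(curve, t) {
  s <- survival_at(curve, t)
  r <- 1 - as.numeric(s)
  attr(r, "extrapolated") <- attr(s, "extrapolated")
  r
}

#' Write / read a Kaplan-Meier curve as a survival-table CSV
#'
#' Columns: `time, n_risk, n_event, survival, variance, ci_low, ci_high`.
#' Reading reconstructs a `km_curve`; `n_total` and `max_time` are
#' recovered conservatively from the table (largest `n_risk`, largest
#' `time`), so the extrapolation flag may trigger slightly earlier than on
#' the original fit.
#'
#' @param curve a `km_curve`.
#' @param path file path.
#' @return `write_survival_table` returns `path` invisibly;
#'   `read_survival_table` returns a `km_curve`.
#' @export
write_survival_table <- function(curve, path) {
  stopifnot(inherits(curve, "km_curve"))
  df <- data.frame(
    time = curve$time, n_risk = curve$n_risk, n_event = curve$n_event,
    survival = curve$survival, variance = curve$variance,
    ci_low = curve$ci_low, ci_high = curve$ci_high
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_survival_table
#' @export
read_survival_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time", "n_risk", "n_event", "survival", "variance",
            "ci_low", "ci_high")
  if (!all(need %in% names(df))) {
    stop("survival table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  structure(
    c(as.list(df[need]),
      list(n_total = if (nrow(df)) max(df$n_risk) else NA_integer_,
           max_time = if (nrow(df)) max(df$time) else 0,
           ci_level = NA_real_)),
    class = "km_curve"
  )
}
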