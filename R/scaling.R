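# Counterfactual risk scaling: the modeling core. The hypothetical active
# surveillance cohort is assumed to carry k times the cumulative risk of the
# surgical cohort at every horizon (a risk-ratio model, deliberately NOT the
# proportional-hazards form S^k), giving excess risk (k - 1) * x and number
# needed to harm 1 / excess.

# numeric tolerance for the k * x <= 1 domain check
.PROB_TOL <- 1e-12

.check_kx <- function(x, k) {
  if (any(x < 0) || any(x > 1)) {
    stop("baseline risk `x` must lie in [0, 1]", call. = FALSE)
  }
  if (any(k < 1)) {
    stop("`k` must be >= 1: the model only describes excess risk, not benefit",
         call. = FALSE)
  }
  if (any(k * x > 1 + .PROB_TOL)) {
    stop("scaled risk k * x exceeds 1 and is not a probability", call. = FALSE)
  }
}

#' Excess risk under a multiplicative risk scenario
#'
#' If surveillance carries `k` times the baseline cumulative risk `x`, the
#' absolute excess risk is `(k - 1) * x`.
#'
#' @param x baseline risk, a probability in `[0, 1]` (recycled against `k`).
#' @param k risk multiplier `>= 1` with `k * x <= 1`.
#' @return `(k - 1) * x`.
#' @examples
#' excess_risk(0.0217, 1.25)  # 15-year baseline, modest scenario
#' @export
excess_risk <- function(x, k) {
  .check_kx(x, k)
  (k - 1) * x
}

#' Total scaled risk under a multiplicative risk scenario
#'
#' @inheritParams excess_risk
#' @return `k * x`, the cumulative risk in the hypothetical cohort.
#'   Computed as `x + (k - 1) * x` so that the additivity identity
#'   `scaled = baseline + excess` holds to the last bit.
#' @examples
#' scaled_risk(0.0099, 2)  # doubled 10-year risk
#' @export
scaled_risk <- function(x, k) {
  .check_kx(x, k)
  x + (k - 1) * x
}

#' Number needed to harm
#'
#' The reciprocal of the absolute excess risk: how many men must choose the
#' riskier strategy for one additional adverse outcome by the horizon.
#' Returned unrounded; the reporting layer rounds half-up to the nearest
#' integer.
#'
#' @param excess positive absolute risk difference.
#' @return `1 / excess`.
#' @examples
#' nnh(excess_risk(0.0217, 1.25))  # about 184 men
#' @export
nnh <- function(excess) {
  if (any(excess <= 0)) {
    stop("`excess` must be > 0: NNH is undefined (infinite) otherwise",
         call. = FALSE)
  }
  1 / excess
}

#' Scale a survival curve onto a hypothetical higher-risk cohort
#'
#' Pointwise on the risk scale: `S'(t) = 1 - k * (1 - S(t))` on the same
#' event-time grid (the `"risk-ratio"` model). The variance is scaled by
#' `k^2` (delta method on the risk scale) and the confidence bounds are
#' mapped through the same linear transform, clamped to `[0, 1]`. A
#' `"hazard-ratio"` variant `S'(t) = S(t)^k` is available for sensitivity
#' analysis; it is not the model the excess-risk and NNH grids use, and for
#' `k > 1` it yields strictly smaller excess risk at any horizon with
#' `0 < S < 1`.
#'
#' @param curve a `km_curve` from [km_fit()].
#' @param k risk multiplier `>= 1`.
#' @param model `"risk-ratio"` (default) or `"hazard-ratio"`.
#' @return A `km_curve` for the hypothetical cohort.
#' @export
scale_survival_curve <- function(curve, k, model = c("risk-ratio", "hazard-ratio")) {
  stopifnot(inherits(curve, "km_curve"))
  model <- match.arg(model)
  if (length(k) != 1L || !is.finite(k) || k < 1) {
    stop("`k` must be a single multiplier >= 1", call. = FALSE)
  }
  out <- curve
  if (model == "risk-ratio") {
    risk <- 1 - curve$survival
    if (any(k * risk > 1 + .PROB_TOL)) {
      stop("k * (1 - S) exceeds 1 somewhere on the curve; scaled survival ",
           "would leave [0, 1]", call. = FALSE)
    }
    out$survival <- pmax(0, 1 - k * risk)
    out$variance <- k^2 * curve$variance
    out$ci_low <- pmin(1, pmax(0, 1 - k * (1 - curve$ci_low)))
    out$ci_high <- pmin(1, pmax(0, 1 - k * (1 - curve$ci_high)))
  } else {
    out$survival <- curve$survival^k
    # delta method through S -> S^k
    out$variance <- (k * curve$survival^(k - 1))^2 * curve$variance
    out$ci_low <- curve$ci_low^k
    out$ci_high <- curve$ci_high^k
  }
  out
}

#' Evaluate the scenario grid of excess risks and NNH
#'
#' One row per (horizon, multiplier) pair: baseline risk, scaled risk,
#' excess risk and number needed to harm. Pure arithmetic, no randomness.
#' A multiplier of exactly 1 yields zero excess and an infinite NNH, kept
#' as `Inf` rather than an error so degenerate grid corners stay visible.
#'
#' @param baselines named numeric vector mapping horizon (years) to
#'   baseline risk `x` (a probability, e.g. `c(`5` = 0.0014)`).
#' @param multipliers numeric vector of risk multipliers, each `>= 1`.
#' @return A data.frame of class `risk_grid` with columns `horizon`,
#'   `multiplier`, `baseline_risk`, `scaled_risk`, `excess_risk`, `nnh`.
#' @examples
#' evaluate_grid(c(`5` = 0.0014, `10` = 0.0099, `15` = 0.0217),
#'               c(1.25, 1.5, 1.75, 2))
#' @export
evaluate_grid <- function(baselines, multipliers) {
  horizons <- suppressWarnings(as.numeric(names(baselines)))
  if (length(baselines) == 0L || anyNA(horizons)) {
    stop("`baselines` must be a named numeric vector with horizons as names",
         call. = FALSE)
  }
  x <- as.numeric(baselines)
  .check_kx(rep(x, each = max(1L, length(multipliers))),
            rep(multipliers, times = length(x)))
  grid <- expand.grid(multiplier = multipliers, horizon = horizons,
                      KEEP.OUT.ATTRS = FALSE)[, c("horizon", "multiplier")]
  grid$baseline_risk <- x[match(grid$horizon, horizons)]
  grid$excess_risk <- (grid$multiplier - 1) * grid$baseline_risk
  grid$scaled_risk <- grid$baseline_risk + grid$excess_risk
  grid$nnh <- ifelse(grid$excess_risk > 0, 1 / grid$excess_risk, Inf)
  class(grid) <- c("risk_grid", "data.frame")
  grid
}

#' @export
print.risk_grid <- function(x, digits = 2, ...) {
  cat("Scenario grid (", length(unique(x$horizon)), " horizon(s) x ",
      length(unique(x$multiplier)), " multiplier(s))\n", sep = "")
  df <- data.frame(
    horizon = x$horizon,
    multiplier = x$multiplier,
    `baseline %` = format_percent(x$baseline_risk, digits),
    `scaled %` = format_percent(x$scaled_risk, digits),
    `excess %` = format_percent(x$excess_risk, digits),
    NNH = format_nnh(x$nnh),
    check.names = FALSE
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Round half-up at a fixed number of decimals
#'
#' Commercial ("half away from zero") rounding on a decimal reading of the
#' value: `0.105` at 2 decimals gives `0.11`, where banker's rounding gives
#' `0.10`. A tiny pre-round shaves binary representation error (e.g.
#' `0.75 * 0.14` is stored just above `0.105`) so results match pencil and
#' paper decimal arithmetic.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(0.105, 2)   # 0.11
#' round_half_up(184.33)     # 184
#' @export
round_half_up <- function(x, digits = 0) {
  z <- x * 10^digits
  z <- round(z, 9)
  sign(z) * floor(abs(z) + 0.5) / 10^digits
}

#' Format a probability as a percentage string
#'
#' @param x probabilities.
#' @param digits decimals on the percent scale; default 2.
#' @return Character vector like `"0.54"` (percent units, no sign).
#' @export
format_percent <- function(x, digits = 2) {
  formatC(round_half_up(100 * x, digits), format = "f", digits = digits)
}

#' Format number needed to harm for reporting
#'
#' Rounds half-up to the nearest integer; infinite values (zero excess
#' risk) render as `"Inf"`.
#'
#' @param x unrounded NNH values.
#' @return Character vector.
#' @export
format_nnh <- function(x) {
  out <- character(length(x))
  fin <- is.finite(x)
  out[fin] <- formatC(round_half_up(x[fin]), format = "d")
  out[!fin] <- "Inf"
  out
}
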