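# Piecewise-exponential survival model: the generative engine behind the
# synthetic cohort. A hazard that is constant on each knot interval exactly
# interpolates any set of landmark survival probabilities, which is all the
# published summary of the reference cohort provides.

#' Piecewise-constant hazard
#'
#' A survival model whose hazard is constant on each interval
#' `[knots[j], knots[j+1])`; the last rate extends from the last knot to
#' infinity. With knots at the published landmark horizons this family
#' passes exactly through any non-increasing set of landmark survival
#' probabilities, making it the natural stand-in for a cohort known only
#' through its Kaplan-Meier landmarks.
#'
#' @param knots numeric vector of interval start times in years; strictly
#'   increasing, starting at 0.
#' @param rates non-negative hazard rates (events per person-year), one per
#'   knot.
#' @return An object of class `piecewise_hazard` with elements `knots` and
#'   `rates`.
#' @seealso [calibrate_piecewise_hazard()], [sample_event_times()]
#' @examples
#' h <- piecewise_hazard(c(0, 5, 10), c(0.0002, 0.0018, 0.0024))
#' ph_survival(h, c(5, 10, 15))
#' @export
piecewise_hazard <- function(knots, rates) {
  knots <- as.numeric(knots)
  rates <- as.numeric(rates)
  if (length(knots) == 0L || length(knots) != length(rates)) {
    stop("`knots` and `rates` must be non-empty and of equal length", call. = FALSE)
  }
  if (knots[1] != 0) {
    stop("`knots` must start at 0", call. = FALSE)
  }
  if (length(knots) > 1L && any(diff(knots) <= 0)) {
    stop("`knots` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("`rates` must be finite and non-negative", call. = FALSE)
  }
  structure(list(knots = knots, rates = rates), class = "piecewise_hazard")
}

#' @export
print.piecewise_hazard <- function(x, ...) {
  m <- length(x$knots)
  upper <- c(x$knots[-1], Inf)
  cat("Piecewise-constant hazard (", m, " interval",
      if (m > 1) "s", "):\n", sep = "")
  for (j in seq_len(m)) {
    cat(sprintf("  [%g, %g): %.6g /year\n", x$knots[j], upper[j], x$rates[j]))
  }
  invisible(x)
}

#' Cumulative hazard of a piecewise-constant hazard
#'
#' @param hazard a [piecewise_hazard()] object.
#' @param t numeric vector of times in years, each `>= 0`.
#' @return Cumulative hazard H(t), same length as `t`.
#' @export
ph_cumhaz <- function(hazard, t) {
  stopifnot(inherits(hazard, "piecewise_hazard"))
  t <- as.numeric(t)
  if (any(t < 0, na.rm = TRUE)) stop("`t` must be non-negative", call. = FALSE)
  k <- hazard$knots
  r <- hazard$rates
  m <- length(k)
  # time spent in interval j before t, summed against the rate
  H <- numeric(length(t))
  upper <- c(k[-1], Inf)
  for (j in seq_len(m)) {
    H <- H + r[j] * pmax(0, pmin(t, upper[j]) - k[j])
  }
  H
}

#' Survival function of a piecewise-constant hazard
#'
#' @inheritParams ph_cumhaz
#' @return S(t) = exp(-H(t)), same length as `t`.
#' @export
ph_survival <- function(hazard, t) {
  exp(-ph_cumhaz(hazard, t))
}

#' Calibrate a piecewise-constant hazard to landmark survival
#'
#' Inverts a set of landmark survival probabilities into the unique
#' piecewise-exponential model whose survival function passes through every
#' landmark: on the interval ending at landmark time t_j the rate is
#' `log(S(t_{j-1}) / S(t_j)) / (t_j - t_{j-1})`, with S(0) = 1 implied. The
#' last rate extends beyond the final landmark indefinitely.
#'
#' @param landmark_survival named numeric vector; names are landmark times
#'   in years (positive), values are survival probabilities in (0, 1],
#'   non-increasing in time.
#' @return A [piecewise_hazard()] whose [ph_survival()] reproduces every
#'   input landmark to machine precision.
#' @examples
#' calibrate_piecewise_hazard(c(`5` = 0.999, `10` = 0.990, `15` = 0.978))
#' @export
calibrate_piecewise_hazard <- function(landmark_survival) {
  s <- as.numeric(landmark_survival)
  t <- suppressWarnings(as.numeric(names(landmark_survival)))
  if (length(s) == 0L || anyNA(t)) {
    stop("`landmark_survival` must be a named numeric vector with numeric times as names",
         call. = FALSE)
  }
  o <- order(t)
  t <- t[o]
  s <- s[o]
  if (any(t <= 0) || anyDuplicated(t)) {
    stop("landmark times must be positive and distinct", call. = FALSE)
  }
  if (any(s <= 0) || any(s > 1)) {
    stop("landmark survival values must lie in (0, 1]", call. = FALSE)
  }
  if (any(diff(s) > 0)) {
    stop("landmark survival must be non-increasing in time", call. = FALSE)
  }
  s_prev <- c(1, s[-length(s)])
  t_prev <- c(0, t[-length(t)])
  rates <- log(s_prev / s) / (t - t_prev)
  piecewise_hazard(knots = t_prev, rates = rates)
}

#' Sample event times from a piecewise-constant hazard
#'
#' Inverse-transform sampling: draw E ~ Exp(1) and solve H(T) = E for T
#' along the piecewise-linear cumulative hazard. Draws use R's global random
#' number generator; call `set.seed()` for reproducibility. If the total
#' cumulative hazard is bounded (e.g. all rates zero) draws that exceed it
#' are returned as `Inf`, meaning the event never occurs.
#'
#' @param hazard a [piecewise_hazard()] object.
#' @param n number of i.i.d. draws, positive.
#' @return Numeric vector of `n` event times in years (possibly `Inf`).
#' @export
sample_event_times <- function(hazard, n) {
  stopifnot(inherits(hazard, "piecewise_hazard"))
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) stop("`n` must be a positive count", call. = FALSE)
  k <- hazard$knots
  r <- hazard$rates
  m <- length(k)
  e <- stats::rexp(n)
  # cumulative hazard reached at the start of each interval
  Hk <- c(0, cumsum(r[-m] * diff(k)))
  # rightmost interval whose starting cumulative hazard is <= e; ties (zero
  # rate intervals) resolve rightward, skipping hazard-free stretches
  j <- findInterval(e, Hk)
  out <- rep(Inf, n)
  pos <- r[j] > 0
  out[pos] <- k[j[pos]] + (e[pos] - Hk[j[pos]]) / r[j[pos]]
  out
}
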