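#' Weibull event-time parameters from a median and a reference survival rate
#'
#' Event times in each arm follow Weibull distributions sharing one shape
#' parameter. The scale is pinned by the median through
#' `scale * log(2)^(1/shape) = median`. The shape is either supplied directly
#' or solved from a second condition, the survival probability at a reference
#' time in the control arm: `exp(-(ref_time/scale)^shape) = ref_survival`.
#'
#' Eliminating the scale gives the closed form
#' `shape = log(-log(ref_survival)/log(2)) / log(ref_time/median)`,
#' so no iterative search is needed. The pair is feasible only when the
#' reference point sits on the same side of the median in both time and
#' probability (`ref_survival < 0.5` iff `ref_time > median`).
#'
#' @param median Median survival time, > 0.
#' @param shape Weibull shape, > 0. If supplied, `ref_time`/`ref_survival`
#'   are ignored and only the scale is solved.
#' @param ref_time Reference time at which `ref_survival` is attained.
#' @param ref_survival Survival probability at `ref_time`, in (0, 1).
#'
#' @return A list with elements `shape` and `scale`.
#'
#' @examples
#' solve_weibull_params(6, shape = 1)             # exponential, scale 6/log(2)
#' solve_weibull_params(10, ref_time = 2, ref_survival = 0.9)
#' @export
solve_weibull_params <- function(median, shape = NULL,
                                 ref_time = NULL, ref_survival = NULL) {
  stopifnot(is.numeric(median), length(median) == 1L, median > 0)
  if (!is.null(shape)) {
    stopifnot(is.numeric(shape), length(shape) == 1L, shape > 0)
    return(list(shape = shape, scale = median / log(2)^(1 / shape)))
  }
  if (is.null(ref_time) || is.null(ref_survival)) {
    abort("supply either `shape` or both `ref_time` and `ref_survival`")
  }
  stopifnot(ref_time > 0, ref_survival > 0, ref_survival < 1)
  if (abs(ref_survival - 0.5) < 1e-12) {
    if (abs(ref_time - median) < 1e-12 * median) {
      abort("under-determined: survival 0.5 at the median holds for every shape")
    }
    abort("infeasible: survival 0.5 is attained only at the median")
  }
  if (abs(ref_time - median) < 1e-12 * median) {
    abort("infeasible: at the median the survival rate must be 0.5")
  }
  num <- log(-log(ref_survival) / log(2))
  den <- log(ref_time / median)
  k <- num / den
  if (!is.finite(k) || k <= 0) {
    abort(paste0(
      "infeasible (median, ref_time, ref_survival) combination: ",
      "survival must fall below 0.5 exactly when ref_time exceeds the median"
    ))
  }
  list(shape = k, scale = median / log(2)^(1 / k))
}

#' Moments of a Weibull event-time distribution
#'
#' Mean, variance, and raw second moment, used to calibrate switching-time
#' distributions to a target mean ratio and correlation.
#'
#' @param shape,scale Weibull shape and scale, both > 0.
#' @return A list with elements `mean`, `variance`, `second_moment`.
#' @examples
#' weibull_moments(1, 6 / log(2))  # exponential: mean = scale, var = scale^2
#' @export
weibull_moments <- function(shape, scale) {
  stopifnot(shape > 0, scale > 0)
  m1 <- scale * gamma(1 + 1 / shape)
  m2 <- scale^2 * gamma(1 + 2 / shape)
  list(mean = m1, variance = m2 - m1^2, second_moment = m2)
}

# Partial Weibull survival integral: \int_0^x exp(-(u/scale)^shape) du,
# exact through the lower incomplete gamma function.
weibull_surv_integral <- function(x, shape, scale) {
  z <- (x / scale)^shape
  (scale / shape) * gamma(1 / shape) * pgamma(z, shape = 1 / shape, rate = 1)
}

#' Uniform accrual entry times
#'
#' Participants enter uniformly over the accrual window `(0, Ta)`; with
#' `Ta = 0` everyone enters at the trial start.
#'
#' @param count Number of entry times to draw.
#' @param Ta Accrual duration, >= 0.
#' @return Numeric vector of length `count`.
#' @export
sample_entry_times <- function(count, Ta) {
  stopifnot(count >= 1, Ta >= 0)
  if (Ta == 0) return(numeric(count))
  runif(count, 0, Ta)
}

# P(subject censored | no switching) for the control arm:
# C = min(U(0,h), Te - v), v ~ U(0,Ta); censored iff C < T.
# For a given admin horizon a = Te - v,
#   E_U[ S(min(U, a)) ] = (1/h) [ \int_0^{min(h,a)} S + max(0, h - a) S(a) ].
censoring_prob <- function(h, shape, scale, Ta, Te) {
  surv <- function(t) exp(-(t / scale)^shape)
  g <- function(a) {
    if (!is.finite(h)) return(surv(a))
    (weibull_surv_integral(pmin(h, a), shape, scale) +
       pmax(0, h - a) * surv(a)) / h
  }
  if (Ta == 0) return(g(Te))
  integrate(function(v) vapply(Te - v, g, 0), 0, Ta,
            rel.tol = 1e-10, abs.tol = 1e-12)$value / Ta
}

# Administrative-only censoring probability E_v[ S(Te - v) ] (the floor any
# total censoring target must exceed).
admin_censoring_prob <- function(shape, scale, Ta, Te) {
  censoring_prob(Inf, shape, scale, Ta, Te)
}

#' Calibrate the uniform dropout bound to a target censoring rate
#'
#' Dropout times are uniform on `(0, h)` and combine with administrative
#' censoring at `Te - v`. `h` is chosen so that the total censoring
#' probability of a control-arm participant, in the absence of treatment
#' switching, equals `rate`. The probability is evaluated by exact partial
#' Weibull integrals plus adaptive quadrature over the entry time, and the
#' root is bracketed and solved to 1e-6 on the rate scale.
#'
#' @param rate Target total censoring probability, in (0, 1). Must exceed the
#'   administrative floor `P(T > Te - v)`.
#' @param shape,scale Control-arm Weibull parameters.
#' @param Ta,Te Accrual and trial durations.
#' @return The dropout upper bound `h` (> 0).
#' @export
solve_dropout_bound <- function(rate, shape, scale, Ta, Te) {
  stopifnot(rate > 0, rate < 1, Te > 0, Ta >= 0, Te >= Ta)
  floor_rate <- admin_censoring_prob(shape, scale, Ta, Te)
  if (rate <= floor_rate + 1e-12) {
    abort(sprintf(
      "requested censoring rate %.6g is below the administrative floor %.6g",
      rate, floor_rate
    ))
  }
  f <- function(h) censoring_prob(h, shape, scale, Ta, Te) - rate
  lo <- 1e-8
  hi <- Te
  while (f(hi) > 0) {
    hi <- hi * 2
    if (hi > 1e12) abort("failed to bracket the dropout bound")
  }
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Sample censoring times
#'
#' Each censoring time is the minimum of a uniform dropout draw on `(0, h)`
#' and the administrative horizon `Te - v`. Both arms share the same
#' censoring law. `h = Inf` means administrative censoring only.
#'
#' @param entry_times Vector of entry times `v`.
#' @param Te Trial duration.
#' @param h Dropout upper bound (possibly `Inf`).
#' @return Vector of censoring times, one per entry time.
#' @export
sample_censoring_times <- function(entry_times, Te, h = Inf) {
  admin <- Te - entry_times
  if (!is.finite(h)) return(admin)
  pmin(runif(length(entry_times), 0, h), admin)
}
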