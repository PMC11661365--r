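# Fast product-limit core used by both the user-facing estimators and the
# Monte-Carlo power engine (which calls it once per arm per replicate).
# Returns the distinct-time table plus RMST and its variance at tau.
# Ties between events and censorings at the same time keep the censored
# subjects in the risk set for that time (events first).
rmst_core <- function(time, event, tau) {
  o <- order(time)
  t_s <- time[o]
  e_s <- event[o]
  n <- length(t_s)
  ut <- unique(t_s)
  idx <- match(t_s, ut)
  tot <- tabulate(idx, nbins = length(ut))
  d <- as.vector(rowsum(as.numeric(e_s), idx, reorder = TRUE))
  nrisk <- n - c(0, cumsum(tot))[seq_along(ut)]
  keep <- d > 0
  et <- ut[keep]
  dd <- d[keep]
  nr <- nrisk[keep]
  sv <- cumprod(1 - dd / nr)
  in_tau <- et <= tau
  et2 <- et[in_tau]
  s2 <- sv[in_tau]
  d2 <- dd[in_tau]
  n2 <- nr[in_tau]
  area <- sum(diff(c(0, et2, tau)) * c(1, s2))
  if (length(et2)) {
    gaps <- diff(c(et2, tau))
    awt <- rev(cumsum(rev(s2 * gaps)))  # \int_{t_i}^{tau} S(t) dt
    term <- ifelse(n2 - d2 == 0, 0, d2 / (n2 * (n2 - d2)))
    v <- sum(awt^2 * term)
  } else {
    v <- 0
  }
  list(
    event_times = et, deaths = dd, at_risk = nr, survival = sv,
    rmst = area, var = v, n = n, n_events = sum(dd)
  )
}

#' Kaplan-Meier curve from a survival sample
#'
#' Product-limit estimate of the survival function. Censored observations
#' tied with an event time remain at risk for that time.
#'
#' @param data A data frame with one row per subject.
#' @param time,event Column names (strings) holding the observed follow-up
#'   time and the event indicator (1 = event, 0 = censored).
#' @return A tibble with class `"km_curve"`, one row per distinct event
#'   time: `time`, `n_risk`, `n_event`, `survival`. The sample size is kept
#'   in attribute `n`.
#' @examples
#' km_fit(data.frame(time = c(1, 2, 3), event = c(0, 1, 1)))
#' @export
km_fit <- function(data, time = "time", event = "event") {
  stopifnot(is.data.frame(data), nrow(data) >= 1)
  y <- data[[time]]
  e <- data[[event]]
  if (is.null(y) || is.null(e)) abort("columns `time` and `event` are required")
  stopifnot(all(is.finite(y)), all(y >= 0), all(e %in% c(0, 1, FALSE, TRUE)))
  core <- rmst_core(y, as.numeric(e), tau = max(y))
  out <- tibble::tibble(
    time = core$event_times,
    n_risk = core$at_risk,
    n_event = core$deaths,
    survival = core$survival
  )
  attr(out, "n") <- core$n
  class(out) <- c("km_curve", class(out))
  out
}

#' Restricted mean survival time of a fitted curve
#'
#' Exact area under the Kaplan-Meier step function on `[0, tau]`. Beyond the
#' last observed event time the last survival value is carried forward.
#'
#' @param curve A `"km_curve"` from [km_fit()].
#' @param tau Horizon, > 0.
#' @return The RMST estimate, in `[0, tau]`.
#' @export
rmst_hat <- function(curve, tau) {
  stopifnot(inherits(curve, "km_curve"), tau > 0)
  keep <- curve$time <= tau
  sum(diff(c(0, curve$time[keep], tau)) * c(1, curve$survival[keep]))
}

#' Variance of the restricted mean survival time
#'
#' Greenwood-type variance of the RMST estimate:
#' `sum over event times t_i <= tau of A_i^2 d_i / (n_i (n_i - d_i))` with
#' `A_i` the area under the curve from `t_i` to `tau`. Terms with
#' `n_i = d_i` (the risk set exhausted by events) are dropped.
#'
#' @inheritParams rmst_hat
#' @return The variance estimate, >= 0.
#' @export
rmst_var <- function(curve, tau) {
  stopifnot(inherits(curve, "km_curve"), tau > 0)
  keep <- curve$time <= tau
  if (!any(keep)) return(0)
  tt <- curve$time[keep]
  ss <- curve$survival[keep]
  dd <- curve$n_event[keep]
  nn <- curve$n_risk[keep]
  gaps <- diff(c(tt, tau))
  awt <- rev(cumsum(rev(ss * gaps)))
  term <- ifelse(nn - dd == 0, 0, dd / (nn * (nn - dd)))
  sum(awt^2 * term)
}

#' One-sided non-inferiority test on the difference in RMSTs
#'
#' Tests `H0: Delta(tau) <= -delta` against `H1: Delta(tau) > -delta`, where
#' `Delta(tau) = R2(tau) - R1(tau)` (experimental minus control).
#' Non-inferiority is claimed when the one-sided lower confidence bound
#' exceeds the negated margin: `Delta_hat - z_(1-alpha) * SE > -delta`, with
#' `SE = sqrt(var1 + var2)`. The inequality is strict, so a boundary case
#' with zero standard error does not reject.
#'
#' @param R1hat,var1 Control-arm RMST estimate and its variance.
#' @param R2hat,var2 Experimental-arm RMST estimate and its variance.
#' @param delta Non-inferiority margin, > 0.
#' @param alpha One-sided significance level, in (0, 1).
#' @return A one-row tibble: `estimate` (the DRMST), `se`, `lower` (the
#'   one-sided bound), `delta`, `alpha`, `reject`.
#' @examples
#' ni_test(R1hat = 5, var1 = 0.005, R2hat = 5, var2 = 0.005,
#'         delta = 0.5, alpha = 0.025)
#' @export
ni_test <- function(R1hat, var1, R2hat, var2, delta, alpha) {
  stopifnot(delta > 0, alpha > 0, alpha < 1, var1 >= 0, var2 >= 0)
  est <- R2hat - R1hat
  se <- sqrt(var1 + var2)
  lower <- est - qnorm(1 - alpha) * se
  tibble::tibble(
    estimate = est, se = se, lower = lower,
    delta = delta, alpha = alpha, reject = lower > -delta
  )
}

#' Non-inferiority DRMST test on subject-level data
#'
#' Convenience wrapper fitting a Kaplan-Meier curve per arm, estimating each
#' RMST and variance at `tau`, and applying [ni_test()]. Suited to a
#' two-arm table read from CSV with columns `time`, `event`, `arm`.
#'
#' @param data Data frame with one row per subject.
#' @param tau RMST horizon.
#' @param delta Non-inferiority margin.
#' @param alpha One-sided significance level.
#' @param time,event,arm Column names.
#' @param control Label of the control arm in `arm`; all other rows are
#'   treated as experimental.
#' @return An object of class `"drmst_ni"`; see [tidy.drmst_ni()] and
#'   [glance.drmst_ni()].
#' @export
drmst_ni_test <- function(data, tau, delta, alpha = 0.025,
                          time = "time", event = "event", arm = "arm",
                          control = "control") {
  stopifnot(is.data.frame(data))
  a <- data[[arm]]
  if (is.null(a)) abort("column `arm` is required")
  is_ctrl <- a == control
  if (!any(is_ctrl) || all(is_ctrl)) {
    abort("`data` must contain both a control arm and an experimental arm")
  }
  per_arm <- lapply(list(control = is_ctrl, experimental = !is_ctrl), function(w) {
    core <- rmst_core(data[[time]][w], as.numeric(data[[event]][w]), tau)
    tibble::tibble(n = core$n, events = core$n_events,
                   rmst = core$rmst, var = core$var)
  })
  arms <- dplyr::bind_rows(per_arm, .id = "arm")
  test <- ni_test(arms$rmst[1], arms$var[1], arms$rmst[2], arms$var[2],
                  delta, alpha)
  structure(list(arms = arms, test = test, tau = tau), class = "drmst_ni")
}

#' @describeIn drmst_ni_test Per-arm RMST summaries as a tibble.
#' @param x,object A `"drmst_ni"` object.
#' @param ... Unused.
#' @method tidy drmst_ni
#' @export
tidy.drmst_ni <- function(x, ...) x$arms

#' @describeIn drmst_ni_test One-row test summary (estimate, se, lower
#'   bound, margin, decision).
#' @method glance drmst_ni
#' @export
glance.drmst_ni <- function(x, ...) x$test

#' @export
print.drmst_ni <- function(x, ...) {
  cat(sprintf("DRMST non-inferiority test at tau = %g\n", x$tau))
  print(x$arms)
  t <- x$test
  cat(sprintf(
    "DRMST = %.4f (SE %.4f), one-sided %.3g%% lower bound %.4f vs -delta = %.4f\n",
    t$estimate, t$se, 100 * t$alpha, t$lower, -t$delta
  ))
  cat(if (t$reject) "=> non-inferiority claimed\n" else "=> non-inferiority NOT claimed\n")
  invisible(x)
}

#' Plot a Kaplan-Meier curve
#'
#' @param object A `"km_curve"` from [km_fit()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tibble::tibble(
    time = c(0, object$time),
    survival = c(1, object$survival)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability") +
    ggplot2::theme_minimal()
}
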