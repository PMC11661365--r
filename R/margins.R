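#' True restricted mean survival time of a Weibull law
#'
#' `R(tau) = \int_0^tau S(t) dt` for a Weibull survival function pinned by
#' its median and shape. Evaluated exactly through the lower incomplete
#' gamma form of the partial Weibull integral (for shape 1 this reduces to
#' `(1 - exp(-lambda tau)) / lambda` with `lambda = log(2)/median`).
#'
#' @param median Median survival, > 0.
#' @param shape Weibull shape, > 0.
#' @param tau RMST horizon, > 0.
#' @return `R(tau)`, a number in `(0, tau)`.
#' @examples
#' true_rmst(log(2) / 0.1, 1, 10)  # exponential rate 0.1: 6.32121
#' @export
true_rmst <- function(median, shape, tau) {
  stopifnot(median > 0, shape > 0, tau > 0)
  p <- solve_weibull_params(median, shape = shape)
  weibull_surv_integral(tau, p$shape, p$scale)
}

#' Convert a hazard-ratio margin to a DRMST margin
#'
#' Under proportional hazards, a non-inferiority margin `hr_margin` (> 1) on
#' the hazard ratio of experimental to control maps to the DRMST margin
#' `delta = R1(tau) - \int_0^tau S1(t)^hr_margin dt`. For Weibull `S1` the
#' power of the survival function is again Weibull (scale divided by
#' `hr_margin^(1/shape)`), so both terms are exact.
#'
#' @param hr_margin Hazard-ratio margin, > 1 (often written `1/theta`).
#' @param median,shape Control-arm Weibull parameters (median and shape).
#' @param tau RMST horizon.
#' @return The DRMST margin `delta` (time units); 0 when `hr_margin = 1`.
#' @examples
#' hr_margin_delta(log(0.88) / log(0.93), median = 47.8, shape = 1, tau = 5.75)
#' @export
hr_margin_delta <- function(hr_margin, median, shape, tau) {
  stopifnot(hr_margin >= 1, tau > 0)
  p <- solve_weibull_params(median, shape = shape)
  r1 <- weibull_surv_integral(tau, p$shape, p$scale)
  r_theta <- weibull_surv_integral(tau, p$shape,
                                   p$scale / hr_margin^(1 / p$shape))
  r1 - r_theta
}

#' Resolve the non-inferiority margin
#'
#' Exactly one of three constructions must be supplied:
#' \describe{
#'   \item{`f1`}{preserved fraction of the control RMST:
#'     `delta = (1 - f1) * R1(tau)`.}
#'   \item{`f2` with `m0`}{preserved fraction of the control-minus-placebo
#'     RMST difference: `delta = (1 - f2) * (R1(tau) - R0(tau))`, where the
#'     placebo survival is Weibull with median `m0` and the shared shape.}
#'   \item{`margin`}{an explicit numeric margin, e.g. one converted from a
#'     hazard-ratio margin by [hr_margin_delta()].}
#' }
#' Supplying more than one construction is an error rather than a silent
#' precedence choice.
#'
#' @param m1 Control-arm median survival.
#' @param shape Shared Weibull shape.
#' @param tau RMST horizon.
#' @param f1 Preserved fraction of the control RMST, in (0, 1).
#' @param f2 Preserved fraction of the control-placebo DRMST, in (0, 1).
#' @param m0 Placebo median survival (required with `f2`).
#' @param margin Explicit numeric margin, > 0.
#' @return A list with class `"margin_spec"`: `option` (`"f1"`, `"f2"`, or
#'   `"numeric"`), `delta`, and the inputs used.
#' @examples
#' resolve_margin(m1 = 6, shape = 1, tau = 12, f1 = 0.8)
#' resolve_margin(m1 = 1, shape = 1, tau = 5, f2 = 0.5, m0 = 0.5)
#' @export
resolve_margin <- function(m1, shape, tau, f1 = NULL, f2 = NULL, m0 = NULL,
                           margin = NULL) {
  supplied <- c(f1 = !is.null(f1), f2 = !is.null(f2), margin = !is.null(margin))
  if (sum(supplied) == 0L) {
    abort("no margin option supplied: give one of `f1`, (`f2`, `m0`), or `margin`")
  }
  if (sum(supplied) > 1L) {
    abort(paste0("margin options are mutually exclusive; got: ",
                 paste(names(supplied)[supplied], collapse = ", ")))
  }
  if (!is.null(f2) && is.null(m0)) abort("`f2` requires the placebo median `m0`")
  r1 <- true_rmst(m1, shape, tau)
  out <- if (!is.null(f1)) {
    stopifnot(f1 > 0, f1 < 1)
    list(option = "f1", delta = (1 - f1) * r1, f1 = f1)
  } else if (!is.null(f2)) {
    stopifnot(f2 > 0, f2 < 1, m0 > 0)
    r0 <- true_rmst(m0, shape, tau)
    if (r1 <= r0) {
      abort(sprintf(
        "f2 margin requires R1(tau) > R0(tau); got R1 = %.4g <= R0 = %.4g",
        r1, r0
      ))
    }
    list(option = "f2", delta = (1 - f2) * (r1 - r0), f2 = f2, m0 = m0, r0 = r0)
  } else {
    stopifnot(is.numeric(margin), length(margin) == 1L, margin > 0)
    list(option = "numeric", delta = margin)
  }
  out$r1 <- r1
  out$tau <- tau
  class(out) <- "margin_spec"
  out
}

#' @export
print.margin_spec <- function(x, ...) {
  cat(sprintf("NI margin (option \"%s\"): delta = %.4f at tau = %g\n",
              x$option, x$delta, x$tau))
  invisible(x)
}
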