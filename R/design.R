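#' Specify and calibrate a non-inferiority trial design
#'
#' Collects every quantity the simulator needs and resolves all derived
#' parameters up front: Weibull scales from the medians and shared shape,
#' the uniform dropout bound from the target control-arm censoring rate,
#' the switching-time distribution from `(rs, rho_s)`, and the
#' non-inferiority margin from whichever of the three constructions is
#' supplied.
#'
#' @param n Control-arm sample size, integer >= 2. The experimental arm gets
#'   `round(r * n)` participants (half away from zero).
#' @param m1,m2 Median survival of the control and experimental arms.
#' @param Ta,Te Accrual duration (entry uniform on `(0, Ta)`) and trial
#'   duration; follow-up is administratively censored at `Te - entry`.
#' @param tau RMST horizon, `0 < tau <= Te`.
#' @param r Allocation ratio experimental : control, > 0.
#' @param shape Shared Weibull shape for both arms (1 = exponential).
#' @param f1,f2,m0,margin Margin construction; exactly one of `f1`,
#'   (`f2`, `m0`), `margin` — see [resolve_margin()].
#' @param ps Switching probability in `[0, 1]`; 0 disables switching.
#' @param rs Mean switching time over mean event time of the origin arm.
#' @param rho_s Target correlation of switching and event time (correlated
#'   families only).
#' @param s_dist Switching-time family: `"unif"`, `"beta"`, `"gamma"`,
#'   `"indepExp"`, or a fixed numeric time. Required when `ps > 0`.
#' @param censoring_rate Either the string `"AC.only"` (administrative
#'   censoring only) or the total censoring probability of a control-arm
#'   participant under no switching, in (0, 1).
#' @param one_sided_alpha One-sided significance level.
#' @param TXswitch Switching direction: `"1to2"` (control to experimental,
#'   default) or `"2to1"`. For `"2to1"` the switching-time moments refer to
#'   the experimental arm and the acceleration factor is `m1/m2`.
#'
#' @return An object of class `"ni_design"`: the inputs plus the resolved
#'   `scale1`, `scale2`, `h` (dropout bound, `Inf` if none), `delta`,
#'   `margin_spec`, `switch_model`, `acceleration`, `n1`, `n2`.
#'
#' @examples
#' ni_design(
#'   n = 232, m1 = 6.0, m2 = 6.4, shape = 1, Ta = 0, Te = 26, tau = 12,
#'   f1 = 0.8, censoring_rate = 0.05, one_sided_alpha = 0.005
#' )
#' @export
ni_design <- function(n, m1, m2, Ta, Te, tau, r = 1, shape = 1,
                      f1 = NULL, f2 = NULL, m0 = NULL, margin = NULL,
                      ps = 0, rs = NULL, rho_s = NULL, s_dist = NULL,
                      censoring_rate = "AC.only",
                      one_sided_alpha = 0.025, TXswitch = c("1to2", "2to1")) {
  check_scalar <- function(x, name, lo = 0, strict = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        (strict && x <= lo) || (!strict && x < lo)) {
      abort(sprintf("`%s` must be a finite number %s %g",
                    name, if (strict) ">" else ">=", lo))
    }
  }
  check_scalar(n, "n", 2, strict = FALSE)
  if (n != round(n)) abort("`n` must be an integer")
  check_scalar(m1, "m1"); check_scalar(m2, "m2")
  check_scalar(Te, "Te"); check_scalar(tau, "tau")
  check_scalar(r, "r"); check_scalar(shape, "shape")
  check_scalar(Ta, "Ta", 0, strict = FALSE)
  if (Te < Ta) abort("`Te` must be at least the accrual duration `Ta`")
  if (tau > Te) abort("`tau` must not exceed the trial duration `Te`")
  if (!is.numeric(one_sided_alpha) || one_sided_alpha <= 0 ||
      one_sided_alpha >= 1) {
    abort("`one_sided_alpha` must lie in (0, 1)")
  }
  if (!is.numeric(ps) || ps < 0 || ps > 1) abort("`ps` must lie in [0, 1]")
  TXswitch <- match.arg(TXswitch)

  n1 <- as.integer(n)
  n2 <- as.integer(floor(r * n + 0.5))  # round half away from zero (r*n > 0)
  if (n2 < 2) abort("experimental arm size round(r * n) must be >= 2")

  w1 <- solve_weibull_params(m1, shape = shape)
  w2 <- solve_weibull_params(m2, shape = shape)

  margin_spec <- resolve_margin(m1 = m1, shape = shape, tau = tau,
                                f1 = f1, f2 = f2, m0 = m0, margin = margin)

  if (identical(censoring_rate, "AC.only")) {
    h <- Inf
  } else {
    if (!is.numeric(censoring_rate) || censoring_rate <= 0 ||
        censoring_rate >= 1) {
      abort("`censoring_rate` must be \"AC.only\" or a number in (0, 1)")
    }
    h <- solve_dropout_bound(censoring_rate, w1$shape, w1$scale, Ta, Te)
  }

  switch_model <- NULL
  acceleration <- if (TXswitch == "1to2") m2 / m1 else m1 / m2
  if (ps > 0) {
    if (is.null(s_dist)) abort("`s_dist` is required when `ps` > 0")
    origin <- if (TXswitch == "1to2") w1 else w2
    mom <- weibull_moments(origin$shape, origin$scale)
    switch_model <- solve_switch_params(s_dist, rs = rs, rho_s = rho_s,
                                        moments = mom)
  }

  structure(list(
    n = n1, r = r, m1 = m1, m2 = m2, shape = shape,
    Ta = Ta, Te = Te, tau = tau,
    ps = ps, rs = rs, rho_s = rho_s, s_dist = s_dist, TXswitch = TXswitch,
    censoring_rate = censoring_rate, one_sided_alpha = one_sided_alpha,
    n1 = n1, n2 = n2,
    scale1 = w1$scale, scale2 = w2$scale,
    h = h, delta = margin_spec$delta, margin_spec = margin_spec,
    switch_model = switch_model, acceleration = acceleration
  ), class = "ni_design")
}

# Re-resolve a design at a different control-arm size (the calibrations do
# not depend on n, so only the arm sizes change).
design_with_n <- function(design, n) {
  design$n <- design$n1 <- as.integer(n)
  design$n2 <- as.integer(floor(design$r * n + 0.5))
  design
}

#' @export
print.ni_design <- function(x, ...) {
  cat("Non-inferiority trial design (DRMST, ITT)\n")
  cat(sprintf("  arms: control n = %d (median %g), experimental n = %d (median %g), Weibull shape %g\n",
              x$n1, x$m1, x$n2, x$m2, x$shape))
  cat(sprintf("  timeline: accrual %g, duration %g, RMST horizon tau = %g\n",
              x$Ta, x$Te, x$tau))
  cat(sprintf("  margin: delta = %.4f (option \"%s\"), one-sided alpha = %g\n",
              x$delta, x$margin_spec$option, x$one_sided_alpha))
  if (is.finite(x$h)) {
    cat(sprintf("  censoring: dropout U(0, %.4g) + administrative (total rate %.3g)\n",
                x$h, x$censoring_rate))
  } else {
    cat("  censoring: administrative only\n")
  }
  if (x$ps > 0) {
    cat(sprintf("  switching: %s, ps = %g, direction %s, acceleration %.4g\n",
                x$switch_model$family, x$ps, x$TXswitch, x$acceleration))
  } else {
    cat("  switching: none\n")
  }
  invisible(x)
}
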