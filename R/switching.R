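#' Calibrate a switching-time distribution
#'
#' The switching time `s` (time from randomization to the moment a
#' participant becomes eligible to switch) is modelled by one of five
#' families. For `"unif"`, `"beta"`, and `"gamma"`, `s = X * T` with `X`
#' independent of the event time `T` of the origin arm, so `s` is positively
#' correlated with `T`; `"indepExp"` draws `s` from an independent
#' exponential; a numeric `s_dist` fixes `s` at that constant (0 means
#' switching at the trial start).
#'
#' The free parameters are solved from two moments: `rs = E(s)/E(T)` and,
#' for the correlated families, `rho_s = corr(s, T)`. Writing `E(X) = rs`,
#' the Pearson correlation of `s = X T` with `T` is
#' `E(X) Var(T) / ( sd(T) * sqrt(E(X)^2 Var(T) + Var(X) E(T^2)) )`,
#' which inverts in closed form to the required
#' `Var(X) = rs^2 Var(T) (1/rho_s^2 - 1) / E(T^2)`; the family's own
#' moment equations then yield its parameters. `"unif"` (X ~ U(0,1)) has no
#' free parameter and is only consistent with `rs = 0.5`.
#'
#' @param s_dist `"unif"`, `"beta"`, `"gamma"`, `"indepExp"`, or a single
#'   non-negative number (fixed switching time).
#' @param rs Ratio of mean switching time to mean event time, > 0.
#' @param rho_s Target correlation between `s` and `T`, in (0, 1). Ignored
#'   for `"unif"`, `"indepExp"`, and fixed times.
#' @param moments Moments of the origin arm's event time, as returned by
#'   [weibull_moments()].
#'
#' @return A list with class `"switch_model"`: the family, solved parameters,
#'   and the implied `(rs, rho_s)`.
#'
#' @examples
#' mom <- weibull_moments(1, 6 / log(2))
#' solve_switch_params("gamma", rs = 0.3, rho_s = 0.775, moments = mom)
#' solve_switch_params(0, moments = mom)  # switch at trial start
#' @export
solve_switch_params <- function(s_dist, rs = NULL, rho_s = NULL, moments) {
  if (is.numeric(s_dist)) {
    stopifnot(length(s_dist) == 1L, s_dist >= 0)
    out <- list(family = "fixed", s0 = s_dist, rs = s_dist / moments$mean,
                rho_s = NA_real_)
    class(out) <- "switch_model"
    return(out)
  }
  family <- match.arg(s_dist, c("unif", "beta", "gamma", "indepExp"))
  V <- moments$variance
  E2 <- moments$second_moment
  mu <- moments$mean
  implied_rho <- function(ex, vx) {
    ex * V / (sqrt(V) * sqrt(ex^2 * V + vx * E2))
  }
  out <- switch(family,
    unif = {
      if (!is.null(rs) && abs(rs - 0.5) > 1e-8) {
        abort(sprintf(
          "s_dist = \"unif\" forces rs = 0.5 (E(X) of U(0,1)); got rs = %g", rs
        ))
      }
      list(family = "unif", rs = 0.5, rho_s = implied_rho(0.5, 1 / 12))
    },
    beta = {
      stopifnot(!is.null(rs), rs > 0, rs < 1, !is.null(rho_s),
                rho_s > 0, rho_s < 1)
      vx <- rs^2 * V * (1 / rho_s^2 - 1) / E2
      if (vx >= rs * (1 - rs)) {
        rho_min <- implied_rho(rs, rs * (1 - rs))
        abort(sprintf(
          "rho_s = %g unattainable for the beta family at rs = %g: requires rho_s > %.4f",
          rho_s, rs, rho_min
        ))
      }
      ab <- rs * (1 - rs) / vx - 1
      a <- rs * ab
      b <- (1 - rs) * ab
      list(family = "beta", shape1 = a, shape2 = b, rs = rs,
           rho_s = implied_rho(a / (a + b), a * b / ((a + b)^2 * (a + b + 1))))
    },
    gamma = {
      stopifnot(!is.null(rs), rs > 0, !is.null(rho_s), rho_s > 0, rho_s < 1)
      vx <- rs^2 * V * (1 / rho_s^2 - 1) / E2
      b <- rs / vx
      a <- rs * b
      list(family = "gamma", shape = a, rate = b, rs = rs,
           rho_s = implied_rho(a / b, a / b^2))
    },
    indepExp = {
      stopifnot(!is.null(rs), rs > 0)
      list(family = "indepExp", rate = 1 / (rs * mu), rs = rs,
           rho_s = 0)
    }
  )
  class(out) <- "switch_model"
  out
}

#' Sample switching times
#'
#' Draws one switching time per subject, tied to the subject's latent event
#' time for the correlated families (`s = X * T`).
#'
#' @param model A `"switch_model"` from [solve_switch_params()].
#' @param T_origin Latent event times of the switching-origin arm.
#' @return Vector of switching times, same length as `T_origin`.
#' @export
sample_switch_times <- function(model, T_origin) {
  stopifnot(inherits(model, "switch_model"))
  n <- length(T_origin)
  switch(model$family,
    unif     = runif(n) * T_origin,
    beta     = rbeta(n, model$shape1, model$shape2) * T_origin,
    gamma    = rgamma(n, shape = model$shape, rate = model$rate) * T_origin,
    indepExp = rexp(n, rate = model$rate),
    fixed    = rep(model$s0, n)
  )
}

#' Rank-preserving structural failure-time transform
#'
#' For a subject who switches at time `s` before their latent event
#' (`s < T`), the remaining survival is stretched by the acceleration factor
#' (the ratio of destination to origin median survival):
#' `T* = s + (T - s) * acceleration`. Non-switchers, and subjects whose
#' switching time falls at or after the event, keep `T* = T`.
#'
#' @param T Latent event times.
#' @param s Switching times.
#' @param switch_flags Logical vector: did the subject agree to switch
#'   (Bernoulli with the switching probability, drawn upstream)?
#' @param acceleration Median ratio `m_destination / m_origin`, > 0.
#' @return Adjusted event times.
#' @examples
#' apply_rpsftm(6, 2, TRUE, 1.5)  # 2 + 4 * 1.5 = 8
#' @export
apply_rpsftm <- function(T, s, switch_flags, acceleration) {
  stopifnot(acceleration > 0, length(s) == length(T),
            length(switch_flags) == length(T))
  eff <- switch_flags & (s < T)
  ifelse(eff, s + (T - s) * acceleration, T)
}

#' @export
print.switch_model <- function(x, ...) {
  cat("Switching-time model:", x$family, "\n")
  pars <- x[setdiff(names(x), c("family", "rs", "rho_s"))]
  if (length(pars)) {
    cat("  parameters:",
        paste(sprintf("%s = %.6g", names(pars), unlist(pars)), collapse = ", "),
        "\n")
  }
  cat(sprintf("  rs = %.4g, rho_s = %.4g\n", x$rs, x$rho_s))
  invisible(x)
}
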