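# One simulated trial, minimal allocations. Uses the current RNG state.
# Returns observed times/events per arm plus the latent switching columns.
sim_trial_core <- function(d) {
  v1 <- if (d$Ta > 0) runif(d$n1, 0, d$Ta) else numeric(d$n1)
  v2 <- if (d$Ta > 0) runif(d$n2, 0, d$Ta) else numeric(d$n2)
  T1 <- rweibull(d$n1, d$shape, d$scale1)
  T2 <- rweibull(d$n2, d$shape, d$scale2)
  C1 <- sample_censoring_times(v1, d$Te, d$h)
  C2 <- sample_censoring_times(v2, d$Te, d$h)
  s1 <- sw1 <- rep(NA_real_, d$n1)
  s2 <- sw2 <- rep(NA_real_, d$n2)
  T1a <- T1
  T2a <- T2
  if (d$ps > 0) {
    if (d$TXswitch == "1to2") {
      s1 <- sample_switch_times(d$switch_model, T1)
      flags <- runif(d$n1) < d$ps
      sw1 <- as.numeric(flags & (s1 < T1))
      T1a <- apply_rpsftm(T1, s1, flags, d$acceleration)
    } else {
      s2 <- sample_switch_times(d$switch_model, T2)
      flags <- runif(d$n2) < d$ps
      sw2 <- as.numeric(flags & (s2 < T2))
      T2a <- apply_rpsftm(T2, s2, flags, d$acceleration)
    }
  }
  list(
    v1 = v1, v2 = v2, T1 = T1, T2 = T2, C1 = C1, C2 = C2,
    s1 = s1, s2 = s2, sw1 = sw1, sw2 = sw2,
    Y1 = pmin(T1a, C1), E1 = as.numeric(T1a <= C1),
    Y2 = pmin(T2a, C2), E2 = as.numeric(T2a <= C2)
  )
}

#' Simulate one trial under a design
#'
#' Draws entry, event, censoring, and switching processes for every
#' participant and returns the subject-level table of one intention-to-treat
#' trial: observed follow-up is `min(adjusted event time, censoring time)`,
#' arm labels are the randomized arms regardless of switching.
#'
#' @param design An [ni_design()].
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return A tibble with one row per subject: `arm`, `entry`, latent
#'   `event_time`, `cens_time`, `switch_time`, `switched`, observed `time`
#'   and `event`.
#' @examples
#' d <- ni_design(n = 20, m1 = 6, m2 = 6.4, Ta = 0, Te = 26, tau = 12,
#'                f1 = 0.8, one_sided_alpha = 0.005)
#' simulate_trial(d, seed = 1)
#' @export
simulate_trial <- function(design, seed = NULL) {
  stopifnot(inherits(design, "ni_design"))
  if (!is.null(seed)) set.seed(seed)
  x <- sim_trial_core(design)
  tibble::tibble(
    arm = rep(c("control", "experimental"), c(design$n1, design$n2)),
    entry = c(x$v1, x$v2),
    event_time = c(x$T1, x$T2),
    cens_time = c(x$C1, x$C2),
    switch_time = c(x$s1, x$s2),
    switched = c(x$sw1, x$sw2) == 1,
    time = c(x$Y1, x$Y2),
    event = c(x$E1, x$E2)
  )
}

#' Monte-Carlo power of the RMST non-inferiority test
#'
#' Simulates `n_simulations` complete trials under the design, applies the
#' one-sided DRMST non-inferiority test at `tau` to each, and reports the
#' rejection proportion together with the mean event counts per arm (from
#' the same replicates).
#'
#' @param design An [ni_design()].
#' @param n_simulations Number of simulated trials.
#' @param seed Integer seed; the result is reproducible given the seed.
#' @return An object of class `"ni_power"` with fields `power`, `mc_se`
#'   (binomial standard error), `E1`, `E2` (mean events in control /
#'   experimental arm), `n_simulations`, `design`, and the per-replicate
#'   tibble `replicates`. See [tidy.ni_power()] and [glance.ni_power()].
#' @examples
#' d <- ni_design(n = 50, m1 = 6, m2 = 6.4, Ta = 0, Te = 26, tau = 12,
#'                f1 = 0.8, one_sided_alpha = 0.005)
#' calculate_power(d, n_simulations = 200, seed = 1)
#' @export
calculate_power <- function(design, n_simulations = 5000, seed = 1) {
  stopifnot(inherits(design, "ni_design"), n_simulations >= 1)
  set.seed(seed)
  z <- qnorm(1 - design$one_sided_alpha)
  est <- se <- numeric(n_simulations)
  rej <- logical(n_simulations)
  e1 <- e2 <- numeric(n_simulations)
  for (i in seq_len(n_simulations)) {
    x <- sim_trial_core(design)
    r1 <- rmst_core(x$Y1, x$E1, design$tau)
    r2 <- rmst_core(x$Y2, x$E2, design$tau)
    est[i] <- r2$rmst - r1$rmst
    se[i] <- sqrt(r1$var + r2$var)
    rej[i] <- est[i] - z * se[i] > -design$delta
    e1[i] <- r1$n_events
    e2[i] <- r2$n_events
  }
  p <- mean(rej)
  structure(list(
    power = p,
    mc_se = sqrt(p * (1 - p) / n_simulations),
    E1 = mean(e1), E2 = mean(e2),
    n_simulations = n_simulations, seed = seed,
    design = design,
    replicates = tibble::tibble(
      replicate = seq_len(n_simulations),
      drmst = est, se = se, reject = rej, events1 = e1, events2 = e2
    )
  ), class = "ni_power")
}

#' @describeIn calculate_power Per-replicate results (DRMST estimate,
#'   standard error, decision, event counts) as a tibble.
#' @param x,object An `"ni_power"` object.
#' @param ... Unused.
#' @method tidy ni_power
#' @export
tidy.ni_power <- function(x, ...) x$replicates

#' @describeIn calculate_power One-row summary: `power`, `mc_se`, `E1`,
#'   `E2`, `delta`, `n`, `n_simulations`.
#' @method glance ni_power
#' @export
glance.ni_power <- function(x, ...) {
  tibble::tibble(
    power = x$power, mc_se = x$mc_se, E1 = x$E1, E2 = x$E2,
    delta = x$design$delta, n = x$design$n1,
    n_simulations = x$n_simulations
  )
}

#' @export
print.ni_power <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo power: %.4f (MC SE %.4f) from %d simulated trials\n",
    x$power, x$mc_se, x$n_simulations
  ))
  cat(sprintf("  expected events: control %.1f, experimental %.1f\n",
              x$E1, x$E2))
  cat(sprintf("  n = %d + %d, delta = %.4f, one-sided alpha = %g\n",
              x$design$n1, x$design$n2, x$design$delta,
              x$design$one_sided_alpha))
  invisible(x)
}

#' @describeIn calculate_power Histogram of the replicate DRMST estimates
#'   with the negated margin marked.
#' @method autoplot ni_power
#' @export
autoplot.ni_power <- function(object, ...) {
  ggplot2::ggplot(object$replicates, ggplot2::aes(.data$drmst)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = -object$design$delta,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = "DRMST estimate per simulated trial",
      y = "Trials",
      title = sprintf("Power %.3f at n = %d (dashed: -delta)",
                      object$power, object$design$n1)
    ) +
    ggplot2::theme_minimal()
}
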