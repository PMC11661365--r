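#' Monte-Carlo power over a grid of control-arm sizes
#'
#' Divides `[nL, nU]` into `B` equal intervals of width
#' `w = round((nU - nL)/B)` (at least 1) and evaluates [calculate_power()]
#' at each grid size `nL + k*w`, `k = 0..B`, with per-point seeds drawn from
#' the root seed. Duplicate grid sizes from a degenerate step are dropped.
#'
#' @param design An [ni_design()]; its `n` is overridden by the grid.
#' @param nL,nU Integer bounds, `2 <= nL < nU`.
#' @param B Number of grid intervals, >= 2.
#' @param n_simulations Replicates per grid point.
#' @param seed Root seed.
#' @return A tibble with one row per grid point: `n`, `power`, `mc_se`,
#'   `E1`, `E2`, `seed`.
#' @export
power_grid <- function(design, nL, nU, B = 10, n_simulations = 5000,
                       seed = 1) {
  stopifnot(inherits(design, "ni_design"), nL >= 2, nU > nL, B >= 2)
  w <- max(1L, as.integer(round((nU - nL) / B)))
  grid <- unique(pmin(nL + (0:B) * w, nU))
  set.seed(seed)
  seeds <- sample.int(2147483646L, length(grid))
  rows <- purrr::map2(grid, seeds, function(n, s) {
    pw <- calculate_power(design_with_n(design, n),
                          n_simulations = n_simulations, seed = s)
    tibble::tibble(n = n, power = pw$power, mc_se = pw$mc_se,
                   E1 = pw$E1, E2 = pw$E2, seed = s)
  })
  dplyr::bind_rows(rows)
}

#' Fit a monotone nondecreasing power curve
#'
#' Smooths noisy Monte-Carlo power estimates into a nondecreasing curve of
#' power against sample size: the grid powers are first projected onto the
#' nondecreasing cone by isotonic regression (pool-adjacent-violators), and
#' a monotone Hermite spline is interpolated through the projected values,
#' giving a continuous nondecreasing function on `[min(n), max(n)]` clamped
#' to `[0, 1]`. Already-monotone inputs are interpolated exactly.
#'
#' @param points Data frame with columns `n` and `power` (>= 3 distinct
#'   sample sizes).
#' @return An object of class `"power_curve"`: the evaluation function
#'   (`predict()`-able), the grid, and the isotonic values.
#' @examples
#' fit_monotone_curve(data.frame(n = c(100, 150, 200),
#'                               power = c(0.62, 0.78, 0.86)))
#' @export
fit_monotone_curve <- function(points) {
  stopifnot(is.data.frame(points), all(c("n", "power") %in% names(points)))
  points <- dplyr::arrange(dplyr::distinct(
    points, .data$n, .keep_all = TRUE), .data$n)
  if (nrow(points) < 3) abort("at least 3 distinct grid points are required")
  iso <- isoreg(points$n, points$power)$yf
  f <- if (diff(range(iso)) < 1e-12) {
    cst <- iso[1]
    function(x) rep(cst, length(x))
  } else {
    splinefun(points$n, iso, method = "hyman")
  }
  structure(list(
    fun = function(x) pmin(1, pmax(0, f(x))),
    grid = points, iso = iso,
    range = range(points$n)
  ), class = "power_curve")
}

#' @export
predict.power_curve <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$n else newdata
  object$fun(x)
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf(
    "Monotone power curve on [%d, %d] through %d grid points\n",
    x$range[1], x$range[2], nrow(x$grid)
  ))
  invisible(x)
}

#' Required sample size for a desired power
#'
#' Evaluates the Monte-Carlo power on a grid of control-arm sizes, fits a
#' monotone smoothed power curve ([fit_monotone_curve()]), and returns the
#' smallest integer `n` in `[nL, nU]` at which the fitted power reaches the
#' desired power `epwr`. If the curve stays below `epwr` everywhere the
#' search fails with "increase nU"; if it is already above `epwr` at `nL`,
#' `nL` is returned with a warning to decrease it.
#'
#' @inheritParams power_grid
#' @param epwr Desired power, in (0, 1).
#' @return An object of class `"ni_size"` with fields `n_required`, `epwr`,
#'   `grid` (the power grid tibble), `curve`. See [tidy.ni_size()] and
#'   [glance.ni_size()].
#' @export
calculate_size <- function(design, nL, nU, epwr, B = 10,
                           n_simulations = 5000, seed = 1) {
  stopifnot(epwr > 0, epwr < 1)
  grid <- power_grid(design, nL = nL, nU = nU, B = B,
                     n_simulations = n_simulations, seed = seed)
  curve <- fit_monotone_curve(grid)
  n_all <- seq(min(grid$n), max(grid$n))
  fitted <- curve$fun(n_all)
  ok <- fitted >= epwr
  if (!any(ok)) {
    abort(sprintf(
      "fitted power stays below epwr = %g on [%d, %d]; increase nU",
      epwr, min(grid$n), max(grid$n)
    ))
  }
  n_req <- n_all[which(ok)[1]]
  if (n_req == min(grid$n)) {
    warn(sprintf(
      "fitted power already reaches epwr = %g at nL = %d; decrease nL",
      epwr, min(grid$n)
    ))
  }
  structure(list(
    n_required = n_req, epwr = epwr,
    grid = grid, curve = curve,
    n_simulations = n_simulations, seed = seed, design = design
  ), class = "ni_size")
}

#' @describeIn calculate_size The power grid (n, power, mc_se, E1, E2,
#'   seed) as a tibble.
#' @param x,object An `"ni_size"` object.
#' @param ... Unused.
#' @method tidy ni_size
#' @export
tidy.ni_size <- function(x, ...) x$grid

#' @describeIn calculate_size One-row summary: `n_required`, `epwr`,
#'   fitted power at the returned size, grid span, replicates per point.
#' @method glance ni_size
#' @export
glance.ni_size <- function(x, ...) {
  tibble::tibble(
    n_required = x$n_required, epwr = x$epwr,
    fitted_power = x$curve$fun(x$n_required),
    nL = min(x$grid$n), nU = max(x$grid$n),
    n_simulations = x$n_simulations
  )
}

#' @export
print.ni_size <- function(x, ...) {
  cat(sprintf(
    "Required control-arm sample size: %d (desired power %g)\n",
    x$n_required, x$epwr
  ))
  cat(sprintf("  fitted power at %d: %.4f; grid [%d, %d], %d replicates/point\n",
              x$n_required, x$curve$fun(x$n_required),
              min(x$grid$n), max(x$grid$n), x$n_simulations))
  invisible(x)
}

#' @describeIn calculate_size Grid powers, fitted curve, desired power and
#'   returned size on one plot.
#' @method autoplot ni_size
#' @export
autoplot.ni_size <- function(object, ...) {
  xs <- seq(min(object$grid$n), max(object$grid$n), length.out = 200)
  line <- tibble::tibble(n = xs, power = object$curve$fun(xs))
  ggplot2::ggplot(object$grid, ggplot2::aes(.data$n, .data$power)) +
    ggplot2::geom_line(data = line, colour = "steelblue") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$power - .data$mc_se, ymax = .data$power + .data$mc_se
    )) +
    ggplot2::geom_hline(yintercept = object$epwr, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$n_required, linetype = "dotted") +
    ggplot2::labs(x = "Control-arm sample size", y = "Power",
                  title = sprintf("Required n = %d for power %g",
                                  object$n_required, object$epwr)) +
    ggplot2::theme_minimal()
}
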