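test_that("Weibull parameters from median and shape use the exact scale", {
  p <- solve_weibull_params(6.0, shape = 1)
  expect_equal(p$scale, 6 / log(2), tolerance = 1e-10)
  p2 <- solve_weibull_params(10, shape = 1.25)
  expect_equal(p2$scale * log(2)^(1 / 1.25), 10, tolerance = 1e-10)
})

test_that("shape solved from a reference survival satisfies both defining equations", {
  cases <- list(
    list(median = 10, t = 2, s = 0.9),
    list(median = 6, t = 18, s = 0.1),
    list(median = 47.8, t = 60, s = 0.4)
  )
  for (cs in cases) {
    p <- solve_weibull_params(cs$median, ref_time = cs$t, ref_survival = cs$s)
    expect_gt(p$shape, 0)
    # median equation
    expect_equal(p$scale * log(2)^(1 / p$shape), cs$median, tolerance = 1e-8)
    # reference survival equation
    expect_equal(exp(-(cs$t / p$scale)^p$shape), cs$s, tolerance = 1e-8)
  }
})

test_that("degenerate or inconsistent calibration points are rejected", {
  # survival 0.5 at the median: any shape fits
  expect_error(solve_weibull_params(6, ref_time = 6, ref_survival = 0.5),
               "under-determined")
  # survival 0.5 away from the median is impossible
  expect_error(solve_weibull_params(6, ref_time = 3, ref_survival = 0.5),
               "infeasible")
  # survival above 0.5 after the median: no positive shape
  expect_error(solve_weibull_params(6, ref_time = 12, ref_survival = 0.8),
               "infeasible")
})

test_that("Weibull moments match closed forms and Monte-Carlo draws", {
  m <- weibull_moments(1, 3)  # exponential
  expect_equal(m$mean, 3)
  expect_equal(m$variance, 9)
  expect_equal(m$second_moment, 18)
  m2 <- weibull_moments(2, 1)
  expect_equal(m2$mean, sqrt(pi) / 2, tolerance = 1e-12)
  # heavy-tailed case against simulation
  set.seed(71)
  x <- rweibull(1e6, 0.75, 1)
  m3 <- weibull_moments(0.75, 1)
  expect_equal(m3$mean, mean(x), tolerance = 3 * sd(x) / sqrt(1e6) / m3$mean)
  expect_equal(m3$second_moment, mean(x^2),
               tolerance = 3 * sd(x^2) / sqrt(1e6) / m3$second_moment)
})

test_that("entry times are uniform on the accrual window", {
  expect_identical(sample_entry_times(5, 0), rep(0, 5))
  set.seed(5)
  v <- sample_entry_times(2e4, 3.5)
  expect_true(all(v >= 0 & v < 3.5))
  ks <- suppressWarnings(stats::ks.test(v, "punif", 0, 3.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("administrative-only censoring equals the trial-end horizon", {
  v <- c(0, 1, 2.5)
  expect_identical(sample_censoring_times(v, Te = 12, h = Inf), 12 - v)
})

test_that("the administrative censoring fraction of the radiotherapy design is 86.2%", {
  # exponential median 47.8, accrual 3.5, duration 12
  p <- solve_weibull_params(47.8, shape = 1)
  expect_equal(admin_censoring_prob(1, p$scale, Ta = 3.5, Te = 12), 0.862,
               tolerance = 5e-4)
  # and a 0.902 total rate sits above that floor, so the bound is solvable
  h <- solve_dropout_bound(0.902, 1, p$scale, Ta = 3.5, Te = 12)
  expect_gt(h, 0)
  expect_equal(censoring_prob(h, 1, p$scale, 3.5, 12), 0.902,
               tolerance = 1e-6)
})

test_that("pure-dropout calibration matches the closed form (1-exp(-lh))/(lh) = q", {
  # Te far beyond the event scale makes administrative censoring negligible
  lam <- log(2) / 6
  h <- solve_dropout_bound(0.3, 1, 6 / log(2), Ta = 0, Te = 1e5)
  h_closed <- uniroot(function(x) (1 - exp(-lam * x)) / (lam * x) - 0.3,
                      c(1, 1e4), tol = 1e-12)$root
  expect_equal(h, h_closed, tolerance = 1e-4)
})

test_that("rates at or below the administrative floor are rejected", {
  # Ta = 0: floor is exp(-lambda * Te)
  p <- solve_weibull_params(6, shape = 1)
  floor_rate <- exp(-log(2) / 6 * 26)
  expect_error(solve_dropout_bound(floor_rate * 0.5, 1, p$scale, 0, 26),
               "administrative floor")
})

test_that("calibrated dropout reproduces the target censoring fraction in simulation", {
  p <- solve_weibull_params(1, shape = 1)
  h <- solve_dropout_bound(0.2, 1, p$scale, Ta = 3, Te = 5)
  set.seed(99)
  n <- 1e5
  v <- runif(n, 0, 3)
  T1 <- rweibull(n, 1, p$scale)
  C <- sample_censoring_times(v, Te = 5, h = h)
  frac <- mean(C < T1)
  expect_equal(frac, 0.2, tolerance = 3 * sqrt(0.2 * 0.8 / n) / 0.2)
  # observed follow-up never exceeds Te - entry
  expect_true(all(pmin(T1, C) <= 5 - v + 1e-12))
})
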