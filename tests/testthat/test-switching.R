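test_that("beta switching parameters approach U(0,1) at rs = 0.5, rho = 0.7746 for exponential times", {
  mom <- exp_moments(1)
  m <- solve_switch_params("beta", rs = 0.5, rho_s = 0.775, moments = mom)
  expect_equal(m$shape1, 1, tolerance = 0.01)
  expect_equal(m$shape2, 1, tolerance = 0.01)
  # exact U(0,1) correlation: 0.5 / sqrt(5/12)
  m2 <- solve_switch_params("unif", rs = 0.5, moments = mom)
  expect_equal(m2$rho_s, 0.5 / sqrt(5 / 12), tolerance = 1e-12)
})

test_that("gamma family reduces to a = 2 rho^2 / (1 - rho^2) for exponential event times", {
  mom <- exp_moments(6.0)
  for (rho in c(0.1, 0.3, 0.5, 0.775, 0.9)) {
    m <- solve_switch_params("gamma", rs = 0.3, rho_s = rho, moments = mom)
    expect_equal(m$shape, 2 * rho^2 / (1 - rho^2), tolerance = 1e-10)
    expect_equal(m$rate, m$shape / 0.3, tolerance = 1e-10)
    expect_equal(m$rho_s, rho, tolerance = 1e-10)  # round trip
  }
})

test_that("independent exponential switching rate is 1 / (rs E(T))", {
  mom <- exp_moments(6.4)
  m <- solve_switch_params("indepExp", rs = 0.3, moments = mom)
  expect_equal(m$rate, 1 / (0.3 * 6.4 / log(2)), tolerance = 1e-12)
})

test_that("infeasible switching calibrations fail loudly", {
  mom <- exp_moments(1)
  expect_error(solve_switch_params("unif", rs = 0.25, moments = mom),
               "rs = 0.5")
  # beta at rs = 0.5 with exponential times cannot go below rho = 0.577
  expect_error(solve_switch_params("beta", rs = 0.5, rho_s = 0.3,
                                   moments = mom),
               "unattainable")
})

test_that("sampled switching times reproduce the target moments", {
  set.seed(31)
  mu <- 6 / log(2)
  T1 <- rexp(2e5, 1 / mu)
  mom <- exp_moments(6)

  m <- solve_switch_params("gamma", rs = 0.3, rho_s = 0.775, moments = mom)
  s <- sample_switch_times(m, T1)
  expect_equal(mean(s) / mu, 0.3, tolerance = 0.01)
  expect_equal(cor(s, T1), 0.775, tolerance = 0.01)

  m2 <- solve_switch_params("unif", moments = mom)
  s2 <- sample_switch_times(m2, T1)
  expect_true(all(s2 < T1))
  expect_equal(cor(s2, T1), 0.7746, tolerance = 0.01)

  m3 <- solve_switch_params("beta", rs = 0.4, rho_s = 0.8, moments = mom)
  s3 <- sample_switch_times(m3, T1)
  expect_true(all(s3 < T1))
  expect_equal(mean(s3) / mu, 0.4, tolerance = 0.01)
  expect_equal(cor(s3, T1), 0.8, tolerance = 0.01)

  m4 <- solve_switch_params("indepExp", rs = 0.3, moments = mom)
  s4 <- sample_switch_times(m4, T1)
  expect_equal(mean(s4) / mu, 0.3, tolerance = 0.01)
  expect_lt(abs(cor(s4, T1)), 0.01)

  m5 <- solve_switch_params(0, moments = mom)
  expect_identical(sample_switch_times(m5, T1[1:5]), rep(0, 5))
})

test_that("the structural failure-time transform stretches only post-switch survival", {
  # identity when the acceleration is 1
  expect_equal(apply_rpsftm(c(3, 7), c(1, 2), c(TRUE, TRUE), 1), c(3, 7))
  # direct arithmetic
  expect_equal(apply_rpsftm(6, 2, TRUE, 1.5), 8)
  # switch at the start accelerates the whole course
  expect_equal(apply_rpsftm(6, 0, TRUE, 1.5), 9)
  # no switch, or switching time at/after the event, leaves T unchanged
  expect_equal(apply_rpsftm(6, 2, FALSE, 1.5), 6)
  expect_equal(apply_rpsftm(6, 6, TRUE, 1.5), 6)
  expect_equal(apply_rpsftm(6, 8, TRUE, 1.5), 6)
})

test_that("acceleration direction orders adjusted times elementwise", {
  set.seed(8)
  T1 <- rexp(500, 1)
  s <- runif(500) * T1
  fl <- runif(500) < 0.5
  up <- apply_rpsftm(T1, s, fl, 1.4)
  dn <- apply_rpsftm(T1, s, fl, 0.7)
  expect_true(all(up >= T1))
  expect_true(all(dn <= T1))
  expect_identical(up > T1, fl & s < T1)
})

test_that("the reverse direction uses experimental-arm moments and inverse acceleration", {
  d <- ni_design(n = 100, m1 = 6, m2 = 6.4, Ta = 0, Te = 26, tau = 12,
                 f1 = 0.8, one_sided_alpha = 0.005,
                 ps = 0.3, rs = 0.3, s_dist = "indepExp", TXswitch = "2to1")
  expect_equal(d$acceleration, 6 / 6.4, tolerance = 1e-12)
  expect_equal(d$switch_model$rate, 1 / (0.3 * 6.4 / log(2)), tolerance = 1e-12)
  # switching happens in the experimental arm only
  tr <- simulate_trial(d, seed = 2)
  expect_true(all(is.na(tr$switch_time[tr$arm == "control"])))
  expect_true(any(tr$switched[tr$arm == "experimental"]))
})
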