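test_that("the three-subject product-limit example is reproduced by hand", {
  x <- generate_fixture("tiny-km")
  k <- km_fit(x)
  expect_equal(k$time, c(2, 3))
  expect_equal(k$survival, c(0.5, 0))
  expect_equal(k$n_risk, c(2, 1))
  expect_equal(rmst_hat(k, 3), 2.5)       # 2 * 1 + 1 * 0.5
  expect_equal(rmst_var(k, 3), 0.125)     # (0.5)^2 * 1 / (2 * 1)
})

test_that("uncensored data give the empirical survival function", {
  set.seed(12)
  y <- rexp(40)
  k <- km_fit(data.frame(time = y, event = 1))
  ys <- sort(unique(y))
  emp <- vapply(ys, function(t) mean(y > t), 0)
  expect_equal(k$survival, emp, tolerance = 1e-12)
  # single subject: survival drops 1 -> 0 at the event
  k1 <- km_fit(data.frame(time = 2, event = 1))
  expect_equal(k1$survival, 0)
  expect_equal(rmst_hat(k1, 5), 2)
})

test_that("an all-censored sample keeps survival at 1 with zero variance", {
  k <- km_fit(data.frame(time = c(1, 2, 3), event = 0))
  expect_equal(nrow(k), 0)
  expect_equal(rmst_hat(k, 2.5), 2.5)  # R = tau when S = 1 throughout
  expect_equal(rmst_var(k, 2.5), 0)
})

test_that("RMST, variance, and tie handling agree with the survival package", {
  skip_if_not_installed("survival")
  set.seed(77)
  for (i in 1:4) {
    n <- sample(40:250, 1)
    t <- rweibull(n, sample(c(0.8, 1, 1.3), 1), 5)
    c <- runif(n, 0, 8)
    y <- round(pmin(t, c), 1)  # rounding forces event/censor ties
    e <- as.numeric(t <= c)
    tau <- 4
    k <- km_fit(data.frame(time = y, event = e))
    sf <- survival::survfit(survival::Surv(y, e) ~ 1)
    tab <- summary(sf, rmean = tau)$table
    expect_equal(rmst_hat(k, tau), unname(tab["rmean"]), tolerance = 1e-10)
    expect_equal(sqrt(rmst_var(k, tau)), unname(tab["se(rmean)"]),
                 tolerance = 1e-8)
  }
})

test_that("the variance estimate tracks the bootstrap variance of the RMST", {
  set.seed(41)
  n <- 400
  t <- rexp(n, 1 / 6)
  c <- runif(n, 2, 20)
  y <- pmin(t, c); e <- as.numeric(t <= c)
  tau <- 10
  k <- km_fit(data.frame(time = y, event = e))
  v_est <- rmst_var(k, tau)
  boot <- vapply(1:2000, function(i) {
    idx <- sample.int(n, replace = TRUE)
    rmst_hat(km_fit(data.frame(time = y[idx], event = e[idx])), tau)
  }, 0)
  expect_equal(v_est, var(boot), tolerance = 0.15)
})

test_that("RMST stays within [0, tau] and is nondecreasing in tau", {
  set.seed(13)
  y <- rexp(60); e <- rbinom(60, 1, 0.7)
  k <- km_fit(data.frame(time = y, event = e))
  taus <- c(0.2, 0.5, 1, 2, 4)
  r <- vapply(taus, function(tt) rmst_hat(k, tt), 0)
  expect_true(all(r >= 0 & r <= taus))
  expect_true(all(diff(r) >= 0))
  # tau below the first event time: area is tau exactly
  expect_equal(rmst_hat(k, min(k$time) / 2), min(k$time) / 2)
})

test_that("the non-inferiority decision follows the lower-bound rule", {
  # direct arithmetic: -1.96 * 0.1 = -0.196 > -0.5
  r <- ni_test(5, 0.005, 5, 0.005, delta = 0.5, alpha = 0.025)
  expect_true(r$reject)
  expect_equal(r$se, 0.1)
  expect_equal(r$lower, -qnorm(0.975) * 0.1)
  # at the boundary with positive SE: never reject
  r2 <- ni_test(5, 0.01, 4.5, 0.01, delta = 0.5, alpha = 0.025)
  expect_false(r2$reject)
  # boundary with zero SE: strict inequality, no rejection
  r3 <- ni_test(5, 0, 4.5, 0, delta = 0.5, alpha = 0.025)
  expect_false(r3$reject)
  # rejection iff estimate + delta > z * SE
  set.seed(3)
  for (i in 1:20) {
    est <- rnorm(1); se <- runif(1, 0.01, 1); del <- runif(1, 0.1, 2)
    r4 <- ni_test(0, se^2 / 2, est, se^2 / 2, del, 0.025)
    expect_identical(r4$reject, est + del > qnorm(0.975) * se)
  }
})

test_that("the subject-level test wrapper matches the arm-wise computation", {
  dat <- generate_fixture("exponential-two-arm", seed = 4)
  res <- drmst_ni_test(dat, tau = 12, delta = 1.3, alpha = 0.005)
  tt <- glance(res)
  arms <- tidy(res)
  expect_equal(nrow(arms), 2)
  expect_equal(tt$estimate, arms$rmst[2] - arms$rmst[1], tolerance = 1e-12)
  expect_identical(tt$reject, tt$lower > -1.3)
  # round trip through CSV preserves the result
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(dat, f, row.names = FALSE)
  res2 <- drmst_ni_test(utils::read.csv(f), tau = 12, delta = 1.3,
                        alpha = 0.005)
  expect_equal(glance(res2), tt)
})
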