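# Shared study designs used across test files.

# Colorectal-cancer-style design: exponential medians 6.0 / 6.4 months,
# no accrual spread, 26-month trial, RMST at 12 months, margin = 20% of the
# control RMST, total control censoring 5%.
design_example1 <- function(n = 232, ...) {
  ni_design(n = n, m1 = 6.0, m2 = 6.4, shape = 1, Ta = 0, Te = 26, tau = 12,
            f1 = 0.8, censoring_rate = 0.05, one_sided_alpha = 0.005, ...)
}

# Simulation-study design: medians 1 / 1.1 (or 0.9), 3 time-unit accrual in
# a 5-unit trial, RMST at 5, margin = 50% of the control-minus-placebo
# DRMST (placebo median 0.5), 20% total control censoring.
design_sim32 <- function(n = 158, m2 = 1.1, ...) {
  ni_design(n = n, m1 = 1, m2 = m2, shape = 1, Ta = 3, Te = 5, tau = 5,
            f2 = 0.5, m0 = 0.5, censoring_rate = 0.2,
            one_sided_alpha = 0.025, ...)
}

# Exponential moments for a given median (switching-time calibration input).
exp_moments <- function(median) {
  mu <- median / log(2)
  list(mean = mu, variance = mu^2, second_moment = 2 * mu^2)
}
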