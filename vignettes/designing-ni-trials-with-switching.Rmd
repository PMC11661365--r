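---
title: "Designing non-inferiority trials with treatment switching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing non-inferiority trials with treatment switching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmstswitch)
```

## The design problem

A non-inferiority (NI) trial with a time-to-event endpoint asks whether an
experimental treatment is not unacceptably worse than an active control.
When the comparison is made on the difference in restricted mean survival
times (DRMST) at a horizon $\tau$,

$$\Delta(\tau) = R_2(\tau) - R_1(\tau), \qquad
  R_i(\tau) = \int_0^\tau S_i(t)\,dt,$$

the test is one-sided: non-inferiority is claimed at level $\alpha$ when

$$\hat\Delta(\tau) - z_{1-\alpha}\,\widehat{SE}(\hat\Delta(\tau)) > -\delta,$$

with $\delta > 0$ the NI margin. Each $\hat R_i(\tau)$ is the area under
the arm's Kaplan–Meier curve up to $\tau$, and its variance is the
Greenwood-type sum over event times $t_i \le \tau$,

$$\widehat{\mathrm{Var}}(\hat R(\tau)) =
  \sum_{t_i \le \tau} \Big[\int_{t_i}^{\tau}\hat S(t)\,dt\Big]^2
  \frac{d_i}{n_i(n_i - d_i)},$$

dropping terms with $n_i = d_i$.

Treatment switching (crossover) complicates the picture: under
intention-to-treat (ITT), control participants who switch onto the
experimental treatment carry its effect into the control arm, attenuating
the apparent difference. Depending on the direction of the true effect this
deflates or inflates power, so a design that ignores switching can be
materially under- or over-sized. No closed-form power formula accommodates
these mechanics; the package therefore estimates power by simulating
complete trials and inverts a smoothed power curve to find sample sizes.

## The generative model

`ni_design()` assembles and calibrates every ingredient once, up front.

**Event times.** Both arms use Weibull distributions with a common shape
$k$ and medians $m_1$, $m_2$, so the scale of each arm is
$\lambda_i = m_i / (\log 2)^{1/k}$, and proportional hazards holds between
arms. The common shape keeps elicitation down to two medians plus either a
shape value or one auxiliary survival probability: given a control survival
rate $S^\*$ at a reference time $t^\*$, `solve_weibull_params()` uses the
closed form $k = \log(-\log S^\*/\log 2)/\log(t^\*/m_1)$ (feasible only
when the reference point lies on the same side of the median in time and
probability).

**Accrual and censoring.** Entry times are uniform on $(0, T_a)$; follow-up
is administratively censored at $T_e - v$. Optional dropout is uniform on
$(0, h)$, identically in both arms. Rather than asking users for $h$, the
design takes the *total* control-arm censoring probability under no
switching and solves for $h$: for admin horizon $a = T_e - v$,

$$P(\text{censored} \mid v) = \frac1h\Big[\int_0^{\min(h,a)} S_1 +
  \max(0, h-a)\,S_1(a)\Big],$$

averaged over $v$ and equated to the target rate (partial Weibull integrals
are evaluated exactly through the lower incomplete gamma function; the
outer average by adaptive quadrature; the root by bisection to $10^{-6}$ on
the rate scale). The target must exceed the administrative floor
$E_v[S_1(T_e - v)]$, and `"AC.only"` skips dropout entirely. This
probability is monotone decreasing in $h$, so the root is unique.

**Switching.** A control participant becomes eligible to switch at a
switching time $s$ and actually switches with probability $p_s$
(independent Bernoulli). Five switching-time families are available; the
correlated ones write $s = X T_1$ with $X \perp T_1$:

| family       | $X$ or $s$                   | free parameters  |
|--------------|------------------------------|------------------|
| `"unif"`     | $X \sim U(0,1)$              | none (forces $r_s = 0.5$) |
| `"beta"`     | $X \sim \mathrm{Beta}(a,b)$  | $a, b$           |
| `"gamma"`    | $X \sim \mathrm{Gamma}(a,b)$ | $a, b$           |
| `"indepExp"` | $s \sim \mathrm{Exp}(b)$, independent | $b$     |
| numeric      | $s$ fixed at that value      | none             |

Calibration is to two interpretable moments, $r_s = E(s)/E(T_1)$ and
$\rho_s = \mathrm{corr}(s, T_1)$. With $E(X) = r_s$, the exact Pearson
correlation of $s = XT_1$ with $T_1$ is

$$\rho_s = \frac{E(X)\,\mathrm{Var}(T_1)}
  {\sqrt{\mathrm{Var}(T_1)}\sqrt{E(X)^2 \mathrm{Var}(T_1) +
   \mathrm{Var}(X) E(T_1^2)}},$$

which inverts in closed form:
$\mathrm{Var}(X) = r_s^2\,\mathrm{Var}(T_1)(1/\rho_s^2 - 1)/E(T_1^2)$,
after which each family's parameters follow from its own moment equations
(for exponential event times the gamma family reduces to
$a = 2\rho_s^2/(1-\rho_s^2)$). Unattainable correlations are rejected with
the attainable bound in the message; e.g. the beta family at $r_s = 0.5$
with exponential times cannot go below $\rho_s \approx 0.577$.

**The switch itself.** Following a rank-preserving structural failure time
model used generatively, a switcher's post-switch survival is stretched by
the acceleration factor $m_2/m_1$:

$$T_1^* = s + (T_1 - s)\,\frac{m_2}{m_1}, \qquad s < T_1,$$

and the observed control time is $Y_1 = \min(T_1^*, C_1)$. Under the
`"gamma"`/`"indepExp"` families $s$ can land at or after the event; such
subjects cannot switch and are treated as non-switchers (the Bernoulli is
not re-drawn). With direction `"2to1"` the mirror applies to the
experimental arm, with $r_s, \rho_s$ referred to the experimental arm's
event-time moments and acceleration $m_1/m_2$ — the natural symmetric
reading, which we fix by convention since only one direction is ever active.
ITT analysis keeps every subject in the randomized arm.

## Margins

Three constructions, mutually exclusive by design (supplying two is an
error, not a precedence decision):

* **Preserved fraction of the control RMST**: $\delta = (1-f_1) R_1(\tau)$.
* **Preserved fraction of the control-minus-placebo DRMST**:
  $\delta = (1-f_2)(R_1(\tau) - R_0(\tau))$, where the placebo survival is
  Weibull with median $m_0$ and the *shared* shape — the minimal assumption
  consistent with the common-shape event model, since only a placebo median
  is elicited. Requires $R_1(\tau) > R_0(\tau)$.
* **Hazard-ratio conversion**: a PH margin $1/\theta > 1$ maps to
  $\delta = R_1(\tau) - \int_0^\tau S_1(t)^{1/\theta} dt$
  (`hr_margin_delta()`); for Weibull $S_1$ the integrand is again Weibull,
  so the conversion is exact. At $1/\theta = 1$, $\delta = 0$.

All true-RMST integrals use the incomplete-gamma closed form rather than
quadrature; the test suite checks them against adaptive quadrature at
$10^{-10}$.

## Power and sample size

`calculate_power()` simulates `n_simulations` (default 5000) full trials —
entry, event, censoring, switching, observation, test — and reports the
rejection fraction, its binomial standard error, and the mean event count
per arm from the same replicates. The per-trial Kaplan–Meier/RMST step is a
vectorized product-limit core shared with `km_fit()`/`rmst_hat()`/
`rmst_var()`; the suite verifies it against `survival::survfit` (including
tied event/censoring times, where censored subjects stay at risk). Beyond
the last observed time the curve is carried forward to $\tau$ — with
$\tau \le T_e$ and administrative censoring this is rarely exercised but
keeps $\hat R$ defined; ties between event and censoring favor the event.

`calculate_size()` evaluates the power at $B+1$ grid sizes
$n_L + k\,w$, $w = \mathrm{round}((n_U - n_L)/B)$ (default $B = 10$,
balancing grid resolution against simulation cost), projects the noisy grid
powers onto the nondecreasing cone by isotonic regression
(pool-adjacent-violators), interpolates a monotone Hermite spline through
the projected values, and returns the smallest integer $n$ whose fitted
power reaches the target `epwr`. Resolving on the integer lattice (rather
than the grid) avoids a rounding ambiguity of up to one grid step. A curve
that never reaches `epwr` raises "increase nU"; one already above it at
$n_L$ returns $n_L$ with a "decrease nL" warning. The smoother was chosen
over a penalized shape-constrained additive model because with ~11 grid
points the isotonic projection plus monotone interpolation already meets
every property that matters downstream (nondecreasing, continuous, faithful
to the grid within Monte-Carlo error) with no tuning parameter; the
returned $n$ inherits the grid powers' sampling noise either way, and the
self-consistency check below bounds its practical impact.

Reproducibility: execution is serial, one `set.seed(seed)` per
`calculate_power()` call; `calculate_size()` draws per-grid-point sub-seeds
from the root seed up front, so results are bit-reproducible for a fixed
seed and grid points are mutually independent.

## What the simulations do and do not establish

The generator emulates: uniform accrual, Weibull proportional-hazards event
times with a common shape, arm-identical uniform-plus-administrative
censoring calibrated to a total control rate, switching times from the
families above, and a common multiplicative treatment effect for switchers.
It does **not** emulate informative censoring, non-uniform accrual,
switching driven by prognosis (the Bernoulli is independent of
$(T, s, C)$), or switchers who benefit less than originally-experimental
participants — in the latter case the acceleration input can be multiplied
by a deflation constant, but choosing that constant is a substantive
judgement, not a package default. Passing tests show the machine reproduces
its own model's operating characteristics, not that a given real trial
satisfies these assumptions.

Scale of the shipped checks: test-suite power estimates use 1200–4000
replicates with tolerance bands widened by the binomial standard errors of
both this run and the 5000-replicate reference values; sample-size checks
translate those bands through the local slope of the fitted power curve.
The worked examples in the README use the default 5000.

Two properties worth knowing when interpreting results:

* **Boundary calibration.** With the margin set at the true deficit
  ($\delta = R_1 - R_2$, $m_2 < m_1$), the rejection rate is $\approx
  \alpha$ — verified in the suite at $3$ Monte-Carlo SEs.
* **Self-consistency of the size search.** Re-running `calculate_power()`
  at the returned $n$ lands within about 2 percentage points of the target
  power; the residual gap is grid-and-noise, not bias (the suite checks
  this too).

Degenerate inputs are rejected loudly rather than repaired: $\tau > T_e$,
accrual longer than the trial, censoring targets at or below the
administrative floor, infeasible $(\rho_s, r_s)$ pairs, `"unif"` switching
with $r_s \ne 0.5$, margins over- or under-specified, experimental arms
rounding below 2 participants ($n_2 = \mathrm{round}(r\,n)$, half away
from zero).

## A worked sketch

```{r, eval = FALSE}
design <- ni_design(
  n = 232, r = 1, m1 = 6.0, m2 = 6.4, shape = 1,
  Ta = 0, Te = 26, tau = 12,
  f1 = 0.8, censoring_rate = 0.05, one_sided_alpha = 0.005,
  ps = 0.89, rs = 0.3, rho_s = 0.5, s_dist = "gamma"
)
pw <- calculate_power(design, n_simulations = 5000, seed = 1)
glance(pw)

sz <- calculate_size(design, nL = 200, nU = 400, epwr = 0.9,
                     n_simulations = 2000, seed = 1)
glance(sz)
autoplot(sz)
```

Batches of scenarios (e.g. sweeping `ps` by switching family) run through
`run_scenario_batch()`, and a standalone subject-level table — real or
simulated — can be tested directly with `drmst_ni_test()`.
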