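Package: rmstswitch
Title: Power and Sample Size for Non-Inferiority Survival Trials with
    Treatment Switching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo power and sample-size calculation for
    non-inferiority trials with a time-to-event endpoint analyzed by the
    difference in restricted mean survival times (RMST) under
    intention-to-treat, when participants may switch (cross over) between
    treatment arms. Simulates Weibull event times with uniform accrual,
    dropout plus administrative censoring calibrated to a target control-arm
    censoring rate, and switching times from several parametric families
    calibrated to a mean ratio and a correlation with the event time; the
    post-switch survival is stretched by the median ratio following a
    rank-preserving structural failure time model. Provides three
    non-inferiority margin constructions (preserved fraction of the control
    RMST, preserved fraction of the control-minus-placebo RMST difference,
    and hazard-ratio conversion), the one-sided RMST non-inferiority test,
    and sample-size inversion through a monotone smoothed power curve.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
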