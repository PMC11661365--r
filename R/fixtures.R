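#' Generate a small deterministic survival dataset
#'
#' Toy subject-level tables used in examples and tests:
#' \describe{
#'   \item{`"tiny-km"`}{three subjects, times (1, 2, 3) with events
#'     (0, 1, 1) — the hand-checkable Kaplan-Meier example.}
#'   \item{`"exponential-two-arm"`}{two exponential arms with medians 6.0
#'     (control) and 6.4 (experimental), 200 subjects per arm,
#'     administratively censored at 26.}
#'   \item{`"switching-demo"`}{a control arm of 100 subjects with gamma
#'     switching times (`rs = 0.3`, `rho_s = 0.5`, `ps = 0.5`) showing the
#'     latent and adjusted event times.}
#' }
#'
#' @param kind One of `"tiny-km"`, `"exponential-two-arm"`,
#'   `"switching-demo"`.
#' @param path Optional CSV path to write the table to.
#' @param seed Seed making the table reproducible.
#' @return A tibble with columns `time`, `event`, `arm` (plus switching
#'   columns for `"switching-demo"`).
#' @examples
#' generate_fixture("tiny-km")
#' @export
generate_fixture <- function(kind, path = NULL, seed = 1) {
  kind <- match.arg(kind, c("tiny-km", "exponential-two-arm",
                            "switching-demo"))
  set.seed(seed)
  out <- switch(kind,
    "tiny-km" = tibble::tibble(
      time = c(1, 2, 3), event = c(0, 1, 1), arm = "control"
    ),
    "exponential-two-arm" = {
      d <- ni_design(n = 200, m1 = 6.0, m2 = 6.4, Ta = 0, Te = 26,
                     tau = 12, f1 = 0.8, one_sided_alpha = 0.005)
      dplyr::select(simulate_trial(d), "time", "event", "arm")
    },
    "switching-demo" = {
      d <- ni_design(n = 100, m1 = 6.0, m2 = 6.4, Ta = 0, Te = 26,
                     tau = 12, f1 = 0.8, ps = 0.5, rs = 0.3, rho_s = 0.5,
                     s_dist = "gamma", one_sided_alpha = 0.005)
      dplyr::filter(simulate_trial(d), .data$arm == "control")
    }
  )
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
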