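#' Hypertension dose-finding worked example
#'
#' Parameter values from a placebo-controlled trial of four dose regimens of
#' an anti-hypertensive compound, used throughout the package as a worked
#' example. The final endpoint is the reduction in diastolic blood pressure
#' (DBP, mmHg) after 8 weeks of treatment, the early endpoint the reduction
#' at 4 weeks; reductions are stored as positive improvements relative to
#' placebo. Final-endpoint effects of the four dose regimens are
#' (1.0, 0.6, 3.9, 1.1) mmHg, early-endpoint effects (2.3, 3.4, 3.8, 1.9)
#' mmHg, with common endpoint standard deviations of 10 mmHg and a strong
#' within-patient correlation of 0.9. Two interim-analysis timings are
#' considered: setting `"i"` with early data on `N1 = 45` patients per group
#' of whom `n1 = 10` also have final data, and the earlier setting `"ii"`
#' with `N1 = 25`, `n1 = 5`.
#'
#' @return list with `model` (an [endpoint_model()]), `settings` (named list
#'   of `c(N1, n1)` pairs), and `arms` (dose-regimen labels).
#' @examples
#' hypertension_example()$model
#' @export
hypertension_example <- function() {
  list(model = endpoint_model(mu_b = c(0, 2.3, 3.4, 3.8, 1.9),
                              mu_B = c(0, 1.0, 0.6, 3.9, 1.1),
                              sigma0 = 10, sigma = 10, rho_w = 0.9),
       settings = list(i = c(N1 = 45L, n1 = 10L),
                       ii = c(N1 = 25L, n1 = 5L)),
       arms = c("DR1", "DR2", "DR3", "DR4"))
}

#' Reference configuration for rule agreement
#'
#' A three-arm configuration used to study how the sign of the
#' within-patient correlation drives agreement between the two selection
#' rules: early-endpoint effects (0.2, 0.1, 0.05), final-endpoint effects
#' (0.3, 0.15, 0.075) (arm 2 and 3 at a half and a quarter of arm 1), unit
#' SDs, `N1 = 32`, `n1 = 4`, `n2 = 64`. Although both marginal selection
#' probabilities for arm 1 are unchanged when `rho_w` flips sign, the
#' probability that *both* rules select arm 1 is markedly smaller at
#' `rho_w = -0.9` than at `+0.9`.
#'
#' @param rho_w within-patient correlation.
#' @param null logical; if `TRUE`, all treatment effects are set to zero
#'   (the configuration used for the degenerate `rho_w = +/-1` cases).
#' @return list with `model` and `design`.
#' @examples
#' agreement_example(-0.9)$model
#' @export
agreement_example <- function(rho_w, null = FALSE) {
  mu_b <- if (null) rep(0, 4) else c(0, 0.2, 0.1, 0.05)
  mu_B <- if (null) rep(0, 4) else c(0, 0.3, 0.15, 0.075)
  list(model = endpoint_model(mu_b, mu_B, sigma0 = 1, sigma = 1,
                              rho_w = rho_w),
       design = trial_design(k = 3, N1 = 32, n1 = 4, n2 = 64))
}
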