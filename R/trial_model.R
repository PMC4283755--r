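#' Bivariate endpoint model
#'
#' Describes the joint distribution of a patient's early (surrogate) and
#' final (primary) endpoint under each treatment. Within a patient the two
#' endpoints are bivariate normal with common standard deviations
#' `sigma0` (early) and `sigma` (final) across arms and within-patient
#' correlation `rho_w`; patients are independent. Arm 0 is the control;
#' larger values encode benefit.
#'
#' @param mu_b numeric vector of early-endpoint group means, element 1 =
#'   control, elements 2..(k+1) = experimental arms (endpoint units).
#' @param mu_B numeric vector of final-endpoint group means, same indexing.
#' @param sigma0 early-endpoint standard deviation (> 0).
#' @param sigma final-endpoint standard deviation (> 0).
#' @param rho_w within-patient correlation between early and final endpoint,
#'   in \[-1, 1\].
#' @param estimated logical; marks the object as holding interim estimates
#'   rather than design values.
#'
#' @return An object of class `endpoint_model`: a list with the validated
#'   fields plus `k`, the number of experimental arms.
#' @seealso [theta_effects()], [delta_effects()], [trial_design()]
#' @examples
#' m <- endpoint_model(mu_b = c(0, 2.3, 3.4, 3.8, 1.9),
#'                     mu_B = c(0, 1.0, 0.6, 3.9, 1.1),
#'                     sigma0 = 10, sigma = 10, rho_w = 0.9)
#' theta_effects(m)
#' @export
endpoint_model <- function(mu_b, mu_B, sigma0, sigma, rho_w, estimated = FALSE) {
  if (!is.numeric(mu_b) || !is.numeric(mu_B) || length(mu_b) != length(mu_B))
    stop("mu_b and mu_B must be numeric vectors of equal length (k+1)")
  if (length(mu_b) < 2L)
    stop("need at least one experimental arm (length(mu_b) >= 2)")
  if (!all(is.finite(c(mu_b, mu_B, sigma0, sigma, rho_w))))
    stop("all model parameters must be finite")
  if (sigma0 <= 0) stop("sigma0 must be > 0")
  if (sigma <= 0) stop("sigma must be > 0")
  if (rho_w < -1 || rho_w > 1) stop("rho_w must lie in [-1, 1]")
  structure(
    list(mu_b = as.numeric(mu_b), mu_B = as.numeric(mu_B),
         sigma0 = as.numeric(sigma0), sigma = as.numeric(sigma),
         rho_w = as.numeric(rho_w), k = length(mu_b) - 1L,
         estimated = isTRUE(estimated)),
    class = "endpoint_model")
}

#' @export
print.endpoint_model <- function(x, ...) {
  cat(if (x$estimated) "Estimated endpoint model" else "Endpoint model",
      sprintf("(k = %d experimental arms)\n", x$k))
  cat("  early means  :", format(x$mu_b, digits = 4), "\n")
  cat("  final means  :", format(x$mu_B, digits = 4), "\n")
  cat(sprintf("  sigma0 = %.4g, sigma = %.4g, rho_w = %.4g\n",
              x$sigma0, x$sigma, x$rho_w))
  invisible(x)
}

#' Treatment effects on the final and early endpoint
#'
#' `theta_effects()` returns the final-endpoint treatment effects
#' \eqn{\theta_i = \mu_{B,i} - \mu_{B,0}}; `delta_effects()` the early-endpoint
#' effects \eqn{\delta_i = \mu_{b,i} - \mu_{b,0}}, for experimental arms
#' \eqn{i = 1, \dots, k}.
#'
#' @param model an [endpoint_model()].
#' @return numeric vector of length `k`.
#' @export
theta_effects <- function(model) model$mu_B[-1L] - model$mu_B[1L]

#' @rdname theta_effects
#' @export
delta_effects <- function(model) model$mu_b[-1L] - model$mu_b[1L]

#' Two-stage trial design
#'
#' Stagewise per-group sample sizes, significance level and combination
#' weights for a seamless phase II/III design. In stage one each of the
#' `k + 1` groups recruits `N1` patients with early-endpoint data, of whom
#' the first `n1` also have final-endpoint data at the interim analysis;
#' all `N1` final observations are available by the final analysis. Stage two
#' recruits `n2` new patients per group on the selected treatment and
#' control.
#'
#' @param k number of experimental arms (>= 1).
#' @param N1 stage-1 per-group early-endpoint sample size.
#' @param n1 stage-1 per-group final-endpoint sample size at interim
#'   (1 <= n1 <= N1).
#' @param n2 stage-2 per-group sample size (newly recruited patients).
#' @param alpha one-sided familywise significance level, in (0, 1).
#' @param w1,w2 combination weights for the weighted inverse-normal test;
#'   must satisfy `w1^2 + w2^2 = 1`. Defaults to [default_weights()] with
#'   squares proportional to the stagewise per-group sample sizes `N1`
#'   and `n2`.
#' @return An object of class `trial_design`.
#' @examples
#' trial_design(k = 3, N1 = 32, n1 = 4, n2 = 64)
#' @export
trial_design <- function(k, N1, n1, n2, alpha = 0.025, w1 = NULL, w2 = NULL) {
  if (is.null(w1) != is.null(w2))
    stop("supply both weights or neither")
  if (is.null(w1)) {
    w <- default_weights(N1, n2)
    w1 <- w[1L]; w2 <- w[2L]
  }
  validate_design(structure(
    list(k = as.integer(k), N1 = as.integer(N1), n1 = as.integer(n1),
         n2 = as.integer(n2), alpha = as.numeric(alpha),
         w1 = as.numeric(w1), w2 = as.numeric(w2)),
    class = "trial_design"))
}

#' Validate a trial design
#'
#' Checks every design invariant and returns the design unchanged when all
#' hold; otherwise signals an error naming the violated invariant.
#'
#' @param design a [trial_design()] object (or a bare list with the same
#'   fields).
#' @return the validated design, invisibly classed as `trial_design`.
#' @export
validate_design <- function(design) {
  req <- c("k", "N1", "n1", "n2", "alpha", "w1", "w2")
  if (!all(req %in% names(design)))
    stop("design lacks fields: ", paste(setdiff(req, names(design)), collapse = ", "))
  with(design, {
    if (!isTRUE(k >= 1)) stop("k must be >= 1")
    if (!isTRUE(n1 >= 1)) stop("n1 must be >= 1")
    if (!isTRUE(n1 <= N1)) stop("n1 exceeds N1")
    if (!isTRUE(n2 >= 1)) stop("n2 must be >= 1")
    if (!isTRUE(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
    if (!isTRUE(w1 >= 0 && w2 >= 0)) stop("weights must be nonnegative")
    if (abs(w1^2 + w2^2 - 1) > 1e-8) stop("weights not normalized (w1^2 + w2^2 != 1)")
  })
  if (!inherits(design, "trial_design")) class(design) <- "trial_design"
  design
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("Two-stage design: k = %d arms vs control\n", x$k))
  cat(sprintf("  stage 1: N1 = %d early / n1 = %d final per group at interim\n",
              x$N1, x$n1))
  cat(sprintf("  stage 2: n2 = %d per group; alpha = %.4g one-sided\n",
              x$n2, x$alpha))
  cat(sprintf("  combination weights: w1 = %.4f, w2 = %.4f\n", x$w1, x$w2))
  invisible(x)
}

#' Default inverse-normal combination weights
#'
#' Weights whose squares are proportional to the planned stagewise per-group
#' sample sizes, the standard convention making the weighted inverse-normal
#' combination a valid level-alpha test (`w1^2 + w2^2 = 1`).
#'
#' @param stage1_n,stage2_n planned per-group sample sizes for the two
#'   stages (>= 1).
#' @return numeric vector `c(w1, w2)`.
#' @examples
#' default_weights(32, 64)  # c(sqrt(1/3), sqrt(2/3))
#' @export
default_weights <- function(stage1_n, stage2_n) {
  if (!isTRUE(stage1_n >= 1) || !isTRUE(stage2_n >= 1))
    stop("stage sample sizes must be >= 1")
  tot <- stage1_n + stage2_n
  c(sqrt(stage1_n / tot), sqrt(stage2_n / tot))
}
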