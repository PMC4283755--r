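#' Standardized early-endpoint statistics
#'
#' For each experimental arm \eqn{i}, the standardized comparison with
#' control on the early endpoint using all `N1` stage-1 patients per group:
#' \deqn{\tilde Z_i = (\bar X_i - \bar X_0)\sqrt{N_1/2}/\sigma_0.}
#' Under the bivariate-normal model the \eqn{\tilde Z_i} are jointly normal
#' with unit variances and pairwise correlation 1/2 (shared control group).
#'
#' @param stage1 a `stage1_trial` (see [simulate_stage1()]).
#' @param sigma0 early-endpoint standard deviation (> 0), assumed known or
#'   a plug-in estimate.
#' @return numeric vector of length `k`.
#' @export
early_z <- function(stage1, sigma0) {
  if (sigma0 <= 0) stop("sigma0 must be > 0")
  m <- colMeans(stage1$early)
  if (anyNA(m)) stop("early endpoint data contain missing values")
  (m[-1L] - m[1L]) * sqrt(stage1$N1 / 2) / sigma0
}

#' Stage-1 final-endpoint statistics
#'
#' Standardized comparisons with control on the final endpoint using all
#' `N1` stage-1 patients per group (available at the final analysis):
#' \eqn{Z_{i,1} = (\bar Y_i - \bar Y_0)\sqrt{N_1/2}/\sigma}. Same joint law
#' as [early_z()] with means \eqn{\theta_i \sqrt{N_1/2}/\sigma}.
#'
#' @param stage1 a `stage1_trial` whose stage-1 follow-up is complete
#'   (`final_all` present).
#' @param sigma final-endpoint standard deviation (> 0).
#' @return numeric vector of length `k`.
#' @export
final_z_stage1 <- function(stage1, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (is.null(stage1$final_all))
    stop("stage-1 final follow-up incomplete: final_all not available")
  m <- colMeans(stage1$final_all)
  (m[-1L] - m[1L]) * sqrt(stage1$N1 / 2) / sigma
}

#' Stage-2 final-endpoint statistic
#'
#' Standardized comparison of the selected treatment with control using only
#' the `n2` per-group patients recruited in stage two:
#' \eqn{Z_{I,2} = (\bar Y_I - \bar Y_0)\sqrt{n_2/2}/\sigma}; independent of
#' every stage-1 statistic by construction.
#'
#' @param stage2 a `stage2_data` (see [simulate_stage2()]).
#' @param sigma final-endpoint standard deviation (> 0).
#' @return a single numeric statistic.
#' @export
final_z_stage2 <- function(stage2, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  n2 <- length(stage2$control)
  if (n2 < 1L || length(stage2$treatment) != n2) stop("empty or unbalanced stage-2 data")
  (mean(stage2$treatment) - mean(stage2$control)) * sqrt(n2 / 2) / sigma
}

#' Effective information of the efficient-score statistic
#'
#' Information per treatment-control comparison underlying the score
#' statistic that combines the `n1` interim final observations with the `N1`
#' early observations per group:
#' \deqn{I = \left[2\sigma^2\left(\frac{1-\rho_w^2}{n_1} +
#'   \frac{\rho_w^2}{N_1}\right)\right]^{-1}.}
#' At `rho_w = 0` this is the information of a final-endpoint-only comparison
#' on `n1` per group; at `n1 = N1` that of one on `N1` per group; it is
#' increasing in `N1` and in `|rho_w|` and depends on `rho_w` only through
#' its square.
#'
#' @param n1,N1 stage-1 per-group sample sizes (final / early endpoint).
#' @param sigma final-endpoint standard deviation.
#' @param rho_w within-patient correlation.
#' @return information (1 / endpoint-units squared).
#' @export
score_information <- function(n1, N1, sigma, rho_w) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (n1 < 1 || n1 > N1) stop("need 1 <= n1 <= N1")
  1 / (2 * sigma^2 * ((1 - rho_w^2) / n1 + rho_w^2 / N1))
}

#' Efficient-score statistics with known nuisance parameters
#'
#' The standardized score statistic for each treatment effect
#' \eqn{\theta_i} given all stage-1 data at the interim: the adjusted
#' treatment-effect estimate
#' \deqn{\hat\theta_i = (\bar Y_i^{(n_1)} - \bar Y_0^{(n_1)}) -
#'   \gamma\left[(\bar X_i^{(n_1)} - \bar X_0^{(n_1)}) -
#'               (\bar X_i^{(N_1)} - \bar X_0^{(N_1)})\right],}
#' with regression coefficient \eqn{\gamma = \rho_w\sigma/\sigma_0},
#' standardized by its exact standard deviation:
#' \eqn{S_i = \hat\theta_i\sqrt{I}} with \eqn{I} from
#' [score_information()]. The \eqn{S_i} are jointly normal with means
#' \eqn{\theta_i\sqrt{I}}, unit variances and pairwise correlation 1/2.
#'
#' @param stage1 a `stage1_trial`.
#' @param model an [endpoint_model()] (or estimated model) supplying
#'   `sigma0`, `sigma` and `rho_w`.
#' @return list with `score` (length-`k` vector) and `info`.
#' @export
score_statistics_known <- function(stage1, model) {
  s0 <- model$sigma0; s <- model$sigma; r <- model$rho_w
  n1 <- stage1$n1; N1 <- stage1$N1
  gamma <- r * s / s0
  xbarN <- colMeans(stage1$early)
  xbar1 <- colMeans(stage1$early[seq_len(n1), , drop = FALSE])
  ybar1 <- colMeans(stage1$final_interim)
  info <- score_information(n1, N1, s, r)
  th <- (ybar1[-1L] - ybar1[1L]) -
    gamma * ((xbar1[-1L] - xbar1[1L]) - (xbarN[-1L] - xbarN[1L]))
  list(score = unname(th * sqrt(info)), info = info)
}

#' Efficient-score statistics with double-regression estimates
#'
#' Plug-in version of [score_statistics_known()] for unknown nuisance
#' parameters, using the double-regression scheme: the slope \eqn{\gamma} is
#' estimated by pooled within-arm least squares of the final on the early
#' endpoint over the `n1` paired patients of every arm, the residual
#' variance \eqn{\sigma_e^2 = (1-\rho_w^2)\sigma^2} from the pooled residual
#' sum of squares, and the early-endpoint variance from all `N1` values per
#' arm. These replace \eqn{\gamma} and the information
#' \eqn{I = [2(\sigma_e^2/n_1 + \gamma^2\sigma_0^2/N_1)]^{-1}} in the
#' known-parameter formula.
#'
#' @param stage1 a `stage1_trial` with `n1 >= 3` (degrees of freedom for
#'   slope and residual variance).
#' @return list with `score`, `info`, and the plug-in estimates `gamma`,
#'   `sigma0`, `sigma_e`.
#' @export
score_statistics_estimated <- function(stage1) {
  n1 <- stage1$n1; N1 <- stage1$N1; k <- stage1$k
  if (n1 < 3L) stop("n1 >= 3 per arm required to estimate slope and residual variance")
  x1 <- stage1$early[seq_len(n1), , drop = FALSE]
  y1 <- stage1$final_interim
  xc <- sweep(x1, 2L, colMeans(x1))
  yc <- sweep(y1, 2L, colMeans(y1))
  sxx <- sum(xc^2); sxy <- sum(xc * yc)
  if (sxx <= 0) stop("zero early-endpoint variance among paired patients")
  gamma <- sxy / sxx
  rss <- sum((yc - gamma * xc)^2)
  df <- (k + 1L) * (n1 - 1L) - 1L   # pooled within-arm, minus common slope
  sigma_e2 <- rss / df
  ec <- sweep(stage1$early, 2L, colMeans(stage1$early))
  sigma0_hat2 <- sum(ec^2) / ((k + 1L) * (N1 - 1L))
  info <- 1 / (2 * (sigma_e2 / n1 + gamma^2 * sigma0_hat2 / N1))
  xbarN <- colMeans(stage1$early)
  xbar1 <- colMeans(x1); ybar1 <- colMeans(y1)
  th <- (ybar1[-1L] - ybar1[1L]) -
    gamma * ((xbar1[-1L] - xbar1[1L]) - (xbarN[-1L] - xbarN[1L]))
  list(score = unname(th * sqrt(info)), info = info, gamma = gamma,
       sigma0 = sqrt(sigma0_hat2), sigma_e = sqrt(sigma_e2))
}

#' Interim estimation of the endpoint model
#'
#' Pooled-across-arm estimates of all endpoint-model parameters from interim
#' stage-1 data, for use by the data-driven selection rule: per-arm early
#' means over all `N1` values, per-arm final means over the `n1` interim
#' values, pooled within-arm standard deviations, and the pooled within-arm
#' Pearson correlation of the `n1` paired observations, clipped to
#' `[-clip, clip]` so downstream plug-in information stays finite.
#'
#' @param stage1 a `stage1_trial` with `n1 >= 3`.
#' @param clip clipping bound for the estimated correlation (default 0.99).
#' @return an [endpoint_model()] with `estimated = TRUE`.
#' @export
estimate_model <- function(stage1, clip = 0.99) {
  n1 <- stage1$n1; N1 <- stage1$N1; k <- stage1$k
  if (n1 < 3L) stop("n1 >= 3 per arm required for interim estimation")
  x1 <- stage1$early[seq_len(n1), , drop = FALSE]
  y1 <- stage1$final_interim
  xc <- sweep(x1, 2L, colMeans(x1))
  yc <- sweep(y1, 2L, colMeans(y1))
  ec <- sweep(stage1$early, 2L, colMeans(stage1$early))
  s02 <- sum(ec^2) / ((k + 1L) * (N1 - 1L))
  s2 <- sum(yc^2) / ((k + 1L) * (n1 - 1L))
  if (s02 <= 0 || s2 <= 0) stop("zero variance in stage-1 data")
  sxx <- sum(xc^2); syy <- sum(yc^2)
  if (sxx <= 0) stop("zero variance in stage-1 data")
  rho <- sum(xc * yc) / sqrt(sxx * syy)
  rho <- max(-clip, min(clip, rho))
  endpoint_model(mu_b = colMeans(stage1$early),
                 mu_B = colMeans(y1),
                 sigma0 = sqrt(s02), sigma = sqrt(s2), rho_w = rho,
                 estimated = TRUE)
}
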