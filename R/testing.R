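#' Dunnett intersection p-value
#'
#' One-sided p-value for an intersection hypothesis over `m` treatment
#' comparisons with a shared control, using the maximum statistic
#' \eqn{Z^{max}}: \eqn{p = 1 - P(\max_{i} Z_i \le z_{obs})} where the
#' \eqn{Z_i} are standard normal with pairwise correlation 1/2, evaluated
#' via [mvn_orthant()].
#'
#' @param z_obs observed maximum statistic.
#' @param m number of comparisons in the intersection (>= 1).
#' @return the p-value.
#' @examples
#' dunnett_pvalue(qnorm(0.975), 1)  # 0.025
#' @export
dunnett_pvalue <- function(z_obs, m) {
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  if (z_obs == -Inf) return(1)
  if (z_obs == Inf) return(0)
  if (m == 1L) return(pnorm(z_obs, lower.tail = FALSE))
  cov <- (diag(m) + 1) / 2
  1 - mvn_orthant(rep(-z_obs, m), cov)
}

#' Weighted inverse-normal combination of stagewise p-values
#'
#' \eqn{C(p_1, p_2) = 1 - \Phi(w_1\Phi^{-1}(1-p_1) + w_2\Phi^{-1}(1-p_2))}
#' with pre-specified weights satisfying \eqn{w_1^2 + w_2^2 = 1}; monotone
#' nondecreasing in each argument. A stagewise p-value of 1 maps through
#' \eqn{\Phi^{-1}(0) = -\infty}: the combination is 1 whenever its weight is
#' positive (and the other term is finite).
#'
#' @param p1,p2 stagewise p-values in (0, 1].
#' @param w1,w2 combination weights, `w1^2 + w2^2 = 1`.
#' @return the combined p-value.
#' @export
combine_pvalues <- function(p1, p2, w1, w2) {
  if (abs(w1^2 + w2^2 - 1) > 1e-8) stop("weights not normalized")
  if (p1 <= 0 || p1 > 1 || p2 <= 0 || p2 > 1) stop("p-values must lie in (0, 1]")
  if (w1 == 0) return(p2)
  if (w2 == 0) return(p1)
  q1 <- qnorm(p1, lower.tail = FALSE)  # Phi^{-1}(1 - p1), -Inf at p = 1
  q2 <- qnorm(p2, lower.tail = FALSE)
  z <- w1 * q1 + w2 * q2
  if (is.nan(z)) return(1)  # +Inf and -Inf terms: dominated by the p = 1 stage
  pnorm(z, lower.tail = FALSE)
}

#' Conservative stage-2 p-value policy
#'
#' The stage-2 p-value for an intersection hypothesis over subset `S` is the
#' selected treatment's p-value when the selected arm belongs to `S`, and 1
#' otherwise (no stage-2 evidence is claimed against hypotheses not carried
#' forward).
#'
#' @param S integer vector, the subset of experimental arms.
#' @param I selected arm index.
#' @param p_I stage-2 p-value of the selected treatment, in (0, 1].
#' @return the subset's stage-2 p-value.
#' @export
stage2_pvalue_policy <- function(S, I, p_I) {
  if (p_I <= 0 || p_I > 1) stop("p_I must lie in (0, 1]")
  if (I %in% S) p_I else 1
}

#' Closed test over all intersection hypotheses
#'
#' Confirmatory analysis after selection: for every nonempty subset
#' \eqn{S \subseteq \{1..k\}} the stage-1 p-value is the Dunnett p-value of
#' \eqn{\max_{i \in S} Z_{i,1}} (all `N1` stage-1 final observations per
#' group), the stage-2 p-value follows [stage2_pvalue_policy()] with
#' \eqn{p_I = 1 - \Phi(Z_{I,2})}, and the two are combined by the weighted
#' inverse-normal rule. An elementary hypothesis \eqn{H_{0i}} is rejected at
#' familywise level `alpha` iff every intersection containing `i` has a
#' combined p-value at most `alpha` (closure principle; strong familywise
#' error control for any stage-1-based selection rule).
#'
#' @param z1_final numeric vector of `k` stage-1 final statistics
#'   ([final_z_stage1()]).
#' @param I selected arm index.
#' @param z2 stage-2 statistic of the selected arm ([final_z_stage2()]).
#' @param design a [trial_design()] (uses `alpha`, `w1`, `w2`).
#' @return An object of class `closed_test_result`: list with `rejected`
#'   (logical vector of length `k`), `selected`, `alpha`, and `subsets`, a
#'   data frame with one row per intersection (`subset`, `p1`, `p2`,
#'   `combined`, `reject`).
#' @export
closed_test <- function(z1_final, I, z2, design) {
  design <- validate_design(design)
  k <- length(z1_final)
  if (k != design$k) stop("z1_final length must equal design k")
  if (k > 20L) stop("k > 20 refused (2^k - 1 intersections)")
  I <- as.integer(I)
  if (I < 1L || I > k) stop("selected arm out of range 1..k")
  p_I <- pnorm(z2, lower.tail = FALSE)
  subsets <- unlist(lapply(seq_len(k), function(m)
    combn(k, m, simplify = FALSE)), recursive = FALSE)
  ns <- length(subsets)
  p1 <- p2 <- Cv <- numeric(ns)
  for (s in seq_len(ns)) {
    S <- subsets[[s]]
    p1[s] <- dunnett_pvalue(max(z1_final[S]), length(S))
    p2[s] <- stage2_pvalue_policy(S, I, max(p_I, .Machine$double.xmin))
    Cv[s] <- combine_pvalues(max(p1[s], .Machine$double.xmin), p2[s],
                             design$w1, design$w2)
  }
  reject_S <- Cv <= design$alpha
  tab <- data.frame(subset = vapply(subsets, paste, "", collapse = ","),
                    p1 = p1, p2 = p2, combined = Cv, reject = reject_S,
                    stringsAsFactors = FALSE)
  rejected <- vapply(seq_len(k), function(i) {
    all(reject_S[vapply(subsets, function(S) i %in% S, logical(1))])
  }, logical(1))
  structure(list(rejected = rejected, selected = I, alpha = design$alpha,
                 subsets = tab),
            class = "closed_test_result")
}

#' @export
print.closed_test_result <- function(x, ...) {
  cat(sprintf("Closed test at one-sided alpha = %.4g (selected arm %d)\n",
              x$alpha, x$selected))
  rej <- which(x$rejected)
  cat("  rejected elementary hypotheses:",
      if (length(rej)) paste0("H0", rej, collapse = ", ") else "none", "\n")
  invisible(x)
}
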