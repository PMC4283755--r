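#' Multivariate normal orthant probability
#'
#' \eqn{P(X_1 \le 0, \dots, X_d \le 0)} for a (possibly degenerate)
#' multivariate normal vector. Three routes, all deterministic:
#' \itemize{
#'   \item compound-symmetric correlation (equal variances, equal
#'     nonnegative off-diagonal correlation, as for every difference vector
#'     arising from a shared control group): exact reduction to a
#'     one-dimensional Gaussian integral evaluated by adaptive quadrature;
#'   \item general positive-definite covariance: Miwa's recursive algorithm
#'     (`mvtnorm::pmvnorm`), exact to ~1e-6 and fully deterministic;
#'   \item rank-deficient covariance through coordinates perfectly
#'     correlated (\eqn{\pm 1}) with another coordinate or with zero
#'     variance: the redundant coordinates are folded into interval
#'     constraints on their representatives (exact), and the reduced
#'     rectangle probability is computed as above.
#' }
#'
#' @param mean mean vector.
#' @param cov covariance matrix (symmetric positive semi-definite).
#' @return the orthant probability.
#' @examples
#' mvn_orthant(c(0, 0), diag(2))               # 0.25
#' mvn_orthant(c(0, 0), matrix(c(1, .5, .5, 1), 2))  # 1/4 + asin(.5)/(2*pi)
#' @export
mvn_orthant <- function(mean, cov) {
  d <- length(mean)
  cov <- as.matrix(cov)
  if (!all(dim(cov) == d)) stop("mean and cov dimensions disagree")
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("cov must be symmetric")
  mvn_rectangle(rep(-Inf, d), rep(0, d), mean, (cov + t(cov)) / 2)
}

# Rectangle probability P(lower < X <= upper), same engine as mvn_orthant.
mvn_rectangle <- function(lower, upper, mean, cov) {
  d <- length(mean)
  if (any(lower >= upper)) return(0)
  v <- diag(cov)
  if (min(v) < -1e-10) stop("cov must be positive semi-definite")
  # zero-variance coordinates: deterministic, check and drop
  zv <- v <= 1e-14 * max(1, max(v))
  if (any(zv)) {
    if (any(mean[zv] <= lower[zv] | mean[zv] > upper[zv])) return(0)
    keep <- !zv
    if (!any(keep)) return(1)
    return(mvn_rectangle(lower[keep], upper[keep], mean[keep],
                         cov[keep, keep, drop = FALSE]))
  }
  sdv <- sqrt(v)
  corr <- cov / tcrossprod(sdv)
  if (any(abs(corr) > 1 + 1e-8)) stop("cov must be positive semi-definite")
  corr[] <- pmin(1, pmax(-1, corr))
  # fold coordinates perfectly correlated with an earlier one into bounds
  if (d > 1L && any(abs(corr[upper.tri(corr)]) >= 1 - 1e-10)) {
    l <- (lower - mean) / sdv; u <- (upper - mean) / sdv
    rep_of <- rep(NA_integer_, d); reps <- integer(0)
    for (j in seq_len(d)) {
      hit <- NA_integer_; sgn <- 1
      for (i in reps) {
        if (abs(corr[i, j]) >= 1 - 1e-10) { hit <- i; sgn <- sign(corr[i, j]); break }
      }
      if (is.na(hit)) { reps <- c(reps, j); rep_of[j] <- j }
      else {
        # standardized x_j = sgn * x_hit exactly
        if (sgn > 0) { l[hit] <- max(l[hit], l[j]); u[hit] <- min(u[hit], u[j]) }
        else { l[hit] <- max(l[hit], -u[j]); u[hit] <- min(u[hit], -l[j]) }
        rep_of[j] <- hit
      }
    }
    if (any(l[reps] >= u[reps])) return(0)
    return(mvn_rectangle(l[reps], u[reps], rep(0, length(reps)),
                         corr[reps, reps, drop = FALSE]))
  }
  if (d == 1L)
    return(pnorm(upper, mean, sdv) - pnorm(lower, mean, sdv))
  # compound symmetry fast path: corr = (1-r) I + r J, r in [0, 1)
  off <- corr[upper.tri(corr)]
  r <- off[1L]
  if (r >= 0 && r < 1 && max(abs(off - r)) < 1e-12) {
    l <- (lower - mean) / sdv; u <- (upper - mean) / sdv
    sr <- sqrt(r); s1 <- sqrt(1 - r)
    f <- function(z) {
      out <- dnorm(z)
      for (i in seq_len(d))
        out <- out * (pnorm((u[i] - sr * z) / s1) - pnorm((l[i] - sr * z) / s1))
      out
    }
    val <- integrate(f, -Inf, Inf, rel.tol = 1e-10, abs.tol = 1e-12,
                     stop.on.error = FALSE)
    if (val$message == "OK") return(min(1, max(0, val$value)))
  }
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev)) stop("cov must be positive semi-definite")
  p <- if (d <= 8L)
    mvtnorm::pmvnorm(lower = lower, upper = upper, mean = mean, sigma = cov,
                     algorithm = mvtnorm::Miwa(steps = 4097, checkCorr = FALSE))
  else {
    # deterministic quasi-Monte-Carlo: fixed internal seed, restored after
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(20140502L)
    mvtnorm::pmvnorm(lower = lower, upper = upper, mean = mean, sigma = cov,
                     algorithm = mvtnorm::GenzBretz(abseps = 1e-7, maxpts = 250000L))
  }
  min(1, max(0, as.numeric(p)))
}

# means of the k early-endpoint statistics and of the k score statistics
selection_stat_means <- function(model, n1, N1) {
  info <- score_information(n1, N1, model$sigma, model$rho_w)
  list(m_friede = delta_effects(model) * sqrt(N1 / 2) / model$sigma0,
       m_stallard = theta_effects(model) * sqrt(info), info = info)
}

# P(arm i is the argmax of k jointly normal statistics with means m, unit
# variances, pairwise correlation 1/2): orthant probability of the k-1
# differences, which have unit variances and correlation 1/2 again.
argmax_prob <- function(i, m) {
  k <- length(m)
  if (k == 1L) return(1)
  diff_means <- m[-i] - m[i]
  cov <- (diag(k - 1L) + 1) / 2
  mvn_orthant(diff_means, cov)
}

#' Early-endpoint-rule selection probability
#'
#' Probability that arm `i` attains the maximal early-endpoint statistic
#' \eqn{\tilde Z_i}, i.e. is selected by the early-endpoint-only rule:
#' the orthant probability that all differences \eqn{\tilde Z_j - \tilde Z_i}
#' are nonpositive (unit variances, pairwise correlation 1/2, means
#' \eqn{(\mu_{b,j} - \mu_{b,i})\sqrt{N_1/2}/\sigma_0}). Depends only on the
#' early-endpoint means and SD, not on `mu_B`, `sigma` or `rho_w`.
#'
#' @param i experimental arm index, in `1..k`.
#' @param mu_b early-endpoint group means (control first, length `k+1`).
#' @param sigma0 early-endpoint SD (> 0).
#' @param N1 stage-1 per-group early-endpoint sample size.
#' @return selection probability.
#' @examples
#' friede_selection_prob(3, c(0, 2.3, 3.4, 3.8, 1.9), sigma0 = 10, N1 = 45)
#' @export
friede_selection_prob <- function(i, mu_b, sigma0, N1) {
  if (sigma0 <= 0) stop("sigma0 must be > 0")
  k <- length(mu_b) - 1L
  if (k < 1L) stop("need at least one experimental arm")
  i <- as.integer(i)
  if (i < 1L || i > k) stop("arm index out of range 1..k")
  m <- (mu_b[-1L] - mu_b[1L]) * sqrt(N1 / 2) / sigma0
  argmax_prob(i, m)
}

#' Efficient-score-rule selection probability
#'
#' Probability that arm `i` attains the maximal score statistic \eqn{S_i}
#' (the rule combining interim final-endpoint data with all early-endpoint
#' data): orthant probability of the differences \eqn{S_j - S_i} with means
#' \eqn{(\theta_j - \theta_i)\sqrt{I}}, unit variances and correlation 1/2,
#' where \eqn{I} is [score_information()]. Invariant to the sign of `rho_w`.
#'
#' @param i experimental arm index, in `1..k`.
#' @param model an [endpoint_model()] (true or estimated values).
#' @param n1,N1 stage-1 per-group sample sizes (final / early endpoint).
#' @return selection probability.
#' @export
stallard_selection_prob <- function(i, model, n1, N1) {
  stopifnot(inherits(model, "endpoint_model"))
  k <- model$k
  i <- as.integer(i)
  if (i < 1L || i > k) stop("arm index out of range 1..k")
  ms <- selection_stat_means(model, n1, N1)
  argmax_prob(i, ms$m_stallard)
}

#' Joint selection probabilities of the two rules
#'
#' Full 2x2 table of "early-endpoint rule selects arm `i`" against
#' "score rule selects arm `i`", from the joint \eqn{2(k-1)}-dimensional
#' normal law of the early-statistic differences and score-statistic
#' differences. The cross-covariance
#' \eqn{\mathrm{Cov}(S_i, \tilde Z_j) = \rho_w \sigma \sqrt{I}\,
#' (1 + 1[i=j])/\sqrt{2 N_1}} carries the sign of `rho_w`, so the agreement
#' probability differs between \eqn{+\rho_w} and \eqn{-\rho_w} even though
#' both marginals do not. At \eqn{|\rho_w| = 1} the law is degenerate (each
#' score difference is an affine function of its early difference) and the
#' probability is computed exactly by interval reduction.
#'
#' @param i experimental arm index, in `1..k`.
#' @param model an [endpoint_model()].
#' @param design a [trial_design()] (uses `n1` and `N1`).
#' @return An object of class `joint_selection_table`: list with cells
#'   `p_both`, `p_friede_only`, `p_stallard_only`, `p_neither`, marginals
#'   `p_friede`, `p_stallard`, and `arm`.
#' @examples
#' m <- endpoint_model(c(0, 0.2, 0.1, 0.05), c(0, 0.3, 0.15, 0.075), 1, 1, 0.9)
#' d <- trial_design(k = 3, N1 = 32, n1 = 4, n2 = 64)
#' joint_selection_prob(1, m, d)
#' @export
joint_selection_prob <- function(i, model, design) {
  stopifnot(inherits(model, "endpoint_model"))
  design <- validate_design(design)
  k <- model$k
  if (design$k != k) stop("model and design disagree on k")
  i <- as.integer(i)
  if (i < 1L || i > k) stop("arm index out of range 1..k")
  n1 <- design$n1; N1 <- design$N1
  ms <- selection_stat_means(model, n1, N1)
  if (k == 1L) {
    tab <- list(arm = i, p_both = 1, p_friede_only = 0, p_stallard_only = 0,
                p_neither = 0, p_friede = 1, p_stallard = 1)
    class(tab) <- "joint_selection_table"
    return(tab)
  }
  # joint covariance of (Ztilde_1..k, S_1..k)
  cs <- (diag(k) + 1) / 2
  cross <- model$rho_w * model$sigma * sqrt(ms$info) *
    (matrix(1, k, k) + diag(k)) / sqrt(2 * N1)
  C <- rbind(cbind(cs, cross), cbind(cross, cs))
  mu <- c(ms$m_friede, ms$m_stallard)
  A <- matrix(0, 2L * (k - 1L), 2L * k)
  row <- 0L
  for (j in setdiff(seq_len(k), i)) {
    row <- row + 1L; A[row, j] <- 1; A[row, i] <- -1
  }
  for (j in setdiff(seq_len(k), i)) {
    row <- row + 1L; A[row, k + j] <- 1; A[row, k + i] <- -1
  }
  md <- as.vector(A %*% mu)
  Cd <- A %*% C %*% t(A)
  idxF <- seq_len(k - 1L); idxS <- k - 1L + idxF
  p_f <- mvn_orthant(md[idxF], Cd[idxF, idxF, drop = FALSE])
  p_s <- mvn_orthant(md[idxS], Cd[idxS, idxS, drop = FALSE])
  p_b <- mvn_orthant(md, Cd)
  tab <- list(arm = i,
              p_both = p_b,
              p_friede_only = max(0, p_f - p_b),
              p_stallard_only = max(0, p_s - p_b),
              p_neither = max(0, 1 - p_f - p_s + p_b),
              p_friede = p_f, p_stallard = p_s)
  class(tab) <- "joint_selection_table"
  tab
}

#' @export
print.joint_selection_table <- function(x, ...) {
  cat(sprintf("Joint selection table for arm %d\n", x$arm))
  m <- matrix(c(x$p_both, x$p_friede_only, x$p_stallard_only, x$p_neither),
              2, 2, dimnames = list(score = c("selects", "other"),
                                    early = c("selects", "other")))
  print(round(m, 4))
  cat(sprintf("marginals: early rule %.4f, score rule %.4f; at least one %.4f\n",
              x$p_friede, x$p_stallard, 1 - x$p_neither))
  invisible(x)
}
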