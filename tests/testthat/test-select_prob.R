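test_that("orthant probabilities match closed forms and an independent oracle", {
  expect_equal(mvn_orthant(0, matrix(1)), 0.5)
  expect_equal(mvn_orthant(c(0, 0), diag(2)), 0.25, tolerance = 1e-8)
  # bivariate, correlation 1/2: P = 1/4 + asin(rho) / (2 pi)
  expect_equal(mvn_orthant(c(0, 0), matrix(c(1, .5, .5, 1), 2)),
               0.25 + asin(0.5) / (2 * pi), tolerance = 1e-6)
  # non-compound-symmetric covariance vs quasi-Monte-Carlo oracle
  cv <- matrix(c(1, .3, -.2, .3, 2, .1, -.2, .1, 1.5), 3)
  mu <- c(0.2, -0.4, 0.1)
  expect_equal(mvn_orthant(mu, cv), oracle_orthant(mu, cv), tolerance = 2e-6)
  expect_error(mvn_orthant(c(0, 0), matrix(c(1, 2, 3, 1), 2)), "symmetric")
  expect_error(mvn_orthant(c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "semi-definite")
})

test_that("degenerate covariances reduce exactly", {
  # x2 = -x1: P(x1 <= 0, -x1 <= 0) = P(x1 = 0) = 0 for continuous x1
  cv <- matrix(c(1, -1, -1, 1), 2)
  expect_equal(mvn_orthant(c(0, 0), cv), 0)
  # x2 = x1 + shift in mean: tighter of the two bounds applies
  expect_equal(mvn_orthant(c(-1, 0), matrix(c(1, 1, 1, 1), 2)), pnorm(0),
               tolerance = 1e-10)
  # zero-variance coordinate with nonpositive mean drops out
  cv3 <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1))
  expect_equal(mvn_orthant(c(0, -5, 0), cv3), 0.25, tolerance = 1e-8)
  expect_equal(mvn_orthant(c(0, 5, 0), cv3), 0)
})

test_that("early-rule probabilities are exchangeable, sum to one, and match simulation", {
  expect_equal(vapply(1:4, friede_selection_prob, numeric(1),
                      mu_b = rep(0, 5), sigma0 = 1, N1 = 20),
               rep(0.25, 4), tolerance = 1e-6)
  mu_b <- c(0, 0.2, 0.1, 0.05)
  p <- vapply(1:3, friede_selection_prob, numeric(1),
              mu_b = mu_b, sigma0 = 1, N1 = 32)
  expect_equal(sum(p), 1, tolerance = 1e-5)
  B <- 200000
  b <- simulate_selection_batch(endpoint_model(mu_b, rep(0, 4), 1, 1, 0),
                                null_design_61(), B, seed = 51)
  emp <- tabulate(apply(b$z_early, 1, which.max), 3) / B
  for (i in 1:3)
    expect_lt(abs(emp[i] - p[i]), 3 * sqrt(p[i] * (1 - p[i]) / B))
})

test_that("score-rule probabilities: exchangeability, sign symmetry, monotonicity, simulation", {
  m0 <- endpoint_model(c(0, 1, 2, 3), rep(0.5, 4), 1, 1, 0.4)
  expect_equal(vapply(1:3, stallard_selection_prob, numeric(1),
                      model = m0, n1 = 4, N1 = 32),
               rep(1 / 3, 3), tolerance = 1e-6)

  m <- endpoint_model(c(0, .2, .1, .05), c(0, .3, .15, .075), 1, 1, 0.7)
  mneg <- endpoint_model(c(0, .2, .1, .05), c(0, .3, .15, .075), 1, 1, -0.7)
  for (i in 1:3)
    expect_equal(stallard_selection_prob(i, m, 4, 32),
                 stallard_selection_prob(i, mneg, 4, 32), tolerance = 1e-12)
  p <- vapply(1:3, stallard_selection_prob, numeric(1), model = m,
              n1 = 4, N1 = 32)
  expect_equal(sum(p), 1, tolerance = 1e-5)

  # increasing theta_1 cannot decrease arm 1's probability
  m_hi <- endpoint_model(c(0, .2, .1, .05), c(0, .5, .15, .075), 1, 1, 0.7)
  expect_gte(stallard_selection_prob(1, m_hi, 4, 32) + 1e-9,
             stallard_selection_prob(1, m, 4, 32))

  B <- 200000
  b <- simulate_selection_batch(m, null_design_61(), B, seed = 52)
  emp <- tabulate(apply(b$score, 1, which.max), 3) / B
  for (i in 1:3)
    expect_lt(abs(emp[i] - p[i]), 3 * sqrt(p[i] * (1 - p[i]) / B))
})

test_that("early-rule probability ignores the final endpoint and correlation", {
  # identical early parameters, wildly different final parameters
  p1 <- friede_selection_prob(2, c(0, .2, .3), 1.5, 24)
  p2 <- friede_selection_prob(2, c(0, .2, .3), 1.5, 24)
  expect_identical(p1, p2)
  args <- formals(friede_selection_prob)
  expect_false(any(c("mu_B", "sigma", "rho_w") %in% names(args)))
})

test_that("joint table is coherent with its marginals", {
  ae <- agreement_example(0.6)
  tab <- joint_selection_prob(1, ae$model, ae$design)
  expect_equal(tab$p_friede,
               friede_selection_prob(1, ae$model$mu_b, 1, 32), tolerance = 1e-5)
  expect_equal(tab$p_stallard,
               stallard_selection_prob(1, ae$model, 4, 32), tolerance = 1e-5)
  expect_equal(tab$p_both + tab$p_friede_only, tab$p_friede, tolerance = 1e-5)
  expect_equal(tab$p_both + tab$p_stallard_only, tab$p_stallard, tolerance = 1e-5)
  expect_lte(tab$p_both, min(tab$p_friede, tab$p_stallard) + 1e-9)
  cells <- c(tab$p_both, tab$p_friede_only, tab$p_stallard_only, tab$p_neither)
  expect_true(all(cells >= 0))
  expect_equal(sum(cells), 1, tolerance = 1e-5)
})

test_that("agreement depends on the sign of the correlation, marginals do not", {
  neg <- agreement_example(-0.9); pos <- agreement_example(0.9)
  tn <- joint_selection_prob(1, neg$model, neg$design)
  tp <- joint_selection_prob(1, pos$model, pos$design)
  expect_equal(tn$p_friede, tp$p_friede, tolerance = 1e-6)
  expect_equal(tn$p_stallard, tp$p_stallard, tolerance = 1e-6)
  expect_gt(tp$p_both - tn$p_both, 0.1)
})

test_that("perfect positive correlation with matched effects forces agreement", {
  # at rho_w = 1 the score statistics are an affine image of the early
  # statistics exactly when theta = (sigma/sigma0) * delta
  m <- endpoint_model(c(0, .2, .1, .05), c(0, .4, .2, .1), 1, 2, 1)
  d <- null_design_61()
  tab <- joint_selection_prob(1, m, d)
  expect_equal(tab$p_both, tab$p_friede, tolerance = 1e-6)
  expect_equal(tab$p_both, tab$p_stallard, tolerance = 1e-6)
  # and at rho_w = -1 under the global null the two rules never agree
  mn <- endpoint_model(rep(0, 4), rep(0, 4), 1, 1, -1)
  tn <- joint_selection_prob(1, mn, d)
  expect_equal(tn$p_both, 0)
  expect_equal(tn$p_friede, 1 / 3, tolerance = 1e-6)
})

test_that("joint table matches empirical agreement frequencies", {
  d <- null_design_61()
  m <- endpoint_model(rep(0, 4), rep(0, 4), 1, 1, 0)  # rho 0: rules independent
  tab <- joint_selection_prob(1, m, d)
  B <- 200000
  b <- simulate_selection_batch(m, d, B, seed = 53)
  f1 <- apply(b$z_early, 1, which.max) == 1
  s1 <- apply(b$score, 1, which.max) == 1
  se <- function(p) 3 * sqrt(p * (1 - p) / B)
  expect_lt(abs(mean(f1 & s1) - tab$p_both), se(tab$p_both))
  expect_lt(abs(mean(f1 & !s1) - tab$p_friede_only), se(tab$p_friede_only))
  expect_lt(abs(mean(!f1 & s1) - tab$p_stallard_only), se(tab$p_stallard_only))
  expect_equal(tab$p_both, tab$p_friede * tab$p_stallard, tolerance = 1e-5)
})
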