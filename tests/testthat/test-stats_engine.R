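test_that("standardized statistics agree with hand computation", {
  # N1 = 2, control early (0,0), arm-1 early (1,1), sigma0 = 1 -> Z~ = 1
  s1 <- make_stage1(early = cbind(c(0, 0), c(1, 1)),
                    final_interim = cbind(c(0, 0), c(2, 2)),
                    final_all = cbind(c(0, 0), c(2, 2)))
  expect_equal(unname(early_z(s1, 1)), 1)
  expect_equal(unname(final_z_stage1(s1, 2)), 1)
  expect_equal(unname(early_z(s1, 2)), 0.5)

  # equal group means -> 0
  s0 <- make_stage1(early = cbind(c(1, 3), c(3, 1)),
                    final_interim = cbind(c(1, 3), c(3, 1)),
                    final_all = cbind(c(1, 3), c(3, 1)))
  expect_equal(unname(early_z(s0, 1)), 0)
  expect_equal(unname(final_z_stage1(s0, 1)), 0)

  # stage 2: n2 = 8, mean difference 1, sigma = 1 -> sqrt(8/2) = 2
  s2 <- structure(list(selected = 1L, control = rep(0, 8),
                       treatment = rep(1, 8)), class = "stage2_data")
  expect_equal(final_z_stage2(s2, 1), 2)
})

test_that("statistics are invariant to a common location shift", {
  d <- trial_design(k = 3, N1 = 16, n1 = 6, n2 = 10)
  m <- endpoint_model(c(0, .2, .1, .05), c(0, .3, .2, .1), 1, 1, 0.6)
  s1 <- simulate_stage1(m, d, seed = 31)
  sh <- s1
  sh$early <- s1$early + 7
  sh$final_interim <- s1$final_interim + 7
  sh$final_all <- s1$final_all + 7
  expect_equal(early_z(sh, 1), early_z(s1, 1))
  expect_equal(final_z_stage1(sh, 1), final_z_stage1(s1, 1))
  expect_equal(score_statistics_known(sh, m)$score,
               score_statistics_known(s1, m)$score)
})

test_that("score information has the stated limits and monotonicity", {
  expect_equal(score_information(4, 32, 1, 0), 1 / (2 / 4))
  expect_equal(score_information(32, 32, 1, 0.7), 32 / 2)
  expect_equal(score_information(4, 32, 1, 0.5), score_information(4, 32, 1, -0.5))
  expect_lt(score_information(4, 32, 1, 0.3), score_information(4, 32, 1, 0.8))
  expect_lt(score_information(4, 32, 1, 0.5), score_information(4, 64, 1, 0.5))
  expect_lt(score_information(4, 32, 2, 0.5), score_information(4, 32, 1, 0.5))
})

test_that("known-parameter score reduces to final-only statistics in limit cases", {
  d <- trial_design(k = 2, N1 = 12, n1 = 12, n2 = 10)
  m <- endpoint_model(c(0, 1, 2), c(0, 1, 0.5), 2, 3, 0.6)
  s1 <- simulate_stage1(m, d, seed = 41)
  # n1 = N1: early adjustment vanishes for any rho_w
  expect_equal(score_statistics_known(s1, m)$score,
               unname(final_z_stage1(s1, m$sigma)), tolerance = 1e-12)
  # rho_w = 0: final-only statistic on the n1 paired patients
  d2 <- trial_design(k = 2, N1 = 12, n1 = 5, n2 = 10)
  m0 <- endpoint_model(c(0, 1, 2), c(0, 1, 0.5), 2, 3, 0)
  s1b <- simulate_stage1(m0, d2, seed = 42)
  ybar <- colMeans(s1b$final_interim)
  expect_equal(score_statistics_known(s1b, m0)$score,
               unname((ybar[-1] - ybar[1]) * sqrt(5 / 2) / 3), tolerance = 1e-12)
})

test_that("score statistics follow the stated multivariate normal law", {
  d <- null_design_61()
  m <- endpoint_model(c(0, .2, .1, .05), c(0, .3, .15, .075), 1, 1, 0.5)
  B <- 100000
  b <- simulate_selection_batch(m, d, B, seed = 8)
  I <- score_information(4, 32, 1, 0.5)
  expect_equal(b$info, I)
  for (i in 1:3) {
    expect_lt(abs(mean(b$score[, i]) - theta_effects(m)[i] * sqrt(I)),
              4 / sqrt(B))
    expect_lt(abs(var(b$score[, i]) - 1), 4 * sqrt(2 / B))
  }
  expect_lt(abs(cor(b$score[, 1], b$score[, 2]) - 0.5), 4 / sqrt(B))
})

test_that("double-regression plug-in is consistent for the known score", {
  d <- trial_design(k = 1, N1 = 10000, n1 = 10000, n2 = 10)
  m <- endpoint_model(c(0, 0.1), c(0, 0.1), 1, 1, 0.5)
  s1 <- simulate_stage1(m, d, seed = 17)
  est <- score_statistics_estimated(s1)
  kn <- score_statistics_known(s1, m)
  expect_lt(abs(est$score - kn$score), 0.05)
  expect_lt(abs(est$info / kn$info - 1), 0.05)
})

test_that("degenerate interim data are caught or clipped", {
  s1 <- make_stage1(early = cbind(c(1, 2, 3), c(2, 3, 4)),
                    final_interim = cbind(c(2, 4, 6), c(4, 6, 8)))
  est <- estimate_model(s1)
  expect_equal(est$rho_w, 0.99)
  expect_true(all(is.finite(score_statistics_estimated(s1)$score)))

  s2 <- make_stage1(early = matrix(1, 3, 2), final_interim = matrix(2, 3, 2))
  expect_error(estimate_model(s2), "zero variance")

  few <- make_stage1(early = cbind(rnorm(4), rnorm(4)),
                     final_interim = cbind(rnorm(2), rnorm(2)))
  expect_error(score_statistics_estimated(few), "n1 >= 3")
})

test_that("interim estimation recovers the true parameters at large n", {
  d <- trial_design(k = 1, N1 = 50000, n1 = 50000, n2 = 10)
  m <- endpoint_model(c(0.5, 1.5), c(1, 2), 1, 1, 0.5)
  s1 <- simulate_stage1(m, d, seed = 23)
  est <- estimate_model(s1)
  expect_lt(abs(est$sigma0 - 1), 0.02)
  expect_lt(abs(est$sigma - 1), 0.02)
  expect_lt(abs(est$rho_w - 0.5), 0.01)  # within 2% of 0.5
  expect_lt(max(abs(est$mu_b - m$mu_b)), 0.02)
  expect_lt(max(abs(est$mu_B - m$mu_B)), 0.02)
  expect_true(est$estimated)
})
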