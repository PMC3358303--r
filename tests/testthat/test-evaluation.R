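fake_fits <- function(est, se = rep(0.1, length(est)), converged = TRUE,
                      corrected = FALSE) {
  z <- qnorm(0.975)
  data.frame(beta1_hat = est, se1 = se,
             ci_low = est - z * se, ci_high = est + z * se,
             converged = converged, corrected = corrected,
             orr_hat = 1 - exp(est))
}

test_that("summarize_fits computes the performance metrics", {
  # degenerate: every estimate equals the truth, CIs cover it and exclude 0
  f <- fake_fits(rep(-0.315, 10), se = rep(0.05, 10))
  s <- summarize_fits(f, -0.315)
  expect_equal(s$bias, 0)
  expect_equal(s$empirical_sd, 0)
  expect_equal(s$mse, 0)
  expect_equal(s$coverage, 1)
  expect_equal(s$power, 1)
  expect_identical(s$n_effective, 10L)

  # hand-checkable mixture
  est <- c(-0.5, -0.1, 0.2, -0.4)
  f2 <- fake_fits(est, se = rep(0.12, 4))
  s2 <- summarize_fits(f2, -0.2)
  expect_equal(s2$bias, mean(est) + 0.2)
  expect_equal(s2$empirical_sd, sd(est))
  expect_equal(s2$mse, mean((est + 0.2)^2))
  expect_equal(s2$coverage, mean(abs(est + 0.2) <= qnorm(0.975) * 0.12))
  expect_equal(s2$power, mean(abs(est) > qnorm(0.975) * 0.12))

  expect_error(summarize_fits(f[0, ], 0))
  expect_error(summarize_fits(f[1, , drop = FALSE], 0), "at least 2")
})

test_that("the MSE identity holds: mse = bias^2 + sd^2 (n-1)/n", {
  set.seed(9)
  for (i in 1:20) {
    ne <- sample(5:200, 1)
    f <- fake_fits(rnorm(ne, -0.3, 0.4))
    s <- summarize_fits(f, -0.315)
    expect_lt(abs(s$mse - (s$bias^2 + s$empirical_sd^2 * (ne - 1) / ne)), 1e-12)
  }
})

test_that("non-converged replicates are excluded and counted; corrected are flagged", {
  f <- fake_fits(c(-0.2, -0.3, -0.4, 5),
                 converged = c(TRUE, TRUE, TRUE, FALSE),
                 corrected = c(FALSE, TRUE, FALSE, FALSE))
  s <- summarize_fits(f, -0.3)
  expect_identical(s$n_effective, 3L)
  expect_identical(s$n_nonconverged, 1L)
  expect_identical(s$n_corrected, 1L)
  expect_equal(s$bias, mean(c(-0.2, -0.3, -0.4)) + 0.3)
  s_strict <- summarize_fits(f, -0.3, include_corrected = FALSE)
  expect_identical(s_strict$n_effective, 2L)
  expect_equal(s_strict$bias, mean(c(-0.2, -0.4)) + 0.3)
})

test_that("power loss is the adjusted-minus-unadjusted power in points", {
  a <- fake_fits(rep(-0.5, 4), se = rep(0.1, 4))
  expect_equal(power_loss(summarize_fits(a, -0.5), summarize_fits(a, -0.5)), 0)
  u <- fake_fits(c(-0.5, -0.1, -0.1, -0.1), se = rep(0.1, 4))
  expect_equal(power_loss(summarize_fits(u, -0.5), summarize_fits(a, -0.5)), 75)
  expect_equal(power_loss(summarize_fits(u, -0.5), summarize_fits(a, -0.5),
                          relative = TRUE), 75)
  # relative scale divides by the adjusted power
  a2 <- fake_fits(c(-0.5, -0.5, -0.1, -0.1), se = rep(0.1, 4)) # power 0.5
  expect_equal(power_loss(summarize_fits(u, -0.5), summarize_fits(a2, -0.5),
                          relative = TRUE), 50)
})

test_that("deviation tables split over/under-estimation of the odds-ratio reduction", {
  true_or <- exp(-0.315)
  # all estimates exactly true: zero probability beyond any positive threshold
  f <- fake_fits(rep(-0.315, 8))
  dt <- deviation_table(f, true_or)
  expect_equal(dt$prob_overall[dt$d > 0], rep(0, sum(dt$d > 0)))
  expect_equal(dt$prob_overall[dt$d == 0], 1)
  expect_equal(dt$prob_over[dt$d == 0] + dt$prob_under[dt$d == 0], 1)

  # known deviations: orr_hat - true_orr = +0.12, -0.07, +0.02, -0.30
  dev <- c(0.12, -0.07, 0.02, -0.30)
  est <- log(exp(-0.315) - dev) # since dev = true_or - exp(beta1_hat)
  f2 <- fake_fits(est)
  dt2 <- deviation_table(f2, true_or, thresholds = c(0, 0.05, 0.1, 0.25))
  expect_equal(dt2$prob_over, c(mean(dev >= 0), 0.25, 0.25, 0))
  expect_equal(dt2$prob_under, c(mean(dev < 0), 0.5, 0.25, 0.25))
  expect_equal(dt2$prob_overall[-1], dt2$prob_over[-1] + dt2$prob_under[-1])
  expect_true(all(diff(dt2$prob_overall) <= 0))
})

test_that("an imposed 5-point imbalance of a strong factor inflates the apparent benefit", {
  # conditional design, strong factor (RR 5), rare-to-moderate prevalence,
  # 125/arm: the unadjusted log OR overestimates the benefit (negative bias
  # for a beneficial treatment), with magnitude around -0.19..-0.09
  spec <- build_scenario(1, "conditional", n_replicates = 2000, seed = 20120401)
  for (lam in c(0.05, 0.1, 0.2)) {
    fits <- run_cell(spec, lam, 125, models = "unadjusted")
    s <- summarize_fits(fits, spec$effects$b1)
    band <- 3 * s$empirical_sd / sqrt(s$n_effective) + 0.005
    expect_lt(s$bias, 0, label = paste("bias at lambda", lam))
    expect_gt(s$bias, -0.18 - band)
    expect_lt(s$bias, -0.09 + band)
  }
})

test_that("two-proportion sample size reproduces the design calculation", {
  # control risk 0.10, treatment RR 0.75, alpha 0.05, power 0.80
  expect_identical(required_sample_size(0.10, 0.75), 2002L)
  expect_error(required_sample_size(0.10, 1), "diverges")
  expect_error(required_sample_size(0.10, 11))
  # inverse-square law: halving the risk difference ~quadruples n
  n1 <- required_sample_size(0.10, 0.75)
  n2 <- required_sample_size(0.10, 0.875)
  expect_equal(n2 / n1, 4, tolerance = 0.1)
  # pooled-variance variant is close to (and no smaller than) the unpooled one here
  np <- required_sample_size(0.10, 0.75, variance = "pooled")
  expect_gt(np, 0.95 * n1)
  expect_lt(abs(np - n1) / n1, 0.05)
})
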