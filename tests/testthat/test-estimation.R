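test_that("Wald intervals are symmetric z-intervals on the log-OR scale", {
  expect_equal(wald_ci(0, 1), c(-1.959964, 1.959964), tolerance = 1e-6)
  expect_equal(wald_ci(-0.315, 0.1), c(-0.511, -0.119), tolerance = 1e-3)
  expect_equal(wald_ci(0.2, 0.5, level = 0.90),
               0.2 + c(-1, 1) * qnorm(0.95) * 0.5, tolerance = 1e-12)
  # CI excludes 0 exactly when |beta/se| exceeds the critical value
  z <- qnorm(0.975)
  ci_in <- wald_ci(0.99 * z * 0.3, 0.3)
  ci_out <- wald_ci(1.01 * z * 0.3, 0.3)
  expect_true(ci_in[1] < 0)
  expect_true(ci_out[1] > 0)
  expect_error(wald_ci(0, 0))
})

test_that("unadjusted fit equals the closed-form 2x2 log odds ratio", {
  # a=10 of n1=100 (treatment), b=20 of n0=100 (control)
  tc <- make_counts(c(100, 0, 100, 0), c(20, 0, 10, 0))
  fit <- fit_unadjusted(tc)
  expect_equal(fit$beta1_hat, -0.8109, tolerance = 1e-4)
  expect_equal(fit$se1, 0.4167, tolerance = 1e-4)
  expect_false(fit$corrected)
  expect_true(fit$converged)
  expect_equal(fit$orr_hat, 1 - exp(fit$beta1_hat))
  expect_lt(fit$ci_low, fit$beta1_hat)
  expect_gt(fit$ci_high, fit$beta1_hat)

  # equal arms give exactly zero
  tc0 <- make_counts(c(50, 50, 50, 50), c(5, 10, 5, 10))
  expect_identical(fit_unadjusted(tc0)$beta1_hat, 0)

  # zero-event arm triggers the 0.5 correction but stays finite
  tc_sep <- make_counts(c(100, 0, 100, 0), c(15, 0, 0, 0))
  fit_sep <- fit_unadjusted(tc_sep)
  expect_true(fit_sep$corrected)
  expect_true(is.finite(fit_sep$beta1_hat))
  expect_true(is.finite(fit_sep$se1))
  # matches the 0.5-augmented closed form
  expect_equal(fit_sep$beta1_hat,
               log((0.5 / 100.5) / (15.5 / 85.5)), tolerance = 1e-12)

  expect_error(fit_unadjusted(make_counts(c(10, 0, 0, 0), c(0, 0, 0, 0))), "arm")
})

test_that("adjusted fit reduces to the unadjusted one when the factor is constant", {
  tc <- make_counts(c(100, 0, 100, 0), c(20, 0, 10, 0))
  fit_a <- fit_adjusted(tc)
  fit_u <- fit_unadjusted(tc)
  expect_equal(fit_a$beta1_hat, fit_u$beta1_hat, tolerance = 1e-8)
  expect_equal(fit_a$se1, fit_u$se1, tolerance = 1e-6)
  expect_true(is.na(fit_a$coefficients[["b2"]]))
})

test_that("adjusted fit is consistent at idealized expected counts", {
  # cells at their expectations for scenario 1, lambda 0.5, huge n: the MLE
  # recovers the conditional effect while the collapsed fit recovers the
  # marginal (attenuated) effect
  n <- 1e6
  eff <- scenario1$effects
  sizes <- rep(n / 2, 4)
  p <- cell_probability(eff, t = c(0, 0, 1, 1), c = c(0, 1, 0, 1))
  tc <- make_counts(sizes, round(p * sizes))
  expect_equal(fit_adjusted(tc)$beta1_hat, -0.315, tolerance = 1e-3)
  expect_equal(fit_unadjusted(tc)$beta1_hat, -0.2598, tolerance = 1e-3)
  expect_equal(fit_unadjusted(tc)$beta1_hat, marginal_log_or(eff, 0.5),
               tolerance = 1e-4)
})

test_that("the IRLS solution maximizes the likelihood (grid oracle)", {
  set.seed(77)
  X <- cbind(1, c(0, 0, 1, 1), c(0, 1, 0, 1))
  offsets <- expand.grid(b0 = seq(-0.5, 0.5, length.out = 21),
                         b1 = seq(-0.5, 0.5, length.out = 21),
                         b2 = seq(-0.5, 0.5, length.out = 21))
  n_checked <- 0
  for (i in 1:50) {
    tc <- simulate_unconditional(scenario1, 0.4, 25)
    fit <- fit_adjusted(tc)
    if (!fit$converged || fit$corrected || anyNA(fit$coefficients)) next
    n_checked <- n_checked + 1
    df <- as.data.frame(tc)
    keep <- df$n_patients > 0
    at_mle <- loglik_cells(fit$coefficients, X[keep, , drop = FALSE],
                           df$n_events[keep], df$n_patients[keep])
    grid_betas <- t(as.matrix(offsets)) + fit$coefficients
    eta <- X[keep, , drop = FALSE] %*% grid_betas
    ll <- colSums(dbinom(df$n_events[keep], df$n_patients[keep], plogis(eta),
                         log = TRUE))
    expect_true(all(ll <= at_mle + 1e-8), info = paste("trial", i))
  }
  expect_gt(n_checked, 25)
})

test_that("aggregated-cell and patient-level fits are identical", {
  set.seed(88)
  for (i in 1:5) {
    tc <- simulate_unconditional(scenario1, 0.4, 25)
    fit_c <- fit_adjusted(tc)
    if (fit_c$corrected || !fit_c$converged) next
    pat <- expand_patients(tc)
    ctl <- glm.control(epsilon = 1e-12)
    ref <- glm(y ~ t + c, family = binomial(), data = pat, control = ctl)
    expect_equal(fit_c$beta1_hat, unname(coef(ref)["t"]), tolerance = 1e-7)
    expect_equal(fit_c$se1, unname(sqrt(diag(vcov(ref)))["t"]), tolerance = 1e-6)
    fit_u <- fit_unadjusted(tc)
    ref_u <- glm(y ~ t, family = binomial(), data = pat, control = ctl)
    expect_equal(fit_u$beta1_hat, unname(coef(ref_u)["t"]), tolerance = 1e-7)
    expect_equal(fit_u$se1, unname(sqrt(diag(vcov(ref_u)))["t"]), tolerance = 1e-6)
  }
})

test_that("adjusted and unadjusted estimates coincide on average when the factor is inert", {
  # no prognostic effect (pf_rr = 1): the odds ratio is collapsible, so the
  # two models estimate the same quantity
  spec <- build_scenario(2, "unconditional", seed = 11)
  spec$effects <- effect_spec(0.2, 0.75, 1)
  fits <- run_cell(spec, 0.5, 500, n_replicates = 400, base_seed = 11)
  m_adj <- mean(fits$beta1_hat[fits$model == "adjusted" & fits$converged])
  m_un <- mean(fits$beta1_hat[fits$model == "unadjusted" & fits$converged])
  expect_lt(abs(m_adj - m_un), 0.02)
})

test_that("separation in the adjusted model triggers the flagged fallback", {
  # no events anywhere: MLE pushed to the boundary
  tc <- make_counts(c(15, 10, 15, 10), c(0, 0, 0, 0))
  fit <- fit_adjusted(tc)
  expect_true(fit$corrected)
  expect_true(fit$converged)
  expect_true(is.finite(fit$beta1_hat))
  expect_true(fit$se1 > 0)
})
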