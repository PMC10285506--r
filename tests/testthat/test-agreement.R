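# MCMC-backed tests run at reduced draws (2 chains x 1000 after 500
# adaptation); the posterior means they assert are stable well beyond the
# tolerances used.

test_that("HDI is the narrowest window and matches known cases", {
  expect_equal(hdi(rep(3.2, 100)), c(3.2, 3.2))
  set.seed(111)
  u <- runif(1e5)
  expect_equal(diff(hdi(u)), 0.95, tolerance = 0.01)
  z <- rnorm(5e4)
  h <- hdi(z)
  q <- quantile(z, c(0.025, 0.975))
  expect_equal(h[1], unname(q[1]), tolerance = 0.05)
  expect_equal(h[2], unname(q[2]), tolerance = 0.05)
  # never wider than the equal-tailed interval, for arbitrary draw sets
  for (r in 1:20) {
    x <- rexp(500) * sample(c(-1, 1), 1) + rnorm(1)
    expect_lte(diff(hdi(x)), diff(unname(quantile(x, c(0.025, 0.975)))) + 1e-12)
  }
  expect_error(hdi(1), "at least 2")
  expect_error(hdi(1:10, mass = 1), "in \\(0, 1\\)")
})

test_that("ROPE fraction counts inclusively and complements exactly", {
  expect_equal(rope_fraction(c(-1, 0, 1), -1, 1), 1)
  expect_equal(rope_fraction(c(5, 7), -1, 1), 0)
  set.seed(121)
  z <- rnorm(1e5)
  expect_equal(rope_fraction(z, -1.96, 1.96), 0.95, tolerance = 0.01)
  inside <- rope_fraction(z, -0.5, 0.5)
  outside <- mean(z < -0.5 | z > 0.5)
  expect_identical(inside + outside, 1)
  expect_error(rope_fraction(z, 1, -1), "<=")
})

test_that("limits of agreement match hand calculation and are equivariant", {
  expect_equal(limits_of_agreement(c(0, 0, 0)), c(low = 0, high = 0))
  loa <- limits_of_agreement(c(-1, 1))
  expect_equal(unname(loa), c(-2.771859, 2.771859), tolerance = 1e-6)
  set.seed(131)
  d <- rnorm(20, 3, 4)
  base <- limits_of_agreement(d)
  expect_equal(limits_of_agreement(d + 7), base + 7)
  expect_equal(limits_of_agreement(d * 3), base * 3)
  expect_error(limits_of_agreement(1), "at least 2")
})

test_that("mean-bias posterior tracks the data and its ROPE behaves", {
  fit0 <- fit_mean_bias(rep(0, 10), fast_mcmc())
  expect_equal(fit0$mu$mean, 0, tolerance = 0.5)
  expect_gt(fit0$mu$rope_fraction, 0.99)
  set.seed(141)
  d10 <- rnorm(50, 10, 1)
  fit10 <- fit_mean_bias(d10, fast_mcmc())
  # conjugate-style oracle: weak priors leave the posterior mean at ybar
  expect_equal(fit10$mu$mean, mean(d10), tolerance = 0.2)
  expect_gt(fit10$mu$hdi_low, 0)
  expect_lt(fit10$mu$rope_fraction, 0.01)
  # paper-scale n with modest spread: most mass inside +/-5 mm
  d0 <- rnorm(13, 0, 3)
  fit13 <- fit_mean_bias(d0, fast_mcmc())
  expect_gt(fit13$mu$rope_fraction, 0.7)
  expect_error(fit_mean_bias(c(1, 2)), "at least 3")
})

test_that("bias regression recovers exact linear structure against an OLS oracle", {
  set.seed(151)
  true_score <- runif(20, -20, 40)
  d <- 2 + 0.5 * true_score
  # noise-free data pins sigma at its floor; the sampler flag is expected
  fit <- suppressWarnings(fit_bias_regression(true_score, d, fast_mcmc()))
  ols <- lm(d ~ true_score)
  expect_equal(fit$intercept$mean, unname(coef(ols)[1]), tolerance = 0.3)
  expect_equal(fit$slope$mean, unname(coef(ols)[2]), tolerance = 0.05)
  fitz <- fit_bias_regression(true_score, rep(0, 20), fast_mcmc())
  expect_gt(fitz$intercept$rope_fraction, 0.95)
  expect_gt(fitz$slope$rope_fraction, 0.95)
  expect_error(fit_bias_regression(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("retest regression sees perfect and shifted agreement correctly", {
  set.seed(161)
  t1 <- rnorm(15, 12, 16)
  fit_same <- suppressWarnings(fit_retest_regression(t1, t1, fast_mcmc()))
  expect_equal(fit_same$slope$mean, 1, tolerance = 0.05)
  expect_equal(fit_same$intercept$mean, 0, tolerance = 1)
  fit_shift <- fit_retest_regression(t1, 5 + t1 + rnorm(15, 0, 0.5), fast_mcmc())
  ols <- lm(I(5 + t1) ~ t1)
  expect_equal(fit_shift$slope$mean, 1, tolerance = 0.1)
  expect_equal(fit_shift$intercept$mean, 5, tolerance = 1.5)
})

test_that("direction contrast summarises coefficient differences with its ROPE", {
  x <- rnorm(4000)
  same <- list(draws = cbind(b_forward = x, b_backward = x))
  ct <- direction_contrast(same)
  expect_equal(ct$mean, 0)
  expect_equal(ct$rope_fraction, 1)
  off <- list(draws = cbind(b_forward = x, b_backward = x + 1))
  ct2 <- direction_contrast(off)
  expect_equal(ct2$mean, 1, tolerance = 1e-9)
  expect_equal(ct2$rope_fraction, 0)
})

test_that("direction-bias model requires both directions and several participants", {
  df <- data.frame(participant_id = "P01", direction = "forward",
                   stimulus_mm = 0, response = "left")
  expect_error(fit_direction_bias_model(df), "participants")
  df2 <- data.frame(participant_id = rep(c("P01", "P02"), 5),
                    direction = "forward", stimulus_mm = 0, response = "left")
  expect_error(fit_direction_bias_model(df2), "directions")
})

test_that("ICC(2,1) matches a variance-component oracle and known edge cases", {
  t1 <- c(2, 8, 5, 11, 7, 4)
  expect_equal(icc_2_1(t1, t1)$icc, 1)
  expect_true(icc_2_1(t1, t1)$degenerate)
  # independent measurements carry no subject signal
  set.seed(171)
  r0 <- icc_2_1(rnorm(300), rnorm(300))
  expect_lt(abs(r0$icc), 0.15)
  # simulated subject + rater + error variance with known ICC(A,1)
  n <- 2000
  subj <- rnorm(n, 0, 4)   # var 16
  rater2 <- 1.5            # fixed session shift, var contribution via MSC
  e1 <- rnorm(n, 0, 2); e2 <- rnorm(n, 0, 2)  # var 4
  r <- icc_2_1(subj + e1, subj + rater2 + e2)
  true_icc <- 16 / (16 + 1.5^2 / 2 + 4)  # rater variance term k=2 two-level
  expect_equal(r$icc, true_icc, tolerance = 0.05)
  expect_true(r$ci_low < r$icc && r$icc < r$ci_high)
  # cross-check against REML variance components (balanced case)
  if (requireNamespace("lme4", quietly = TRUE)) {
    t1s <- c(9, 6, 8, 7, 10, 6); t2s <- c(2, 1, 4, 1, 5, 2)
    long <- data.frame(y = c(t1s, t2s),
                       subj = factor(rep(1:6, 2)),
                       sess = factor(rep(1:2, each = 6)))
    m <- lme4::lmer(y ~ 1 + (1 | subj) + (1 | sess), data = long,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(m))
    v <- setNames(vc$vcov, vc$grp)
    icc_reml <- v[["subj"]] / (v[["subj"]] + v[["sess"]] + v[["Residual"]])
    expect_equal(icc_2_1(t1s, t2s)$icc, unname(icc_reml), tolerance = 0.05)
  }
  expect_error(icc_2_1(1:2, 2:3), "at least 3")
})

test_that("sampler configuration is honoured exactly", {
  y <- c(1.2, -0.5, 3.1, 0.4, -2.2, 1.8, 0.9, -1.1, 2.5, 0.3)
  cfg <- mcmc_config(draws = 250, chains = 3, tuning = 100, seed = 4)
  fit <- fit_mean_bias(y, cfg)
  expect_equal(fit$diagnostics$n_retained, 750)
  expect_equal(fit$diagnostics$chains, 3)
  expect_equal(fit$diagnostics$tuning_per_chain, 100)
  # same config and seed: bit-identical draws
  fit2 <- fit_mean_bias(y, cfg)
  expect_identical(fit$draws, fit2$draws)
  expect_error(mcmc_config(draws = 0), "positive")
})
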