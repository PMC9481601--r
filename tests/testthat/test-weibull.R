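test_that("the MLE recovers planted Weibull parameters at n = 1000", {
  set.seed(2023)
  fit <- weibull_tto(rweibull(1000, shape = 2, scale = 100))
  expect_lt(abs(coef(fit)[["alpha"]] - 100), 5)
  expect_lt(abs(coef(fit)[["beta"]] - 2), 0.15)
  expect_true(fit$alpha_ci[1] < coef(fit)[["alpha"]] &&
                coef(fit)[["alpha"]] < fit$alpha_ci[2])
  expect_equal(fit$failure_type, "wear_out")  # beta CI well above 1 here
})

test_that("exponential data yield shape near 1 and scale near the mean", {
  set.seed(7)
  x <- rexp(800, rate = 1 / 90)
  fit <- weibull_tto(x)
  # with shape fixed at 1 the scale MLE is the sample mean; the free fit
  # should sit close to that and its shape interval should cover 1
  expect_lt(abs(coef(fit)[["alpha"]] - mean(x)) / mean(x), 0.05)
  expect_true(fit$beta_ci[1] <= 1 && 1 <= fit$beta_ci[2])
  expect_equal(fit$failure_type, "random")
})

test_that("degenerate and tiny samples are handled without error", {
  expect_error(weibull_tto(numeric(0)), "no onset samples")
  expect_warning(f1 <- weibull_tto(35.5), "degenerate")
  expect_equal(f1$median, 35.5)
  expect_equal(f1$failure_type, "indeterminate")
  expect_true(all(is.na(coef(f1))))

  expect_warning(f2 <- weibull_tto(c(35.5, 35.5)), "degenerate")
  expect_equal(f2$failure_type, "indeterminate")

  # two distinct samples still fit, with very wide intervals
  f3 <- weibull_tto(c(2.5, 475.5))
  expect_true(all(is.finite(coef(f3))))
  expect_gt(f3$beta_ci[2] / f3$beta_ci[1], 10)
})

test_that("failure-type classification follows the CI-versus-1 rule", {
  expect_equal(classify_failure(0.43, 0.95), "early")
  expect_equal(classify_failure(1.25, 3.28), "wear_out")
  expect_equal(classify_failure(0.93, 1.19), "random")
  expect_equal(classify_failure(NA, NA), "indeterminate")
  # scaling the time unit leaves beta (dimensionless) untouched
  set.seed(31)
  x <- rweibull(300, shape = 1.4, scale = 120)
  f_days <- weibull_tto(x)
  f_weeks <- weibull_tto(x / 7)
  expect_equal(coef(f_weeks)[["beta"]], coef(f_days)[["beta"]],
               tolerance = 1e-3)
  expect_equal(f_weeks$failure_type, f_days$failure_type)
})

test_that("point estimates agree with an independent survreg fit", {
  set.seed(123)
  x <- rweibull(400, shape = 1.3, scale = 140)
  fit <- weibull_tto(x)
  sr <- survival::survreg(survival::Surv(x) ~ 1, dist = "weibull")
  expect_equal(coef(fit)[["alpha"]], unname(exp(sr$coefficients)),
               tolerance = 1e-3)
  expect_equal(coef(fit)[["beta"]], 1 / sr$scale, tolerance = 1e-3)
})

test_that("profile and Wald intervals agree at moderate n", {
  set.seed(55)
  fit <- weibull_tto(rweibull(500, shape = 1.2, scale = 100))
  wald <- confint(fit, type = "wald")
  prof <- confint(fit, type = "profile")
  expect_equal(prof, wald, tolerance = 0.05)
})

test_that("quantile summaries are distribution-free with linear interpolation", {
  x <- c(10, 20, 30, 40)
  fit <- weibull_tto(x)
  expect_equal(fit$median, 25)
  expect_equal(fit$q1, 17.5)
  expect_equal(fit$q3, 32.5)
})

test_that("Wald shape interval attains near-nominal coverage at n = 150", {
  n_rep <- 200
  true_beta <- 1.06
  true_alpha <- 124
  covered <- 0L
  rel_bias_a <- rel_bias_b <- numeric(n_rep)
  set.seed(909)
  for (i in seq_len(n_rep)) {
    fit <- suppressWarnings(
      weibull_tto(rweibull(150, shape = true_beta, scale = true_alpha)))
    covered <- covered +
      (fit$beta_ci[1] <= true_beta && true_beta <= fit$beta_ci[2])
    rel_bias_a[i] <- (coef(fit)[["alpha"]] - true_alpha) / true_alpha
    rel_bias_b[i] <- (coef(fit)[["beta"]] - true_beta) / true_beta
  }
  expect_lt(abs(stats::median(rel_bias_a)), 0.05)
  expect_lt(abs(stats::median(rel_bias_b)), 0.05)
  expect_gte(covered / n_rep, 0.91)
  expect_lte(covered / n_rep, 0.99)
})

test_that("simulate draws from the fitted distribution deterministically", {
  set.seed(8)
  fit <- weibull_tto(rweibull(200, 1.5, 80))
  s1 <- simulate(fit, nsim = 2, seed = 99)
  s2 <- simulate(fit, nsim = 2, seed = 99)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(200L, 2L))
  expect_true(all(unlist(s1) > 0))
})
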