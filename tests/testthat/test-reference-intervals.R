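test_that("empirical quantile interpolates at rank 1 + (n-1)q", {
  expect_equal(empirical_quantile(1:101, 0.025), 3.5)
  expect_equal(empirical_quantile(c(9, 2, 5), 0), 2)
  expect_equal(empirical_quantile(c(9, 2, 5), 1), 9)
  expect_equal(empirical_quantile(rep(7, 30), c(0, 0.3, 1)), c(7, 7, 7))
  expect_error(empirical_quantile(numeric(0), 0.5), "empty")
  # agrees with the standard interpolating quantile on random samples
  set.seed(4)
  for (rep in 1:20) {
    x <- rnorm(sample(5:200, 1))
    q <- runif(5)
    expect_equal(empirical_quantile(x, q),
                 unname(quantile(x, q, type = 7)))
  }
})

test_that("bootstrap reference interval recovers known quantiles", {
  # constant sample: degenerate interval with zero-width CIs
  ri <- bootstrap_reference_interval(rep(5, 50), n_bootstrap = 100, seed = 1)
  expect_equal(ri$lower_ri, 5)
  expect_equal(ri$upper_ri, 5)
  expect_equal(ri$lower_ci, c(5, 5))
  expect_equal(ri$upper_ci, c(5, 5))

  set.seed(99)
  x <- rnorm(5000, 380, 63)
  ri <- bootstrap_reference_interval(x, n_bootstrap = 200, seed = 2)
  expect_lt(abs(ri$lower_ri - 256.5), 4)
  expect_lt(abs(ri$upper_ri - 503.5), 4)
  expect_true(ri$lower_ci[1] <= ri$lower_ri && ri$lower_ri <= ri$lower_ci[2])
  expect_true(ri$upper_ci[1] <= ri$upper_ri && ri$upper_ri <= ri$upper_ci[2])

  set.seed(100)
  u <- runif(10001)
  ri <- bootstrap_reference_interval(u, n_bootstrap = 100, seed = 3)
  expect_lt(abs(ri$lower_ri - 0.025), 0.01)
  expect_lt(abs(ri$upper_ri - 0.975), 0.01)
})

test_that("bootstrap reference interval is seeded and monotone", {
  set.seed(12)
  x <- rnorm(80, 380, 63)
  a <- bootstrap_reference_interval(x, n_bootstrap = 300, seed = 7)
  b <- bootstrap_reference_interval(x, n_bootstrap = 300, seed = 7)
  expect_identical(a, b)
  # widening the coverage widens the interval
  wide <- bootstrap_reference_interval(x, coverage = 0.99,
                                       n_bootstrap = 50, seed = 7)
  expect_lte(wide$lower_ri, a$lower_ri)
  expect_gte(wide$upper_ri, a$upper_ri)
  # adding a value above the upper endpoint cannot decrease it
  more <- bootstrap_reference_interval(c(x, max(x) + 100),
                                       n_bootstrap = 50, seed = 7)
  expect_gte(more$upper_ri, a$upper_ri)
  # missing values are removed and counted
  mi <- bootstrap_reference_interval(c(x, NA, NA), n_bootstrap = 50, seed = 7)
  expect_equal(mi$n_missing, 2)
  expect_equal(mi$n, 80)
  expect_error(bootstrap_reference_interval(rnorm(10)), "n >= 20")
  expect_warning(bootstrap_reference_interval(rnorm(25), n_bootstrap = 20,
                                              seed = 1), "imprecise")
})

test_that("reference-interval table covers all 30 grid parameters", {
  sim <- generate_cohort(generator_config(seed = 6))
  ri <- reference_interval_table(sim$cohort, n_bootstrap = 50, seed = 6)
  expect_equal(nrow(ri), 30)
  expect_setequal(ri$parameter, index_parameters())
  done <- !is.na(ri$lower_ri)
  expect_true(all(ri$lower_ri[done] <= ri$upper_ri[done]))
  trv <- ri[ri$parameter == "mean_trv", ]
  expect_gt(trv$lower_ri, 0.1)
  expect_lt(trv$upper_ri, 0.6)
})

test_that("quantile regression interpolates exact planes and recovers slopes", {
  d <- data.frame(age = seq(2, 12, length.out = 40))
  d$y <- 10 + 2 * d$age
  fit <- quantile_regression_fit(d, "y", "age", n_bootstrap = 0)
  expect_equal(fit$coefficients$estimate,
               c(10, 2), tolerance = 1e-6)

  set.seed(21)
  n <- 2000
  d2 <- data.frame(age = runif(n, 4, 11),
                   sex = sample(c("M", "F"), n, replace = TRUE),
                   re = runif(n, -2.5, 4))
  d2$y <- 380 - 0.9 * d2$age + rnorm(n, 0, 10)
  fit2 <- quantile_regression_fit(d2, "y", c("age", "sex", "re"),
                                  n_bootstrap = 0)
  cf <- fit2$coefficients
  expect_lt(abs(cf$estimate[cf$term == "age"] - (-0.9)), 0.3)
  expect_lt(abs(cf$estimate[cf$term == "sex_M"]), 0.3 * 10)
  expect_lt(abs(cf$estimate[cf$term == "re"]), 0.3)

  # symmetric noise: median regression close to least squares
  ols <- coef(lm(y ~ age + sex + re, data = d2))
  expect_equal(cf$estimate[cf$term == "age"], unname(ols["age"]),
               tolerance = 0.25)

  # bootstrap inference is seeded and brackets the estimate
  fit3 <- quantile_regression_fit(d2, "y", "age", n_bootstrap = 60, seed = 9)
  fit3b <- quantile_regression_fit(d2, "y", "age", n_bootstrap = 60, seed = 9)
  expect_identical(fit3, fit3b)
  cf3 <- fit3$coefficients
  expect_true(all(cf3$ci_low <= cf3$estimate & cf3$estimate <= cf3$ci_high))

  d2$age_copy <- d2$age * 2
  expect_error(quantile_regression_fit(d2, "y", c("age", "age_copy"),
                                       n_bootstrap = 0), "collinear")
})

test_that("normality assessment behaves across sample shapes", {
  # type-I error: Gaussian samples rarely rejected
  rejections <- vapply(1:200, function(s) {
    set.seed(s)
    assess_normality(rnorm(64))$p_value < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.10)
  # a gross outlier is detected
  expect_lt(assess_normality(c(rep(1, 49), 1000))$p_value, 0.01)
  # degenerate input is reported as not applicable
  res <- assess_normality(rep(3, 30))
  expect_false(res$applicable)
  expect_true(is.na(res$W))
  expect_error(assess_normality(rnorm(2)), "3 <= n")
})
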