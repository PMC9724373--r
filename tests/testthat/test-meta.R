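test_that("log-effect conversion matches the Wald formula and round-trips the CI", {
  z <- qnorm(0.975)
  s <- data.frame(factor_id = "f", estimate = 2, ci_low = 1, ci_high = 4)
  eff <- log_effects(s)
  expect_equal(eff$y, log(2))
  expect_equal(eff$se, log(4) / (2 * z))

  # log-symmetric CI around a null estimate (inclusion filter off)
  s0 <- data.frame(factor_id = "f", estimate = 1, ci_low = 0.5, ci_high = 2)
  eff0 <- log_effects(s0, require_gt1 = FALSE)
  expect_equal(eff0$y, 0)
  expect_equal(eff0$se, log(4) / (2 * z))

  # round-trip: exp(y +/- z*se) recovers the CI ends for arbitrary valid rows
  set.seed(11)
  for (i in 1:20) {
    y <- runif(1, 0.1, 2.5)
    se <- runif(1, 0.05, 0.6)
    row <- data.frame(factor_id = "f", estimate = exp(y),
                      ci_low = exp(y - z * se), ci_high = exp(y + z * se))
    e <- log_effects(row)
    expect_equal(exp(e$y - z * e$se), row$ci_low, tolerance = 1e-12)
    expect_equal(exp(e$y + z * e$se), row$ci_high, tolerance = 1e-12)
  }
})

test_that("study screening rejects invalid rows with reason codes and flags asymmetry", {
  s <- data.frame(
    factor_id = "f",
    study_label = c("neg", "zero_width", "null_or", "ok", "skewed"),
    estimate = c(-2, 2, 0.8, 2, 2),
    ci_low = c(1, 2, 0.6, 1.5, 1.8),
    ci_high = c(4, 2, 1.0, 2.7, 9)
  )
  expect_message(eff <- log_effects(s), "flagged")
  rej <- attr(eff, "rejected")
  expect_equal(sort(rej$reason), sort(c("nonpositive", "zero_se", "estimate_le_1")))
  expect_equal(nrow(eff), 2)
  expect_equal(eff$asymmetric, c(FALSE, TRUE))
})

test_that("fixed-effect pooling is the inverse-variance weighted mean", {
  expect_equal(fixed_effect_pool(0.5, 0.2), list(y_bar = 0.5, se_bar = 0.2))
  two <- fixed_effect_pool(c(0.693, 0.693), c(0.3537, 0.3537))
  expect_equal(two$y_bar, 0.693)
  expect_equal(two$se_bar, 0.3537 / sqrt(2))
  # equal weights reduce to the arithmetic mean
  expect_equal(fixed_effect_pool(c(0, 0.693), c(0.3537, 0.3537))$y_bar, 0.3465)
  expect_error(fixed_effect_pool(numeric(0), numeric(0)), "no effects")
  expect_error(fixed_effect_pool(c(0, 1), c(0.2, 0)), "positive")
})

test_that("heterogeneity statistics match the hand-computed two-study oracle", {
  y <- c(0, log(2)); se <- c(0.3537, 0.3537)
  q <- cochran_q(y, se)
  expect_equal(q$Q, 1.920, tolerance = 5e-4)
  expect_equal(q$df, 1L)
  expect_equal(i_squared(q$Q, q$df), 47.9, tolerance = 1e-3)
  expect_equal(dl_tau2(y, se), 0.1151, tolerance = 5e-4)

  # no dispersion
  q0 <- cochran_q(rep(0.4, 3), rep(0.2, 3))
  expect_equal(q0$Q, 0)
  expect_equal(q0$p, 1)
  expect_equal(dl_tau2(rep(0.4, 3), rep(0.2, 3)), 0)

  # permutation invariance
  set.seed(21)
  y <- rnorm(8); se <- runif(8, 0.1, 0.5)
  p <- sample(8)
  expect_equal(cochran_q(y, se)$Q, cochran_q(y[p], se[p])$Q)
})

test_that("I-squared truncates at zero and is bounded", {
  expect_equal(i_squared(1, 1), 0)
  expect_equal(i_squared(2, 1), 50)
  expect_equal(i_squared(0, 3), 0)
  expect_error(i_squared(2, 0), "df")
  set.seed(5)
  for (i in 1:25) {
    v <- i_squared(runif(1, 0, 50), sample(1:10, 1))
    expect_gte(v, 0); expect_lte(v, 100)
  }
})

test_that("DL tau2 is nonnegative and scales quadratically with se", {
  set.seed(31)
  for (i in 1:20) {
    k <- sample(3:12, 1)
    y <- rnorm(k, 0.5, 0.4); se <- runif(k, 0.1, 0.5)
    t2 <- dl_tau2(y, se)
    expect_gte(t2, 0)
    if (t2 > 0) {
      expect_equal(dl_tau2(2 * y, 2 * se), 4 * t2, tolerance = 1e-10)
    }
  }
})

test_that("random-effects pooling: identity at k=1, FE limit, permutation invariance", {
  one <- random_effects_pool(log(3.2), 0.25)
  expect_equal(one$pooled_estimate, 3.2)
  expect_equal(one$pooled_se_log, 0.25)
  expect_equal(one$tau2, 0)

  set.seed(41)
  y <- rnorm(6, 0.6, 0.1); se <- runif(6, 0.1, 0.3)  # low dispersion: tau2 may be 0
  fe <- random_effects_pool(y, se, method = "FE")
  expect_equal(fe$pooled_log, fixed_effect_pool(y, se)$y_bar)
  expect_equal(fe$pooled_se_log, fixed_effect_pool(y, se)$se_bar)

  p <- sample(6)
  re1 <- random_effects_pool(y, se)
  re2 <- random_effects_pool(y[p], se[p])
  expect_equal(re1$pooled_log, re2$pooled_log)
  expect_equal(re1$tau2, re2$tau2)

  # equal se and zero tau2: pooled log effect is the arithmetic mean
  y_eq <- c(0.2, 0.4, 0.6)
  fe_eq <- random_effects_pool(y_eq, rep(0.3, 3), method = "FE")
  expect_equal(fe_eq$pooled_log, mean(y_eq))
})

test_that("random-effects pooling agrees with metafor's DL implementation", {
  skip_if_not_installed("metafor")
  set.seed(51)
  y <- rnorm(12, 0.7, 0.3); se <- runif(12, 0.1, 0.5)
  ours <- random_effects_pool(y, se)
  ref <- metafor::rma(yi = y, sei = se, method = "DL")
  expect_equal(ours$pooled_log, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(ours$pooled_se_log, ref$se, tolerance = 1e-10)
  expect_equal(ours$tau2, ref$tau2, tolerance = 1e-10)
  expect_equal(ours$Q, ref$QE, tolerance = 1e-10)
  expect_equal(ours$I2, ref$I2, tolerance = 1e-6)
})

test_that("Egger regression matches a closed-form OLS oracle and handles degeneracy", {
  set.seed(61)
  y <- rnorm(10, 0.5, 0.4); se <- runif(10, 0.1, 0.5)
  eg <- egger_test(y, se)
  expect_equal(eg$intercept, oracle_ols_intercept(1 / se, y / se),
               tolerance = 1e-10)

  # effects symmetric about a common mean with matched se: intercept ~ 0
  mu <- 0.8; d <- c(0.1, 0.25, 0.4); se_s <- c(0.15, 0.25, 0.35)
  eg_sym <- egger_test(c(mu + d, mu - d), rep(se_s, 2))
  expect_lt(abs(eg_sym$intercept), 1e-10)

  # constant precision: not evaluable
  expect_true(is.na(egger_test(c(0.1, 0.2, 0.3), rep(0.2, 3))$intercept))
  # too few studies
  expect_true(is.na(egger_test(c(0.1, 0.2), c(0.2, 0.3))$intercept))
})

test_that("Begg rank correlation equals brute-force pair counting", {
  set.seed(71)
  for (i in 1:10) {
    k <- sample(4:12, 1)
    y <- rnorm(k, 0.5, 0.4); se <- runif(k, 0.1, 0.5)
    bg <- begg_test(y, se)
    fe <- fixed_effect_pool(y, se)
    dev <- (y - fe$y_bar) / sqrt(se^2 - fe$se_bar^2)
    expect_equal(bg$tau, oracle_kendall(dev, se^2), tolerance = 1e-10)
    expect_lte(abs(bg$tau), 1)
  }
  expect_true(is.na(begg_test(0.5, 0.2)$tau))
})

test_that("funnel points are sorted by se and survive CSV round-trip", {
  set.seed(81)
  y <- rnorm(7); se <- runif(7, 0.1, 0.5)
  fp <- funnel_points(y, se)
  expect_equal(nrow(fp), 7)
  expect_false(is.unsorted(fp$se))
  expect_equal(nrow(funnel_points(0.2, 0.1)), 1)

  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(fp, path, row.names = FALSE)
  expect_equal(read.csv(path), fp, tolerance = 1e-12)
})

test_that("pool_studies pools per factor, keeps input order, and logs exclusions", {
  set.seed(91)
  studies <- gen_studies(seed = 91)
  pooled <- pool_studies(studies)
  expect_s3_class(pooled, "pooled_effects")
  expect_equal(pooled$factor_id, unique(studies$factor_id))
  expect_true(all(pooled$pooled_estimate > 0))
  expect_true(all(pooled$ci_low <= pooled$pooled_estimate &
                    pooled$pooled_estimate <= pooled$ci_high))
  rej <- attr(pooled, "rejected")
  expect_true(all(rej$reason == "estimate_le_1"))
  expect_true(all(rej$estimate <= 1))
  expect_equal(pooled$k[pooled$factor_id == "radon"] + sum(rej$factor_id == "radon"),
               sum(studies$factor_id == "radon"))
})
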