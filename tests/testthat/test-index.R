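test_that("published coefficient fixtures are intact and sum to 1.000", {
  lcri <- published_coefficients("LCRI")
  expect_length(lcri$weights, 7)
  expect_equal(sum(lcri$weights), 1, tolerance = 1e-3)
  expect_equal(unname(lcri$weights[1]), 0.461)

  il <- published_coefficients("LCRI_IL")
  expect_length(il$weights, 4)
  expect_equal(sum(il$weights), 1, tolerance = 1e-3)
  expect_equal(unname(il$weights[1]), 0.701)

  expect_error(published_coefficients("LCRI_TX"), "available")
})

test_that("binary evaluation spans [0, 1] and is monotone in exposures", {
  lcri <- published_coefficients("LCRI")
  empty <- setNames(rep(0, 7), lcri$factor_ids)
  full <- setNames(rep(1, 7), lcri$factor_ids)
  smoking <- empty; smoking["active_smoking"] <- 1

  expect_equal(evaluate_binary(empty, lcri), 0)
  expect_equal(evaluate_binary(full, lcri), 1, tolerance = 2e-3)
  expect_equal(evaluate_binary(smoking, lcri), 0.461)

  # adding one exposure never decreases the index (random coefficient sets)
  set.seed(131)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    w <- runif(n); w <- w / sum(w)
    coefs <- index_coefficients(w, paste0("f", seq_len(n)))
    prof <- setNames(rbinom(n, 1, 0.5), coefs$factor_ids)
    base <- evaluate_binary(prof, coefs)
    off <- which(prof == 0)
    if (length(off) > 0) {
      prof2 <- prof; prof2[sample(off, 1)] <- 1
      expect_gt(evaluate_binary(prof2, coefs), base)
    }
    expect_gte(base, 0); expect_lte(base, 1)
  }

  expect_error(evaluate_binary(empty[-1], lcri), "active_smoking")
  expect_error(evaluate_binary(full * 0.5, lcri), "0 or 1")
})

test_that("z-scoring standardizes columns and propagates missing values", {
  tab <- data.frame(a = c(1, 2, 3), b = c(5, 5, 5), c = c(1, NA, 3))
  z <- zscore_columns(tab, "a")
  expect_equal(z$a_z, c(-1, 0, 1))
  expect_error(zscore_columns(tab, "b"), "zero variance.*'b'|'b'.*zero variance")
  expect_error(zscore_columns(tab, "missing_col"), "missing_col")

  z2 <- zscore_columns(tab, "c")
  expect_true(is.na(z2$c_z[2]))
  expect_equal(mean(z2$c_z, na.rm = TRUE), 0)

  set.seed(141)
  for (i in 1:10) {
    d <- data.frame(x = rnorm(sample(5:50, 1), runif(1, -10, 10), runif(1, 0.5, 5)))
    zz <- zscore_columns(d, "x")$x_z
    expect_equal(mean(zz), 0, tolerance = 1e-12)
    expect_equal(sd(zz), 1, tolerance = 1e-12)
  }
})

test_that("composite scores are the weighted z sums and behave linearly", {
  one <- index_coefficients(c(x = 1), sum_tol = 1e-12)
  tab <- data.frame(x = c(1, 4, 7, 10))
  tab <- zscore_columns(tab, "x")
  tab <- composite_score(tab, one)
  expect_equal(tab$composite, tab$x_z)

  # perfectly anticorrelated equal-weight columns cancel
  tab2 <- data.frame(a = c(1, 2, 3, 4))
  tab2$b <- 10 - tab2$a
  tab2 <- zscore_columns(tab2, c("a", "b"))
  half <- index_coefficients(c(a = 0.5, b = 0.5))
  tab2 <- composite_score(tab2, half)
  expect_equal(tab2$composite, rep(0, 4), tolerance = 1e-12)

  # independently computed weighted sum + superposition in weights
  set.seed(151)
  d <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  d <- zscore_columns(d, c("a", "b", "c"))
  w <- c(a = 0.5, b = 0.3, c = 0.2)
  got <- composite_score(d, index_coefficients(w))$composite
  want <- 0.5 * d$a_z + 0.3 * d$b_z + 0.2 * d$c_z
  expect_equal(got, want, tolerance = 1e-12)

  wa <- composite_score(d, index_coefficients(c(a = 0.98, b = 0.01, c = 0.01)))$composite
  wb <- composite_score(d, index_coefficients(c(a = 0.01, b = 0.98, c = 0.01)))$composite
  # linearity: any convex combination of coefficient sets combines composites
  mix <- composite_score(d, index_coefficients((c(a = 0.98, b = 0.01, c = 0.01) +
                                                  c(a = 0.01, b = 0.98, c = 0.01)) / 2))$composite
  expect_equal(mix, (wa + wb) / 2, tolerance = 1e-12)
})

test_that("composite goes missing when a factor z is missing", {
  d <- data.frame(a = c(1, 2, NA, 4), b = c(4, 3, 2, 1))
  d <- zscore_columns(d, c("a", "b"))
  expect_message(
    d <- composite_score(d, index_coefficients(c(a = 0.6, b = 0.4))),
    "missing"
  )
  expect_true(is.na(d$composite[3]))
  expect_equal(sum(is.na(d$composite)), 1)
})

test_that("percentiles use the average-rank/n convention and are monotone", {
  expect_equal(to_percentile(c(0.1, 0.5, 0.7, 2)), c(25, 50, 75, 100))
  expect_equal(to_percentile(rep(3, 5)), rep(60, 5))  # mean rank 3 of 5
  expect_error(to_percentile(c(NA, NA)), "missing")

  set.seed(161)
  x <- rnorm(50)
  p1 <- to_percentile(x)
  p2 <- to_percentile(exp(2 * x) + 5)  # order-preserving transform
  expect_equal(p1, p2)
  expect_true(all(diff(p1[order(x)]) >= 0))
  expect_equal(max(p1), 100)
})

test_that("build_region_index assembles z-scores, composite, and percentiles", {
  set.seed(171)
  gr <- gen_regions(n_regions = 30, seed = 171)
  coefs <- published_coefficients("LCRI_IL")
  tab <- build_region_index(gr$regions, coefs)
  expect_s3_class(tab, "region_index")
  expect_true(all(c("active_smoking_z", "radon_z", "composite",
                    "composite_z", "percentile") %in% names(tab)))
  expect_equal(mean(tab$composite_z), 0, tolerance = 1e-12)
  expect_equal(sort(tab$percentile)[30], 100)

  # column mapping: same data under raw column names
  raw <- gr$regions
  names(raw)[names(raw) == "active_smoking"] <- "smoking_pct"
  mapped <- build_region_index(raw, coefs,
                               factor_cols = c(active_smoking = "smoking_pct"))
  expect_equal(mapped$composite, tab$composite)
  expect_error(build_region_index(raw, coefs), "active_smoking")
})

test_that("binary index mode computes weighted indicator sums per region", {
  coefs <- published_coefficients("LCRI_IL")
  regions <- data.frame(
    region_id = c("r1", "r2", "r3"),
    active_smoking = c(1, 0, 1), alcohol = c(0, 0, 1),
    outdoor_air_pollution = c(0, 0, 1), radon = c(0, 0, 1)
  )
  tab <- build_region_index(regions, coefs, mode = "binary")
  expect_equal(tab$composite, c(0.701, 0, 1))
  expect_equal(tab$percentile, c(200 / 3, 100 / 3, 100))
})
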