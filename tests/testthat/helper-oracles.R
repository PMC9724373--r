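# Independent oracles used to cross-check the implementation.

# Kendall tau by O(k^2) pair counting (tau-a; equals tau-b without ties).
oracle_kendall <- function(a, b) {
  k <- length(a)
  conc <- disc <- 0L
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s <- sign(a[i] - a[j]) * sign(b[i] - b[j])
      if (s > 0) conc <- conc + 1L
      if (s < 0) disc <- disc + 1L
    }
  }
  (conc - disc) / choose(k, 2)
}

# Closed-form simple-regression intercept (independent of lm()).
oracle_ols_intercept <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  mean(y) - slope * mean(x)
}

# Closed-form Pearson r and its two-sided t-test p-value.
oracle_pearson <- function(x, y) {
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  n <- length(x)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# Random positive reciprocal matrix with Saaty-scale upper triangle.
rand_reciprocal <- function(n) {
  a <- diag(n)
  vals <- c(1 / 9:2, 1:9)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a[i, j] <- sample(vals, 1)
      a[j, i] <- 1 / a[i, j]
    }
  }
  a
}

# Dense eigensolver route to the principal eigenvector (oracle for the
# power iteration).
oracle_eigen <- function(a) {
  e <- eigen(a)
  i <- which.max(Re(e$values))
  w <- Re(e$vectors[, i])
  w <- w * sign(sum(w))
  list(lambda_max = Re(e$values[i]), weights = w / sum(w))
}

# Table-1-scale pooled effect sizes used across tests.
table1_effects <- function() {
  c(active_smoking = 8.63, indoor_air_pollution = 1.76,
    occupational_exposure = 1.60, alcohol = 1.45, secondhand_smoke = 1.43,
    outdoor_air_pollution = 1.25, radon = 1.24)
}
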