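#' Fixed-effect inverse-variance pooling
#'
#' Weighted average of log effects with weights `w_i = 1/se_i^2`.
#'
#' @param y Numeric vector of log effects.
#' @param se Numeric vector of standard errors (all positive).
#' @return List with `y_bar` (pooled log effect) and `se_bar`
#'   (= `1/sqrt(sum(w))`).
#' @export
fixed_effect_pool <- function(y, se) {
  check_effects(y, se)
  w <- 1 / se^2
  list(y_bar = sum(w * y) / sum(w), se_bar = 1 / sqrt(sum(w)))
}

check_effects <- function(y, se) {
  if (length(y) == 0L) stop("no effects to pool", call. = FALSE)
  if (length(y) != length(se)) stop("y and se lengths differ", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(se))) {
    stop("non-finite log effect or standard error", call. = FALSE)
  }
  if (any(se <= 0)) stop("all standard errors must be positive", call. = FALSE)
  invisible(TRUE)
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_i * (y_i - y_bar)^2)` with fixed-effect weights; p-value from a
#' chi-square distribution with `k - 1` degrees of freedom.
#'
#' @inheritParams fixed_effect_pool
#' @return List with `Q`, `df` and `p` (`p` is `NA` when `k < 2`).
#' @export
cochran_q <- function(y, se) {
  check_effects(y, se)
  k <- length(y)
  if (k < 2L) {
    warning("k < 2: heterogeneity not testable", call. = FALSE)
    return(list(Q = 0, df = 0L, p = NA_real_))
  }
  w <- 1 / se^2
  y_bar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - y_bar)^2)
  df <- k - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Higgins' I-squared inconsistency statistic
#'
#' `I2 = max(0, (Q - df)/Q) * 100`; defined as 0 when `Q = 0`.
#'
#' @param Q Cochran's Q statistic (nonnegative).
#' @param df Degrees of freedom (`k - 1`, at least 1).
#' @return Percentage in \eqn{[0, 100]}.
#' @export
i_squared <- function(Q, df) {
  if (df < 1L) stop("df must be >= 1", call. = FALSE)
  if (Q < 0) stop("Q must be nonnegative", call. = FALSE)
  if (Q == 0) return(0)
  max(0, (Q - df) / Q) * 100
}

#' DerSimonian-Laird between-study variance
#'
#' Moment estimator
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` with fixed-effect
#' weights `w = 1/se^2`.
#'
#' @inheritParams fixed_effect_pool
#' @return Nonnegative scalar estimate of the between-study variance.
#' @export
dl_tau2 <- function(y, se) {
  check_effects(y, se)
  k <- length(y)
  if (k < 2L) {
    warning("k < 2: tau2 not estimable, returning 0", call. = FALSE)
    return(0)
  }
  w <- 1 / se^2
  q <- cochran_q(y, se)
  max(0, (q$Q - q$df) / (sum(w) - sum(w^2) / sum(w)))
}

#' Random-effects pooling of one factor's log effects
#'
#' Inverse-variance pooling with random-effects weights
#' `w*_i = 1/(se_i^2 + tau2)`, DerSimonian-Laird `tau2`, a Wald confidence
#' interval on the log scale back-transformed to the ratio scale, and
#' heterogeneity plus publication-bias diagnostics.
#'
#' @inheritParams fixed_effect_pool
#' @param conf_level Confidence level for the pooled interval (default 0.95).
#' @param method `"DL"` (DerSimonian-Laird random effects, default) or
#'   `"FE"` (fixed effect, i.e. `tau2` forced to 0).
#' @return An object of class `"meta_pool"`: a list with elements `k`,
#'   `pooled_log`, `pooled_se_log`, `pooled_estimate`, `ci_low`, `ci_high`
#'   (ratio scale), `Q`, `df`, `Q_p`, `I2`, `tau2`, `egger_intercept`,
#'   `egger_p`, `begg_tau`, `begg_p`, `method`, `conf_level`.
#' @export
#' @examples
#' y <- c(0, log(2)); se <- c(0.3537, 0.3537)
#' random_effects_pool(y, se)
random_effects_pool <- function(y, se, conf_level = 0.95, method = c("DL", "FE")) {
  method <- match.arg(method)
  check_effects(y, se)
  k <- length(y)
  z_crit <- stats::qnorm(1 - (1 - conf_level) / 2)

  if (k >= 2L) {
    q <- cochran_q(y, se)
    I2 <- i_squared(q$Q, q$df)
    tau2 <- if (method == "DL") dl_tau2(y, se) else 0
  } else {
    q <- list(Q = 0, df = 0L, p = NA_real_)
    I2 <- 0
    tau2 <- 0
  }

  w <- 1 / (se^2 + tau2)
  pooled_log <- sum(w * y) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))

  eg <- egger_test(y, se)
  bg <- begg_test(y, se)

  structure(list(
    k = k,
    pooled_log = pooled_log,
    pooled_se_log = pooled_se,
    pooled_estimate = exp(pooled_log),
    ci_low = exp(pooled_log - z_crit * pooled_se),
    ci_high = exp(pooled_log + z_crit * pooled_se),
    Q = q$Q, df = q$df, Q_p = q$p, I2 = I2, tau2 = tau2,
    egger_intercept = eg$intercept, egger_p = eg$p,
    begg_tau = bg$tau, begg_p = bg$p,
    method = method, conf_level = conf_level
  ), class = "meta_pool")
}

#' @export
print.meta_pool <- function(x, digits = 3, ...) {
  cat(sprintf("Random-effects pool (%s), k = %d\n", x$method, x$k))
  cat(sprintf("  estimate %.*f [%.*f, %.*f] (ratio scale)\n",
              digits, x$pooled_estimate, digits, x$ci_low, digits, x$ci_high))
  cat(sprintf("  Q = %.*f (df = %d, p = %s), I2 = %.1f%%, tau2 = %.*f\n",
              digits, x$Q, x$df, format.pval(x$Q_p, digits = digits),
              x$I2, digits + 1, x$tau2))
  cat(sprintf("  Egger intercept = %s (p = %s); Begg tau = %s (p = %s)\n",
              format(x$egger_intercept, digits = digits),
              format.pval(x$egger_p, digits = digits),
              format(x$begg_tau, digits = digits),
              format.pval(x$begg_p, digits = digits)))
  invisible(x)
}

#' Egger regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standardized effect `y/se` on the precision
#' `1/se`; the intercept and its two-sided t-test (`k - 2` df) are returned.
#' Requires `k >= 3` and non-constant precisions; degenerate inputs return
#' `NA`s.
#'
#' @inheritParams fixed_effect_pool
#' @return List with `intercept` and `p` (both `NA` when not evaluable).
#' @export
egger_test <- function(y, se) {
  check_effects(y, se)
  k <- length(y)
  if (k < 3L) return(list(intercept = NA_real_, p = NA_real_))
  prec <- 1 / se
  if (stats::sd(prec) < .Machine$double.eps^0.5 * mean(prec)) {
    return(list(intercept = NA_real_, p = NA_real_))
  }
  fit <- stats::lm(I(y / se) ~ prec)
  coefs <- summary(fit)$coefficients
  list(intercept = unname(coefs["(Intercept)", "Estimate"]),
       p = unname(coefs["(Intercept)", "Pr(>|t|)"]))
}

#' Begg and Mazumdar rank correlation test
#'
#' Kendall rank correlation between the variance-standardized deviations
#' from the fixed-effect pooled value, `(y - y_bar)/sqrt(se^2 - se_bar^2)`,
#' and the sampling variances, with the normal-approximation two-sided
#' p-value (no continuity correction).
#'
#' @inheritParams fixed_effect_pool
#' @return List with `tau` and `p` (`NA` when `k < 2`).
#' @export
begg_test <- function(y, se) {
  check_effects(y, se)
  k <- length(y)
  if (k < 2L) return(list(tau = NA_real_, p = NA_real_))
  fe <- fixed_effect_pool(y, se)
  v_star <- pmax(se^2 - fe$se_bar^2, .Machine$double.eps)
  dev <- (y - fe$y_bar) / sqrt(v_star)
  ct <- suppressWarnings(
    stats::cor.test(dev, se^2, method = "kendall",
                    exact = FALSE, continuity = FALSE)
  )
  list(tau = unname(ct$estimate), p = ct$p.value)
}

#' Funnel-plot coordinates
#'
#' Exports `(y, se)` pairs sorted by increasing standard error, ready for
#' plotting or CSV export. No filtering is applied.
#'
#' @inheritParams fixed_effect_pool
#' @return Data frame with columns `y` and `se`, sorted by `se`.
#' @export
funnel_points <- function(y, se) {
  check_effects(y, se)
  ord <- order(se)
  data.frame(y = y[ord], se = se[ord])
}

#' Pool a study table into one effect size per risk factor
#'
#' Splits a study-evidence table by `factor_id`, converts each factor's rows
#' to log effects (applying the estimate > 1 inclusion rule by default), and
#' runs [random_effects_pool()] per factor.
#'
#' @param studies Study data frame (see [read_studies()]).
#' @param conf_level Confidence level (default 0.95).
#' @param method Pooling method passed to [random_effects_pool()].
#' @param require_gt1 Apply the estimate > 1 inclusion rule (default `TRUE`).
#' @return An object of class `"pooled_effects"`: a data frame with one row
#'   per factor (columns `factor_id`, `pooled_estimate`, `ci_low`,
#'   `ci_high`, `k`, `Q`, `I2`, `tau2`, `egger_p`, `begg_p`), with the
#'   per-factor `"meta_pool"` objects in attribute `"pools"` and the
#'   rejected rows in attribute `"rejected"`.
#' @export
pool_studies <- function(studies, conf_level = 0.95, method = "DL",
                         require_gt1 = TRUE) {
  eff <- log_effects(studies, conf_level = conf_level,
                     require_gt1 = require_gt1)
  if (nrow(eff) == 0L) stop("no studies left after screening", call. = FALSE)
  split_eff <- split(eff, eff$factor_id)
  pools <- lapply(split_eff, function(d) {
    random_effects_pool(d$y, d$se, conf_level = conf_level, method = method)
  })
  rows <- lapply(names(pools), function(f) {
    p <- pools[[f]]
    data.frame(
      factor_id = f,
      pooled_estimate = p$pooled_estimate,
      ci_low = p$ci_low, ci_high = p$ci_high,
      k = p$k, Q = p$Q, I2 = p$I2, tau2 = p$tau2,
      egger_p = p$egger_p, begg_p = p$begg_p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  # keep first-appearance order of factors, not alphabetical
  out <- out[match(unique(eff$factor_id), out$factor_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pools") <- pools
  attr(out, "rejected") <- attr(eff, "rejected")
  class(out) <- c("pooled_effects", "data.frame")
  out
}

#' @export
print.pooled_effects <- function(x, digits = 3, ...) {
  cat("Pooled effects (random-effects meta-analysis), ",
      nrow(x), " factor(s)\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej) > 0L) {
    cat(nrow(rej), "study row(s) excluded:",
        paste(sprintf("%s (%s)", rej$study_label, rej$reason), collapse = ", "),
        "\n")
  }
  invisible(x)
}
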