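#' Pearson correlation with two-sided t-test
#'
#' Sample Pearson correlation with the p-value from the t transform with
#' `n - 2` degrees of freedom (two-sided). Missing values are deleted
#' pairwise and the effective `n` is reported.
#'
#' @param x,y Numeric vectors of equal length.
#' @param alpha Significance level used for the `significant` flag
#'   (default 0.05, two-tailed).
#' @return One-row data frame with `r`, `p`, `n`, `significant`.
#' @export
pearson_cor <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 paired non-missing values", call. = FALSE)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson",
                        alternative = "two.sided")
  data.frame(r = unname(ct$estimate), p = ct$p.value, n = n,
             significant = ct$p.value < alpha)
}

#' Correlations among composite, factors, and outcomes
#'
#' All pairwise Pearson correlations among the standardized composite
#' (`composite_z`), each factor column, and each outcome column of a region
#' index table, with two-tailed p-values and the 0.05 significance flag.
#'
#' @param table A region index table (see [build_region_index()]).
#' @param outcomes Character vector of outcome column names.
#' @param factors Character vector of factor columns to include (defaults to
#'   the coefficient factors recorded on the table).
#' @param alpha Significance level (default 0.05).
#' @return Data frame of class `"correlation_table"` with columns `var1`,
#'   `var2`, `r`, `p`, `n`, `significant`.
#' @export
correlation_matrix <- function(table, outcomes,
                               factors = attr(table, "coefficients")$factor_ids,
                               alpha = 0.05) {
  vars <- c("composite_z", factors, outcomes)
  missing <- setdiff(vars, names(table))
  if (length(missing) > 0L) {
    stop("column(s) not in table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pairs <- utils::combn(vars, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    v1 <- pairs[1, i]; v2 <- pairs[2, i]
    cbind(data.frame(var1 = v1, var2 = v2, stringsAsFactors = FALSE),
          pearson_cor(table[[v1]], table[[v2]], alpha = alpha))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' Per-factor sensitivity correlations
#'
#' Correlates each individual factor column with each outcome column —
#' the component-wise sensitivity analysis of the composite index. The
#' output has one row per factor x outcome pair.
#'
#' @inheritParams correlation_matrix
#' @return Data frame with columns `factor_id`, `outcome`, `r`, `p`, `n`,
#'   `significant`.
#' @export
per_factor_sensitivity <- function(table, outcomes,
                                   factors = attr(table, "coefficients")$factor_ids,
                                   alpha = 0.05) {
  missing <- setdiff(c(factors, outcomes), names(table))
  if (length(missing) > 0L) {
    stop("column(s) not in table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  grid <- expand.grid(factor_id = factors, outcome = outcomes,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cbind(grid[i, , drop = FALSE],
          pearson_cor(table[[grid$factor_id[i]]], table[[grid$outcome[i]]],
                      alpha = alpha))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
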