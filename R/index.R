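#' Index coefficient sets
#'
#' A coefficient set pairs an ordered list of risk factors with positive
#' weights summing to 1 (within rounding, for published vectors). It is the
#' object evaluated against exposure profiles in binary mode and multiplied
#' into z-scores in z-score mode.
#'
#' @param weights Numeric vector of positive weights.
#' @param factor_ids Factor names, same length and order as `weights`
#'   (defaults to `names(weights)`).
#' @param name Label for the coefficient set.
#' @param sum_tol Tolerance on `sum(weights) - 1` (default 1e-3, loose
#'   enough for published vectors rounded to 3 decimals).
#' @return An object of class `"index_coefficients"`.
#' @export
index_coefficients <- function(weights, factor_ids = names(weights),
                               name = "custom", sum_tol = 1e-3) {
  if (is.null(factor_ids) || length(factor_ids) != length(weights)) {
    stop("factor_ids must name every weight", call. = FALSE)
  }
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  if (abs(sum(weights) - 1) > sum_tol) {
    stop("weights must sum to 1 (got ", format(sum(weights)), ")",
         call. = FALSE)
  }
  structure(list(factor_ids = as.character(factor_ids),
                 weights = stats::setNames(as.numeric(weights),
                                           as.character(factor_ids)),
                 name = name),
            class = "index_coefficients")
}

#' @export
print.index_coefficients <- function(x, ...) {
  cat(sprintf("Index coefficients '%s' (%d factors, sum = %.3f)\n",
              x$name, length(x$weights), sum(x$weights)))
  print(x$weights)
  invisible(x)
}

# Published coefficient vectors. These are fixtures quoted verbatim from the
# source publication's index equations; they cannot be re-derived from the
# printed pooled effect sizes because the underlying judgment matrix was not
# published.
published_sets <- list(
  LCRI = list(
    factor_ids = c("active_smoking", "indoor_air_pollution",
                   "occupational_exposure", "alcohol",
                   "secondhand_smoke", "outdoor_air_pollution", "radon"),
    weights = c(0.461, 0.185, 0.132, 0.078, 0.076, 0.038, 0.030)
  ),
  LCRI_IL = list(
    factor_ids = c("active_smoking", "alcohol",
                   "outdoor_air_pollution", "radon"),
    weights = c(0.701, 0.147, 0.095, 0.057)
  )
)

#' Published lung-cancer risk index coefficients
#'
#' Returns the published coefficient fixtures: `"LCRI"`, the 7-factor
#' lung-cancer risk index over (active smoking, indoor air pollution,
#' occupational exposure, alcohol, secondhand smoke, outdoor air pollution,
#' radon), and `"LCRI_IL"`, the 4-factor Illinois case-study index over
#' (active smoking, alcohol, outdoor air pollution, radon). Both sum to
#' 1.000 at the published 3-decimal rounding.
#'
#' @param name `"LCRI"` or `"LCRI_IL"`.
#' @return An `"index_coefficients"` object.
#' @export
#' @examples
#' published_coefficients("LCRI_IL")
published_coefficients <- function(name) {
  if (length(name) != 1L || !name %in% names(published_sets)) {
    stop("unknown coefficient set '", paste(name, collapse = ","),
         "'; available: ", paste(names(published_sets), collapse = ", "),
         call. = FALSE)
  }
  set <- published_sets[[name]]
  index_coefficients(set$weights, set$factor_ids, name = name)
}

#' Evaluate a binary exposure profile against index coefficients
#'
#' The binary index mode: each factor indicator is 0 (no exposure) or 1
#' (exposure present) and the index is the weighted sum, ranging from 0 (no
#' predicted risk) to the coefficient total, 1 (all exposures present).
#'
#' @param profile Named numeric vector of 0/1 indicators covering every
#'   factor in `coef` (order-free; matching is by name).
#' @param coef An `"index_coefficients"` object.
#' @return Scalar index value in \eqn{[0, 1]}.
#' @export
#' @examples
#' lcri <- published_coefficients("LCRI")
#' evaluate_binary(c(active_smoking = 1, indoor_air_pollution = 0,
#'                   occupational_exposure = 0, alcohol = 0,
#'                   secondhand_smoke = 0, outdoor_air_pollution = 0,
#'                   radon = 0), lcri)
evaluate_binary <- function(profile, coef) {
  stopifnot(inherits(coef, "index_coefficients"))
  if (is.null(names(profile))) {
    if (length(profile) != length(coef$factor_ids)) {
      stop("unnamed profile must match the coefficient length", call. = FALSE)
    }
    names(profile) <- coef$factor_ids
  }
  missing <- setdiff(coef$factor_ids, names(profile))
  if (length(missing) > 0L) {
    stop("profile lacks indicator(s) for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ind <- profile[coef$factor_ids]
  if (any(!ind %in% c(0, 1))) {
    stop("indicators must be 0 or 1", call. = FALSE)
  }
  sum(coef$weights * ind)
}

#' Z-score columns of a region table
#'
#' Standardizes the given columns across regions: `z = (x - mean)/sd` with
#' the sample (n - 1) standard deviation. Missing values are excluded from
#' the mean/sd and propagate as missing z-scores. New columns are appended
#' with a `_z` suffix.
#'
#' @param table Region data frame.
#' @param columns Character vector of column names to standardize.
#' @return `table` with one `<column>_z` column appended per input column.
#' @export
zscore_columns <- function(table, columns) {
  missing <- setdiff(columns, names(table))
  if (length(missing) > 0L) {
    stop("column(s) not in table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(table) < 2L) stop("need at least 2 regions", call. = FALSE)
  for (col in columns) {
    x <- table[[col]]
    if (!is.numeric(x)) stop("column '", col, "' is not numeric", call. = FALSE)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("column '", col, "' has zero variance; cannot z-score",
           call. = FALSE)
    }
    table[[paste0(col, "_z")]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  table
}

#' Weighted composite of z-scored factors
#'
#' Computes `composite = sum_f weight_f * z_f` per region plus a
#' standardized copy `composite_z`. Regions with a missing z-score in any
#' weighted factor get a missing composite (no silent imputation).
#'
#' @param table Region data frame already carrying `<factor>_z` columns
#'   (see [zscore_columns()]).
#' @param coef An `"index_coefficients"` object whose `factor_ids` match the
#'   z columns (i.e. column `<factor_id>_z` must exist for each factor).
#' @return `table` with `composite` and `composite_z` columns appended.
#' @export
composite_score <- function(table, coef) {
  stopifnot(inherits(coef, "index_coefficients"))
  zcols <- paste0(coef$factor_ids, "_z")
  missing <- setdiff(zcols, names(table))
  if (length(missing) == length(zcols)) {
    stop("no coefficient factor has a z column in the table", call. = FALSE)
  }
  if (length(missing) > 0L) {
    stop("missing z column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  zmat <- as.matrix(table[, zcols, drop = FALSE])
  composite <- as.vector(zmat %*% coef$weights)
  n_miss <- sum(is.na(composite))
  if (n_miss > 0L) {
    message(n_miss, " region(s) have a missing factor z-score; composite set to NA")
  }
  table$composite <- composite
  s <- stats::sd(composite, na.rm = TRUE)
  if (!is.finite(s) || s == 0) s <- 1  # degenerate: all-equal composites
  table$composite_z <- (composite - mean(composite, na.rm = TRUE)) / s
  table
}

#' Percentile ranks of a composite column
#'
#' Converts composite scores to percentiles with the average-rank
#' convention: `percentile = 100 * rank / n` over non-missing values, so the
#' maximum maps to 100 and ties share a rank. The transform is monotone in
#' the composite. Missing values stay missing.
#'
#' @param x Numeric vector of composite scores.
#' @return Numeric vector of percentiles in \eqn{(0, 100]}.
#' @export
to_percentile <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) stop("all composite values are missing", call. = FALSE)
  out <- rep(NA_real_, length(x))
  out[ok] <- 100 * rank(x[ok], ties.method = "average") / sum(ok)
  out
}

#' Build a full region index table
#'
#' One-call z-score pipeline: standardize the factor columns, form the
#' weighted composite, standardize it, and attach percentiles. Factor
#' columns may be renamed to coefficient factor ids via `factor_cols`.
#'
#' In binary mode the factor columns must hold 0/1 exposure indicators and
#' the composite is the plain weighted sum (the index then lives in
#' \eqn{[0, 1]}); in z-score mode (default) the factor columns are
#' continuous exposures standardized across regions first.
#'
#' @param regions Region data frame with a `region_id` column (created from
#'   row numbers if absent), one column per factor, and optional outcome
#'   columns.
#' @param coef An `"index_coefficients"` object.
#' @param factor_cols Optional named character vector mapping
#'   `factor_id -> column name` when table columns are not already named by
#'   factor id.
#' @param mode `"zscore"` (default) or `"binary"`.
#' @return A data frame of class `"region_index"` with per-factor z-scores
#'   (z-score mode only), `composite`, `composite_z` and `percentile`;
#'   `coef` is kept in attribute `"coefficients"`.
#' @export
build_region_index <- function(regions, coef, factor_cols = NULL,
                               mode = c("zscore", "binary")) {
  mode <- match.arg(mode)
  stopifnot(inherits(coef, "index_coefficients"))
  if (!"region_id" %in% names(regions)) {
    regions <- cbind(region_id = seq_len(nrow(regions)), regions)
  }
  if (!is.null(factor_cols)) {
    bad <- setdiff(unname(factor_cols), names(regions))
    if (length(bad) > 0L) {
      stop("mapped column(s) not in region table: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    idx <- match(unname(factor_cols), names(regions))
    names(regions)[idx] <- names(factor_cols)
  }
  absent <- setdiff(coef$factor_ids, names(regions))
  if (length(absent) > 0L) {
    stop("region table lacks factor column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (mode == "zscore") {
    tab <- zscore_columns(regions, coef$factor_ids)
    tab <- composite_score(tab, coef)
  } else {
    tab <- regions
    tab$composite <- vapply(seq_len(nrow(tab)), function(i) {
      prof <- unlist(tab[i, coef$factor_ids])
      evaluate_binary(prof, coef)
    }, numeric(1))
    s <- stats::sd(tab$composite, na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- 1
    tab$composite_z <- (tab$composite - mean(tab$composite, na.rm = TRUE)) / s
  }
  tab$percentile <- to_percentile(tab$composite)
  attr(tab, "coefficients") <- coef
  class(tab) <- c("region_index", "data.frame")
  tab
}
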