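# Saaty's Random Index for positive reciprocal matrices of order n = 2..10.
# CR = CI1/RI is undefined where RI = 0; by convention CR = 0 for n = 2.
saaty_ri <- c(`2` = 0, `3` = 0.58, `4` = 0.90, `5` = 1.12, `6` = 1.24,
              `7` = 1.32, `8` = 1.41, `9` = 1.45, `10` = 1.49)

#' Build a pairwise comparison matrix from pooled effect sizes
#'
#' Constructs the n x n positive reciprocal comparison matrix whose entry
#' `a_ij` expresses the importance of factor i relative to factor j.
#'
#' Two deterministic mappings from effect sizes to matrix entries are
#' available:
#' \describe{
#'   \item{`continuous_ratio`}{`a_ij = ES_i / ES_j` exactly. The matrix is
#'     perfectly consistent by construction, so the priority weights reduce
#'     to `ES / sum(ES)` and the consistency ratio is 0.}
#'   \item{`saaty_rounded`}{for `ES_i >= ES_j`, `a_ij` is the ratio rounded
#'     to the nearest integer and clamped to the Saaty scale `[1, 9]`
#'     (1 = equal importance ... 9 = extreme importance); `a_ji = 1/a_ij`.}
#' }
#' A judgment matrix elicited by experts can instead be supplied directly to
#' [principal_eigenvector()].
#'
#' @param effects Numeric vector of pooled effect sizes, all > 1 (ratio
#'   measures at or below 1 carry no excess-risk signal and are not
#'   comparable on the importance scale).
#' @param factor_ids Optional character vector of factor names (defaults to
#'   `names(effects)`).
#' @param mode `"continuous_ratio"` (default) or `"saaty_rounded"`.
#' @return A `"comparison_matrix"`: a numeric matrix with dimnames set to
#'   the factor ids and the mapping mode in attribute `"mode"`.
#' @export
#' @examples
#' comparison_matrix(c(smoking = 8.63, radon = 1.24), mode = "saaty_rounded")
comparison_matrix <- function(effects, factor_ids = names(effects),
                              mode = c("continuous_ratio", "saaty_rounded")) {
  mode <- match.arg(mode)
  n <- length(effects)
  if (n < 2L) stop("need at least 2 factors", call. = FALSE)
  if (any(!is.finite(effects)) || any(effects <= 0)) {
    stop("all effect sizes must be positive", call. = FALSE)
  }
  if (any(effects <= 1)) {
    stop("all effect sizes must exceed 1 (AHP inclusion rule); offending: ",
         paste(which(effects <= 1), collapse = ", "), call. = FALSE)
  }
  if (is.null(factor_ids)) factor_ids <- paste0("factor_", seq_len(n))

  a <- matrix(1, n, n, dimnames = list(factor_ids, factor_ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      r <- effects[i] / effects[j]
      hi <- max(r, 1 / r)
      entry <- if (mode == "saaty_rounded") min(max(round(hi), 1), 9) else hi
      if (r >= 1) {
        a[i, j] <- entry
        a[j, i] <- 1 / entry
      } else {
        a[j, i] <- entry
        a[i, j] <- 1 / entry
      }
    }
  }
  structure(a, mode = mode, class = c("comparison_matrix", "matrix", "array"))
}

#' Principal eigenvector of a comparison matrix by power iteration
#'
#' Iterates `x <- A x` with L1 normalization from a uniform start vector.
#' Positive reciprocal matrices have a dominant positive (Perron) eigenvalue,
#' so the iteration converges to the principal eigenvector; `lambda_max` is
#' recovered as the L1 growth factor at convergence.
#'
#' @param a Square positive matrix (a `"comparison_matrix"` or any matrix
#'   satisfying its invariants: unit diagonal, `a_ji = 1/a_ij`, entries > 0).
#' @param tol Convergence tolerance on the L1 difference of successive
#'   normalized vectors (default 1e-10).
#' @param max_iter Iteration cap (default 10000).
#' @return List with `lambda_max`, `weights` (positive, summing to 1) and
#'   `iterations`.
#' @export
principal_eigenvector <- function(a, tol = 1e-10, max_iter = 10000L) {
  a <- unclass(a)
  n <- nrow(a)
  if (is.null(n) || n != ncol(a) || n < 2L) {
    stop("a must be a square matrix of order >= 2", call. = FALSE)
  }
  if (any(a <= 0)) stop("comparison matrix entries must be positive", call. = FALSE)
  recip_err <- max(abs(a * t(a) - 1))
  if (recip_err > 1e-6) {
    stop("matrix is not reciprocal (max |a_ij * a_ji - 1| = ",
         format(recip_err), ")", call. = FALSE)
  }

  x <- rep(1 / n, n)
  lambda <- NA_real_
  for (it in seq_len(max_iter)) {
    x_new <- as.vector(a %*% x)
    lambda <- sum(x_new)          # L1 growth factor: x is L1-normalized
    x_new <- x_new / lambda
    if (sum(abs(x_new - x)) < tol) {
      names(x_new) <- rownames(a)
      return(list(lambda_max = lambda, weights = x_new, iterations = it))
    }
    x <- x_new
  }
  stop("power iteration did not converge in ", max_iter, " iterations",
       call. = FALSE)
}

#' Consistency index of a comparison matrix
#'
#' `CI1 = (lambda_max - n) / (n - 1)`; zero iff the matrix is perfectly
#' consistent (`lambda_max = n`).
#'
#' @param lambda_max Dominant eigenvalue.
#' @param n Matrix order (>= 2).
#' @return The consistency index.
#' @export
consistency_index <- function(lambda_max, n) {
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  (lambda_max - n) / (n - 1)
}

#' Consistency ratio and pass/fail report
#'
#' `CR = CI1 / RI(n)` with Saaty's Random Index; a matrix is conventionally
#' acceptable when `CR < 0.1`. For `n = 2` the RI is 0 and CR is defined as
#' 0 (a 2 x 2 reciprocal matrix is always consistent).
#'
#' @param ci1 Consistency index from [consistency_index()].
#' @param n Matrix order, 2 to 10 (the range of the tabulated RI).
#' @return An object of class `"consistency_report"`: list with `ci1`, `ri`,
#'   `cr`, `n`, `passes`.
#' @export
consistency_ratio <- function(ci1, n) {
  key <- as.character(n)
  if (!key %in% names(saaty_ri)) {
    stop("Random Index is tabulated for n in 2..10, got n = ", n,
         call. = FALSE)
  }
  ri <- unname(saaty_ri[key])
  cr <- if (n == 2L) 0 else ci1 / ri
  structure(list(ci1 = ci1, ri = ri, cr = cr, n = as.integer(n),
                 passes = cr < 0.1),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("Consistency: CI1 = %.4g, RI(%d) = %.2f, CR = %.4g -> %s\n",
              x$ci1, x$n, x$ri, x$cr,
              if (x$passes) "acceptable (CR < 0.1)" else "NOT acceptable (CR >= 0.1)"))
  invisible(x)
}

#' Derive AHP priority weights from pooled effect sizes
#'
#' The full weighting step: build the pairwise comparison matrix, extract
#' the principal eigenvector as the priority (weight) vector, and check
#' consistency. Weights are L1-normalized so they can be read as index
#' coefficients summing to 1.
#'
#' @inheritParams comparison_matrix
#' @param on_inconsistent What to do when `CR >= 0.1`: `"warn"` (default)
#'   or `"fail"`.
#' @param tol,max_iter Passed to [principal_eigenvector()].
#' @return An object of class `"ahp"`: list with `weights` (named, sum 1),
#'   `lambda_max`, `matrix`, `consistency` (a `"consistency_report"`),
#'   `mode`, `effects`.
#' @export
#' @examples
#' fit <- derive_weights(c(smoking = 8.63, alcohol = 1.45,
#'                         pm25 = 1.25, radon = 1.24))
#' coef(fit)
derive_weights <- function(effects, factor_ids = names(effects),
                           mode = c("continuous_ratio", "saaty_rounded"),
                           on_inconsistent = c("warn", "fail"),
                           tol = 1e-10, max_iter = 10000L) {
  mode <- match.arg(mode)
  on_inconsistent <- match.arg(on_inconsistent)
  a <- comparison_matrix(effects, factor_ids = factor_ids, mode = mode)
  eig <- principal_eigenvector(a, tol = tol, max_iter = max_iter)
  n <- nrow(a)
  report <- consistency_ratio(consistency_index(eig$lambda_max, n), n)
  if (!report$passes) {
    msg <- sprintf("comparison matrix fails the consistency check (CR = %.3f >= 0.1)",
                   report$cr)
    if (on_inconsistent == "fail") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  effects <- stats::setNames(as.numeric(effects), rownames(a))
  structure(list(weights = eig$weights, lambda_max = eig$lambda_max,
                 matrix = a, consistency = report, mode = mode,
                 effects = effects),
            class = "ahp")
}

#' @export
print.ahp <- function(x, digits = 4, ...) {
  cat(sprintf("AHP priority weights (%s mapping), n = %d\n",
              x$mode, length(x$weights)))
  w <- sort(x$weights, decreasing = TRUE)
  print(round(w, digits))
  cat(sprintf("lambda_max = %.*f; ", digits, x$lambda_max))
  print(x$consistency)
  invisible(x)
}

#' @export
coef.ahp <- function(object, ...) object$weights

#' @export
summary.ahp <- function(object, ...) {
  data.frame(
    factor_id = names(object$weights),
    effect_size = unname(object$effects),
    weight = unname(object$weights),
    weight_percent = unname(object$weights) * 100,
    stringsAsFactors = FALSE
  )
}
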