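#' Read a study-evidence table
#'
#' Reads a CSV of per-study effect estimates, one row per published study per
#' risk factor. Required columns: `factor_id`, `estimate`, `ci_low`,
#' `ci_high`. Optional columns: `study_label`, `estimate_kind` (`"OR"` or
#' `"RR"`; retained for audit only, the two are pooled together on the log
#' scale).
#'
#' @param path Path to a CSV file (UTF-8, dot decimal separator).
#' @return A data frame of study estimates.
#' @export
read_studies <- function(path) {
  studies <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_studies(studies)
  studies
}

validate_studies <- function(studies) {
  required <- c("factor_id", "estimate", "ci_low", "ci_high")
  missing <- setdiff(required, names(studies))
  if (length(missing) > 0L) {
    stop("study table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"study_label" %in% names(studies)) {
    studies$study_label <- paste0("study_", seq_len(nrow(studies)))
  }
  if (!"estimate_kind" %in% names(studies)) {
    studies$estimate_kind <- "OR"
  }
  invisible(studies)
}

#' Convert ratio-scale estimates with 95\% CIs to log effects
#'
#' Transforms each study's OR/RR and confidence interval to a log effect
#' `y = log(estimate)` with standard error
#' `se = (log(ci_high) - log(ci_low)) / (2 * z_crit)`, assuming a symmetric
#' Wald interval on the log scale.
#'
#' Rows are screened before conversion:
#' \itemize{
#'   \item nonpositive estimate or CI bound: rejected (`"nonpositive"`);
#'   \item `ci_low == ci_high`: rejected, zero standard error (`"zero_se"`);
#'   \item `estimate <= 1` when `require_gt1 = TRUE`: rejected
#'     (`"estimate_le_1"`) — downstream AHP weighting requires risk
#'     estimates above 1;
#'   \item CI grossly asymmetric on the log scale (ratio of half-widths
#'     above `asymmetry_tol`): kept, but flagged in the `asymmetric` column.
#' }
#'
#' @param studies Data frame with columns `factor_id`, `estimate`, `ci_low`,
#'   `ci_high` (see [read_studies()]).
#' @param conf_level Confidence level of the reported intervals (default
#'   0.95, i.e. `z_crit = qnorm(0.975)`).
#' @param require_gt1 Reject rows with `estimate <= 1`? Default `TRUE`,
#'   matching the inclusion rule for AHP inputs.
#' @param asymmetry_tol Flag threshold for the ratio of log-scale CI
#'   half-widths. Default 1.5.
#' @return A data frame with columns `factor_id`, `study_label`, `y`, `se`,
#'   `estimate`, `asymmetric`; rejected rows (with a `reason` column) are
#'   attached as attribute `"rejected"`.
#' @export
#' @examples
#' s <- data.frame(factor_id = "smoking", estimate = 2, ci_low = 1, ci_high = 4)
#' log_effects(s, require_gt1 = FALSE)
log_effects <- function(studies, conf_level = 0.95, require_gt1 = TRUE,
                        asymmetry_tol = 1.5) {
  studies <- validate_studies(studies)
  z_crit <- stats::qnorm(1 - (1 - conf_level) / 2)

  reason <- rep(NA_character_, nrow(studies))
  bad <- with(studies, estimate <= 0 | ci_low <= 0 | ci_high <= 0 |
                is.na(estimate) | is.na(ci_low) | is.na(ci_high))
  reason[bad] <- "nonpositive"
  zero_se <- !bad & studies$ci_low == studies$ci_high
  reason[zero_se] <- "zero_se"
  if (require_gt1) {
    le1 <- !bad & !zero_se & studies$estimate <= 1
    reason[le1] <- "estimate_le_1"
  }

  keep <- is.na(reason)
  rejected <- studies[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  kept <- studies[keep, , drop = FALSE]

  y <- log(kept$estimate)
  se <- (log(kept$ci_high) - log(kept$ci_low)) / (2 * z_crit)
  hw_up <- log(kept$ci_high) - y
  hw_dn <- y - log(kept$ci_low)
  ratio <- pmax(hw_up, hw_dn) / pmin(hw_up, hw_dn)
  asymmetric <- is.finite(ratio) & ratio > asymmetry_tol
  if (any(asymmetric)) {
    message(sum(asymmetric), " row(s) have log-scale CI half-width ratio > ",
            asymmetry_tol, "; kept but flagged")
  }

  out <- data.frame(
    factor_id = kept$factor_id,
    study_label = kept$study_label,
    y = y,
    se = se,
    estimate = kept$estimate,
    asymmetric = asymmetric,
    stringsAsFactors = FALSE
  )
  attr(out, "rejected") <- rejected
  out
}
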