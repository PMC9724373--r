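#' Read a pipeline configuration
#'
#' Configurations are YAML or JSON (by file extension) with fields:
#' \describe{
#'   \item{factors}{list of entries with `factor_id`, `column` (region-table
#'     column name, or `"unavailable"` when no regional data exist) and
#'     either `effect` (a pooled effect size) or nothing, in which case the
#'     factor is pooled from `studies_csv`.}
#'   \item{studies_csv}{optional study-evidence CSV pooled per factor for
#'     entries without a fixed `effect`.}
#'   \item{region_csv}{region table CSV (`region_id`, factor columns,
#'     outcome columns).}
#'   \item{map}{`"continuous_ratio"` or `"saaty_rounded"`.}
#'   \item{mode}{`"zscore"` or `"binary"`.}
#'   \item{outcomes}{outcome column names.}
#'   \item{use_published}{optional fixture name (`"LCRI"`, `"LCRI_IL"`)
#'     replacing AHP-derived weights.}
#'   \item{drop_factors}{optional factor ids, each re-analyzed with that
#'     factor removed (drop-one sensitivity).}
#'   \item{seed}{optional integer recorded in the manifest.}
#' }
#' Relative paths are resolved against the config file's directory.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return The configuration as a named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  config <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    stop("config must be .yaml/.yml or .json", call. = FALSE)
  )
  dir <- dirname(normalizePath(path))
  for (f in c("studies_csv", "region_csv")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      candidate <- file.path(dir, config[[f]])
      if (file.exists(candidate)) config[[f]] <- candidate
    }
  }
  validate_pipeline_config(config)
}

validate_pipeline_config <- function(config) {
  if (is.null(config$factors) || length(config$factors) < 2L) {
    stop("config needs at least 2 factors", call. = FALSE)
  }
  config$map <- config$map %||% "continuous_ratio"
  config$mode <- config$mode %||% "zscore"
  ids <- vapply(config$factors, function(f) f$factor_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate factor_id in config", call. = FALSE)
  cols <- vapply(config$factors, function(f) f$column %||% "unavailable",
                 character(1))
  overlap <- intersect(config$outcomes, cols)
  if (length(overlap) > 0L) {
    stop("outcome column(s) also used as factor column(s): ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pooled effect per config factor
#'
#' Resolves each configured factor to a pooled effect size: a literal
#' `effect` value if given, otherwise the random-effects pooled estimate
#' from the configured study CSV.
#' @keywords internal
resolve_effects <- function(config) {
  ids <- vapply(config$factors, function(f) f$factor_id, character(1))
  effects <- vapply(config$factors, function(f) f$effect %||% NA_real_,
                    numeric(1))
  if (anyNA(effects)) {
    if (is.null(config$studies_csv)) {
      stop("factor(s) without a pooled effect and no studies_csv: ",
           paste(ids[is.na(effects)], collapse = ", "), call. = FALSE)
    }
    pooled <- pool_studies(read_studies(config$studies_csv))
    for (i in which(is.na(effects))) {
      row <- match(ids[i], pooled$factor_id)
      if (is.na(row)) {
        stop("no studies found for factor '", ids[i], "'", call. = FALSE)
      }
      effects[i] <- pooled$pooled_estimate[row]
    }
  }
  stats::setNames(effects, ids)
}

#' Subset factors to available data and re-derive weights
#'
#' Drops factors without regional data and re-runs the AHP weighting on the
#' survivors' pooled effect sizes — the step that turns a full index into a
#' region-tailored one when some exposures have no published regional data.
#'
#' @param effects Named vector of pooled effect sizes for the full factor
#'   set.
#' @param available Character vector of factor ids that have regional data.
#' @param mode Comparison-matrix mapping (see [comparison_matrix()]).
#' @param ... Passed to [derive_weights()].
#' @return List with `coefficients` (an `"index_coefficients"`), `ahp` (the
#'   full `"ahp"` fit) and `dropped` (character vector).
#' @export
#' @examples
#' es <- c(active_smoking = 8.63, indoor_air_pollution = 1.76,
#'         occupational_exposure = 1.60, alcohol = 1.45,
#'         secondhand_smoke = 1.43, outdoor_air_pollution = 1.25,
#'         radon = 1.24)
#' subset_and_reweight(es, c("active_smoking", "alcohol",
#'                           "outdoor_air_pollution", "radon"))
subset_and_reweight <- function(effects, available = names(effects),
                                mode = "continuous_ratio", ...) {
  unknown <- setdiff(available, names(effects))
  if (length(unknown) > 0L) {
    stop("available factor(s) not in the effect set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- names(effects)[names(effects) %in% available]
  if (length(keep) < 2L) {
    stop("fewer than 2 factors have regional data", call. = FALSE)
  }
  dropped <- setdiff(names(effects), keep)
  fit <- derive_weights(effects[keep], mode = mode, ...)
  list(
    coefficients = index_coefficients(fit$weights, names(fit$weights),
                                      name = "ahp_derived"),
    ahp = fit,
    dropped = dropped
  )
}

#' Drop-one-factor sensitivity analysis
#'
#' Removes one factor, re-derives the AHP weights on the survivors, rebuilds
#' the composite index, and recomputes the index-outcome correlations, so
#' the effect of the dropped factor on the index's validity can be read off
#' side by side.
#'
#' @param effects Named vector of pooled effect sizes (the factors currently
#'   in the index).
#' @param regions Region data frame (factor columns named by factor id or
#'   mapped via `factor_cols`).
#' @param outcomes Outcome column names.
#' @param drop Factor id to remove.
#' @param mode Comparison-matrix mapping.
#' @param index_mode `"zscore"` or `"binary"`.
#' @param factor_cols Optional factor-to-column mapping (see
#'   [build_region_index()]).
#' @return List with `coefficients` (reduced set), `before` and `after`
#'   (index-outcome correlation tables), and `comparison` (one row per
#'   outcome with `r_before`, `r_after`).
#' @export
drop_factor_sensitivity <- function(effects, regions, outcomes, drop,
                                    mode = "continuous_ratio",
                                    index_mode = "zscore",
                                    factor_cols = NULL) {
  if (!drop %in% names(effects)) {
    stop("factor '", drop, "' is not in the index", call. = FALSE)
  }
  if (length(effects) - 1L < 2L) {
    stop("dropping '", drop, "' would leave fewer than 2 factors",
         call. = FALSE)
  }
  index_outcome_cors <- function(es) {
    fit <- derive_weights(es, mode = mode)
    coefs <- index_coefficients(fit$weights, names(fit$weights),
                                name = "ahp_derived")
    tab <- build_region_index(regions, coefs, factor_cols = factor_cols,
                              mode = index_mode)
    rows <- lapply(outcomes, function(oc) {
      cbind(data.frame(outcome = oc, stringsAsFactors = FALSE),
            pearson_cor(tab$composite_z, tab[[oc]]))
    })
    list(coefficients = coefs, cors = do.call(rbind, rows))
  }
  before <- index_outcome_cors(effects)
  after <- index_outcome_cors(effects[setdiff(names(effects), drop)])
  comparison <- data.frame(
    outcome = before$cors$outcome,
    r_before = before$cors$r,
    r_after = after$cors$r
  )
  list(coefficients = after$coefficients, before = before$cors,
       after = after$cors, comparison = comparison)
}

#' Run the full index pipeline
#'
#' End-to-end orchestration: resolve pooled effects, subset to factors with
#' regional data, derive AHP weights (or apply a published fixture), build
#' the region index table, compute the correlation and sensitivity tables,
#' and write everything plus a machine-readable manifest to `out_dir`.
#'
#' Outputs written: `weights.csv`, `consistency.json`, `index_table.csv`,
#' `correlations.csv`, `sensitivity.csv`, per-dropped-factor
#' `drop_<factor>.csv`, `manifest.json`, `run.log`. Identical config and
#' seed produce byte-identical outputs.
#'
#' @param config Config list (see [read_pipeline_config()]) or a path to a
#'   YAML/JSON config file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`coefficients`,
#'   `consistency`, `index_table`, `correlations`, `sensitivity`,
#'   `drop_sensitivity`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  stage <- "resolve_effects"
  result <- tryCatch({
    effects <- resolve_effects(config)
    say("pooled effects: ",
        paste(sprintf("%s=%.4g", names(effects), effects), collapse = ", "))

    stage <- "read_regions"
    if (is.null(config$region_csv)) stop("config lacks region_csv", call. = FALSE)
    regions <- utils::read.csv(config$region_csv, stringsAsFactors = FALSE)
    cols <- vapply(config$factors, function(f) f$column %||% "unavailable",
                   character(1))
    ids <- names(effects)
    available <- ids[cols != "unavailable"]
    declared <- cols[cols != "unavailable"]
    missing_cols <- setdiff(declared, names(regions))
    if (length(missing_cols) > 0L) {
      stop("region table lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    factor_cols <- stats::setNames(declared, available)

    stage <- "subset_and_reweight"
    sw <- subset_and_reweight(effects, available, mode = config$map)
    if (length(sw$dropped) > 0L) {
      say("dropped (no regional data): ", paste(sw$dropped, collapse = ", "))
    }
    coefs <- sw$coefficients
    consistency <- sw$ahp$consistency
    if (!is.null(config$use_published)) {
      coefs <- published_coefficients(config$use_published)
      say("using published coefficient fixture '", config$use_published, "'")
    }

    stage <- "build_index"
    index_tab <- build_region_index(regions, coefs,
                                    factor_cols = factor_cols[coefs$factor_ids],
                                    mode = config$mode)

    stage <- "correlations"
    outcomes <- unlist(config$outcomes)
    cors <- sens <- NULL
    if (length(outcomes) > 0L) {
      cors <- correlation_matrix(index_tab, outcomes)
      sens <- per_factor_sensitivity(index_tab, outcomes)
    }

    stage <- "drop_sensitivity"
    drops <- list()
    for (d in unlist(config$drop_factors)) {
      drops[[d]] <- drop_factor_sensitivity(
        effects[coefs$factor_ids], regions, outcomes, d,
        mode = config$map, index_mode = config$mode,
        factor_cols = factor_cols[coefs$factor_ids]
      )
      say("drop-", d, " sensitivity: ",
          paste(sprintf("%s r %.3f -> %.3f", drops[[d]]$comparison$outcome,
                        drops[[d]]$comparison$r_before,
                        drops[[d]]$comparison$r_after), collapse = "; "))
    }

    stage <- "write_outputs"
    wdf <- data.frame(factor_id = coefs$factor_ids,
                      weight = unname(coefs$weights),
                      weight_percent = unname(coefs$weights) * 100)
    utils::write.csv(wdf, file.path(out_dir, "weights.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(lambda_max = sw$ahp$lambda_max, ci1 = consistency$ci1,
           ri = consistency$ri, cr = consistency$cr,
           passes = consistency$passes),
      file.path(out_dir, "consistency.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame(index_tab),
                     file.path(out_dir, "index_table.csv"), row.names = FALSE)
    if (!is.null(cors)) {
      utils::write.csv(cors, file.path(out_dir, "correlations.csv"),
                       row.names = FALSE)
      utils::write.csv(sens, file.path(out_dir, "sensitivity.csv"),
                       row.names = FALSE)
    }
    for (d in names(drops)) {
      utils::write.csv(drops[[d]]$comparison,
                       file.path(out_dir, paste0("drop_", d, ".csv")),
                       row.names = FALSE)
    }

    manifest <- list(
      package = "metaahp",
      version = as.character(utils::packageVersion("metaahp")),
      seed = config$seed %||% NA,
      map = config$map, mode = config$mode,
      factors = ids, available = available,
      outcomes = as.list(outcomes),
      coefficient_source = if (is.null(config$use_published)) "ahp" else
        config$use_published,
      outputs = sort(setdiff(list.files(out_dir),
                             c("manifest.json", "run.log")))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))

    list(coefficients = coefs, consistency = consistency,
         index_table = index_tab, correlations = cors, sensitivity = sens,
         drop_sensitivity = drops, manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
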