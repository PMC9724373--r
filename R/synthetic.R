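#' Default synthetic study-evidence design
#'
#' Seven risk factors with true pooled effects matching the magnitudes of a
#' typical lung-cancer evidence base (one dominant factor near OR 8.6, six
#' between 1.2 and 1.8), 52 studies in total, moderate between-study
#' heterogeneity (`tau2 = 0.05`) and study standard errors between 0.1 and
#' 0.5 on the log scale.
#'
#' @return Data frame with columns `factor_id`, `true_log_effect`, `tau2`,
#'   `k`, `se_low`, `se_high`.
#' @export
default_study_spec <- function() {
  data.frame(
    factor_id = c("active_smoking", "indoor_air_pollution",
                  "occupational_exposure", "alcohol", "secondhand_smoke",
                  "outdoor_air_pollution", "radon"),
    true_log_effect = log(c(8.63, 1.76, 1.60, 1.45, 1.43, 1.25, 1.24)),
    tau2 = 0.05,
    k = c(12L, 8L, 8L, 6L, 6L, 6L, 6L),
    se_low = 0.1,
    se_high = 0.5,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic study-evidence table
#'
#' For each factor and study: the study-level true log effect is drawn from
#' `Normal(true_log_effect, tau2)`, the standard error uniformly from
#' `[se_low, se_high]`, and the observed log effect from
#' `Normal(study effect, se^2)`. The emitted row carries
#' `OR = exp(y)` with the 95\% Wald interval `exp(y +/- z * se)`. Rows with
#' `OR <= 1` are emitted as drawn — screening them out is the job of the
#' meta-analysis inclusion filter, not of the generator.
#'
#' @param spec Study design data frame (see [default_study_spec()]).
#' @param seed Integer seed; identical seeds give byte-identical tables.
#' @param conf_level Confidence level of the emitted intervals (default 0.95).
#' @return Study data frame in the [read_studies()] dialect with the spec
#'   stored in attribute `"ground_truth"`.
#' @export
gen_studies <- function(spec = default_study_spec(), seed = 1,
                        conf_level = 0.95) {
  required <- c("factor_id", "true_log_effect", "tau2", "k",
                "se_low", "se_high")
  missing <- setdiff(required, names(spec))
  if (length(missing) > 0L) {
    stop("study spec lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(spec$k < 1L) || any(spec$tau2 < 0) || any(spec$se_low <= 0) ||
      any(spec$se_high < spec$se_low)) {
    stop("invalid study spec", call. = FALSE)
  }
  set.seed(seed)
  z_crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    k <- spec$k[i]
    theta <- stats::rnorm(k, spec$true_log_effect[i], sqrt(spec$tau2[i]))
    se <- stats::runif(k, spec$se_low[i], spec$se_high[i])
    y <- stats::rnorm(k, theta, se)
    data.frame(
      factor_id = spec$factor_id[i],
      study_label = paste0(spec$factor_id[i], "_study_", seq_len(k)),
      estimate = exp(y),
      ci_low = exp(y - z_crit * se),
      ci_high = exp(y + z_crit * se),
      estimate_kind = "OR",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ground_truth") <- spec
  out
}

#' Default synthetic region-table design
#'
#' Emulates a state of 102 counties with four exposures: current-smoker
#' percentage (normal, mean 18, sd 3.5), binge/heavy drinking percentage
#' (normal, mean 18, sd 3), PM2.5 concentration in micrograms per cubic
#' metre (normal, mean 9, sd 1.5), and radon in pCi/L (lognormal, mean 4.5,
#' sd 2 — radon is nonnegative and right-skewed).
#'
#' @return Data frame with columns `factor_id`, `mean`, `sd`, `dist`.
#' @export
default_region_spec <- function() {
  data.frame(
    factor_id = c("active_smoking", "alcohol", "outdoor_air_pollution",
                  "radon"),
    mean = c(18, 18, 9, 4.5),
    sd = c(3.5, 3, 1.5, 2),
    dist = c("normal", "normal", "normal", "lognormal"),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic region table with planted outcome correlation
#'
#' Draws per-region factor values from the spec's distributions, computes
#' the true composite as the ground-truth-weighted sum of z-scored factors,
#' and draws each outcome from the linear model
#' `outcome = mean + sd * (rho * composite_z + sqrt(1 - rho^2) * noise)`
#' with standard normal noise, which plants a population correlation `rho`
#' between the standardized true composite and the outcome.
#'
#' @param n_regions Number of regions (default 102).
#' @param spec Factor design data frame (see [default_region_spec()]).
#' @param weights Ground-truth index weights, named by factor id; default
#'   the published 4-factor case-study coefficients.
#' @param rho Planted composite-outcome correlation, `|rho| < 1`
#'   (default 0.5).
#' @param outcomes Named list of `c(mean, sd)` pairs per outcome column;
#'   default age-adjusted-rate-like scales: incidence mean 65, sd 10 and
#'   mortality mean 45, sd 8 per 100,000.
#' @param seed Integer seed.
#' @return List with `regions` (data frame: `region_id`, factor columns,
#'   outcome columns) and `truth` (list: `weights`, `rho`, `seed`,
#'   `true_composite`, `true_composite_z`).
#' @export
gen_regions <- function(n_regions = 102,
                        spec = default_region_spec(),
                        weights = coef_as_vector(published_coefficients("LCRI_IL")),
                        rho = 0.5,
                        outcomes = list(incidence = c(65, 10),
                                        mortality = c(45, 8)),
                        seed = 1) {
  if (n_regions < 3L) stop("n_regions must be >= 3", call. = FALSE)
  if (any(spec$sd <= 0)) stop("factor sds must be positive", call. = FALSE)
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  missing_w <- setdiff(spec$factor_id, names(weights))
  if (length(missing_w) > 0L) {
    stop("weights lack factor(s): ", paste(missing_w, collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  regions <- data.frame(region_id = sprintf("region_%03d", seq_len(n_regions)))
  for (i in seq_len(nrow(spec))) {
    m <- spec$mean[i]; s <- spec$sd[i]
    x <- if (identical(spec$dist[i], "lognormal")) {
      sdlog <- sqrt(log(1 + s^2 / m^2))
      stats::rlnorm(n_regions, log(m) - sdlog^2 / 2, sdlog)
    } else {
      stats::rnorm(n_regions, m, s)
    }
    regions[[spec$factor_id[i]]] <- x
  }
  zmat <- scale(as.matrix(regions[, spec$factor_id]))
  w <- weights[spec$factor_id]
  composite <- as.vector(zmat %*% w)
  composite_z <- (composite - mean(composite)) / stats::sd(composite)
  for (oc in names(outcomes)) {
    ms <- outcomes[[oc]]
    noise <- stats::rnorm(n_regions)
    regions[[oc]] <- ms[1] + ms[2] * (rho * composite_z +
                                        sqrt(1 - rho^2) * noise)
  }
  list(regions = regions,
       truth = list(weights = as.list(w), rho = rho, seed = seed,
                    true_composite = composite,
                    true_composite_z = composite_z))
}

coef_as_vector <- function(coef) coef$weights

#' Write a complete synthetic analysis bundle
#'
#' Generates a study table and a region table from the same seed and writes
#' `studies.csv`, `regions.csv`, `truth.json` and a ready-to-run pipeline
#' `config.yaml` into `dir`. The config pools the four region factors from
#' the study CSV, derives weights with the given mapping, builds the z-score
#' index, and correlates it with both synthetic outcomes.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for both generators.
#' @param rho Planted composite-outcome correlation (default 0.5).
#' @param n_regions Number of regions (default 102).
#' @param map Comparison-matrix mapping written into the config.
#' @return Invisibly, the config (as a list) with resolved paths.
#' @export
synth_bundle <- function(dir, seed = 1, rho = 0.5, n_regions = 102,
                         map = "continuous_ratio") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  studies <- gen_studies(seed = seed)
  region_spec <- default_region_spec()
  gr <- gen_regions(n_regions = n_regions, spec = region_spec, rho = rho,
                    seed = seed + 1L)
  utils::write.csv(studies, file.path(dir, "studies.csv"), row.names = FALSE)
  utils::write.csv(gr$regions, file.path(dir, "regions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(gr$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  config <- list(
    factors = lapply(seq_len(nrow(region_spec)), function(i) {
      list(factor_id = region_spec$factor_id[i],
           column = region_spec$factor_id[i])
    }),
    studies_csv = file.path(dir, "studies.csv"),
    region_csv = file.path(dir, "regions.csv"),
    map = map,
    mode = "zscore",
    outcomes = c("incidence", "mortality"),
    seed = seed
  )
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  invisible(config)
}
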