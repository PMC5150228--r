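#' Configure an end-to-end pipeline run
#'
#' Bundles and validates the stage configurations for
#' \code{\link{run_pipeline}}: cohort generation, spectral trend model,
#' artifact model, preprocessing, and the measure set to model. Every stage
#' config is validated here, before any stage runs.
#'
#' @param cohort a \code{\link{cohort_config}}.
#' @param trend a \code{\link{spectral_trend_model}}.
#' @param artifact an \code{\link{artifact_model}}.
#' @param preprocess a \code{\link{preprocess_config}}.
#' @param measures band/feature names to model per channel.
#' @param seed global seed for the run.
#' @return a list of class \code{run_config}.
#' @export
run_config <- function(cohort = cohort_config(),
                       trend = spectral_trend_model(),
                       artifact = artifact_model(),
                       preprocess = preprocess_config(),
                       measures = c("delta", "theta", "alpha", "beta", "alpha_peak"),
                       seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(trend, "spectral_trend_model"),
            inherits(artifact, "artifact_model"),
            inherits(preprocess, "preprocess_config"))
  structure(list(cohort = cohort, trend = trend, artifact = artifact,
                 preprocess = preprocess, measures = measures,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Polynomial rolling hash (mod 2^31 - 1) of a character scalar, 8 hex digits.
fnv1a_hash <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

config_hash <- function(config) {
  flat <- unlist(config, use.names = TRUE)
  fnv1a_hash(paste(names(flat), format(flat, digits = 15), sep = "=", collapse = ";"))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full synthesis-to-regression pipeline
#'
#' Executes the four stages in order - synthesize and write a cohort,
#' preprocess it, extract per-user features, fit the age-trend models - with
#' every stage reading and writing files under \code{out_dir}, so stages
#' are independently inspectable. Rerunning with the same config and seed
#' reproduces every CSV output bit-identically.
#'
#' Outputs under \code{out_dir}: \code{data/} (raw session CSVs, manifest,
#' artifact ground truth), \code{pre/} (cleaned sessions and
#' \code{qc.csv}), \code{features.csv} (one row per user and task),
#' \code{tables/coefficients.csv} (per measure, channel and task: the six
#' coefficients, R^2, significance markers, and per-sex age terms when the
#' interaction refit triggered) and \code{metadata.json} (seed, config
#' hash, exclusion accounting, conventions).
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir run directory (created if needed).
#' @param seed overrides \code{config$seed} when given.
#' @return invisibly, a list with \code{qc}, \code{features},
#'   \code{coefficients} (the coefficient table), \code{fits} (the
#'   \code{age_trend_fit} objects, named measure.channel.task) and
#'   \code{metadata}.
#' @export
run_pipeline <- function(config, out_dir, seed = config$seed) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(out_dir, "data")
  pre_dir <- file.path(out_dir, "pre")

  profiles <- stage("synth", {
    p <- sample_cohort(config$cohort, config$trend, seed = seed)
    write_cohort(p, config$cohort, config$trend, config$artifact,
                 out_dir = data_dir, seed = seed + 1L)
    p
  })
  pre <- stage("preprocess",
    preprocess_cohort(file.path(data_dir, "manifest.csv"),
                      config$preprocess, out_dir = pre_dir))
  features <- stage("features",
    features_table(pre, dir = pre_dir,
                   out_file = file.path(out_dir, "features.csv")))

  tab <- stage("model", {
    dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
    fits <- list()
    rows <- list()
    for (task in unique(features$task)) {
      ft <- features[features$task == task, , drop = FALSE]
      specs <- list()
      for (m in config$measures) for (ch in eeg_channels)
        specs[[paste(m, ch, task, sep = ".")]] <-
          list(measure = m, channel = ch, col = paste(ch, m, sep = "_"))
      specs[[paste("alpha_asym", "AF8-AF7", task, sep = ".")]] <-
        list(measure = "alpha_asym", channel = "AF8-AF7", col = "asym_frontal")
      specs[[paste("alpha_asym", "TP10-TP9", task, sep = ".")]] <-
        list(measure = "alpha_asym", channel = "TP10-TP9",
             col = "asym_temporoparietal")
      for (key in names(specs)) {
        sp <- specs[[key]]
        if (!sp$col %in% names(ft)) next
        fit <- tryCatch(fit_age_trend(ft, sp$col), error = function(e) {
          warning("measure ", key, " not fitted: ", conditionMessage(e),
                  call. = FALSE)
          NULL
        })
        if (is.null(fit)) next
        fits[[key]] <- fit
        est <- coef(fit)
        stars <- stats::setNames(fit$coefficients$stars, fit$coefficients$term)
        row <- data.frame(
          measure = sp$measure, channel = sp$channel, task = task,
          intercept = est[["(Intercept)"]], age = est[["age_c"]],
          age2 = est[["age_c2"]], sex = est[["sex"]],
          age_sex = est[["age_c:sex"]], age2_sex = est[["age_c2:sex"]],
          r_squared = fit$r_squared,
          stars_intercept = stars[["(Intercept)"]], stars_age = stars[["age_c"]],
          stars_age2 = stars[["age_c2"]], stars_sex = stars[["sex"]],
          stars_age_sex = stars[["age_c:sex"]],
          stars_age2_sex = stars[["age_c2:sex"]],
          age_m = NA_real_, age_f = NA_real_,
          age2_m = NA_real_, age2_f = NA_real_,
          stringsAsFactors = FALSE)
        if (!is.null(fit$sex_fits)) {
          for (s in names(fit$sex_fits)) {
            sf <- fit$sex_fits[[s]]
            suffix <- if (s == "male") "m" else "f"
            row[[paste0("age_", suffix)]] <-
              sf$estimate[sf$term == "age_c"]
            row[[paste0("age2_", suffix)]] <-
              sf$estimate[sf$term == "age_c2"]
          }
        }
        rows[[key]] <- row
      }
    }
    coefficients <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(coefficients))
      stop("no measure could be fitted (too few (age, sex) cells)")
    utils::write.csv(coefficients,
                     file.path(out_dir, "tables", "coefficients.csv"),
                     row.names = FALSE)
    list(coefficients = coefficients, fits = fits)
  })

  metadata <- list(
    seed = seed,
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("eeglifespan")),
    n_users = nrow(profiles),
    n_excluded_underage = pre$n_excluded_underage,
    n_sessions = nrow(pre$qc),
    n_rejected_sessions = pre$n_rejected_sessions,
    n_rejected_pairs = pre$n_rejected_pairs,
    n_retained_sessions = sum(pre$qc$retained),
    power_threshold = config$preprocess$power_threshold,
    max_reject_frac = config$preprocess$max_reject_frac,
    max_sessions_per_user = config$preprocess$max_sessions_per_user,
    p_value_df = "cell-level residual degrees of freedom",
    star_thresholds = c(0.05, 0.01, 0.001, 0.0001)
  )
  jsonlite::write_json(metadata, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(qc = pre$qc, features = features,
                 coefficients = tab$coefficients, fits = tab$fits,
                 metadata = metadata))
}
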