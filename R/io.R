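#' Write a feature table to CSV with a provenance sidecar
#'
#' The CSV dialect: header row, UTF-8, `.` decimal separator; columns
#' `exam_id`, `batch_id`, `site`, `manufacturer`, `field_strength`, `age`,
#' `sex` first, then one column per feature. A YAML sidecar
#' (`<path>.provenance.yml`) records the seed and generation summary passed
#' via `provenance`.
#'
#' @param table A feature table.
#' @param path Output CSV path.
#' @param provenance Optional named list (seed, spec summary, ...) written to
#'   the sidecar; omit with `NULL`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, provenance = NULL) {
  ord <- c(intersect(META_COLS, names(table)), feature_columns(table))
  readr::write_csv(table[ord], path)
  if (!is.null(provenance)) {
    yaml::write_yaml(provenance, paste0(path, ".provenance.yml"))
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return A feature table tibble; metadata columns typed (age double, sex
#'   integer), every remaining column double. Feature order is preserved.
#' @export
read_feature_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta <- intersect(META_COLS, names(tab))
  if (!all(c("exam_id", "batch_id") %in% meta)) {
    abort("not a feature table CSV: exam_id/batch_id columns missing")
  }
  if ("sex" %in% meta) tab$sex <- as.integer(tab$sex)
  feats <- setdiff(names(tab), META_COLS)
  tab[feats] <- lapply(tab[feats], as.numeric)
  tab
}

#' Write the report tables of a study run
#'
#' Writes `summary.csv` (one row per family x experiment, the layout of the
#' study's report tables: experiment, controlled variable, significant
#' counts and mean/SD Cohen's F before and after harmonization), one
#' per-feature result CSV per family x experiment x stage, and a
#' `provenance.yml` with the run configuration and seed.
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$summary, file.path(dir, "summary.csv"))
  for (key in names(report$results)) {
    readr::write_csv(report$results[[key]]$original,
                     file.path(dir, paste0(key, "_original.csv")))
    readr::write_csv(report$results[[key]]$harmonized,
                     file.path(dir, paste0(key, "_harmonized.csv")))
  }
  cfg <- report$config
  yaml::write_yaml(
    list(seed = cfg$seed,
         feature_families = cfg$feature_families,
         effect_strength = cfg$effect_strength,
         combat_mode = cfg$combat_mode,
         covariates = cfg$covariates,
         alpha = cfg$alpha,
         tol = cfg$tol, max_iter = cfg$max_iter,
         designs = cfg$designs,
         n_exams = nrow(report$metadata)),
    file.path(dir, "provenance.yml")
  )
  invisible(dir)
}

#' Write a ComBat fit summary file
#'
#' Structured-text (YAML) summary of a fit: grand means, covariates,
#' per-batch EB hyperparameters and iteration counts, skipped features.
#'
#' @param fit A `combat_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_summary <- function(fit, path) {
  stopifnot(inherits(fit, "combat_fit"))
  yaml::write_yaml(
    list(mode = fit$mode,
         batches = as.list(stats::setNames(as.integer(fit$n_per_batch),
                                           fit$batch_levels)),
         covariates = fit$covariates,
         dropped_covariates = fit$dropped_covariates,
         n_features = length(fit$features),
         skipped_features = fit$features[fit$skipped],
         alpha_hat_range = range(fit$alpha_hat),
         priors = if (is.null(fit$priors)) NULL else
           lapply(split(fit$priors, seq_len(nrow(fit$priors))), as.list),
         iterations = if (is.null(fit$iterations)) NULL else
           as.list(fit$iterations),
         converged = if (is.null(fit$converged)) NULL else
           as.list(fit$converged)),
    path
  )
  invisible(path)
}
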