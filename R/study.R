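#' The six built-in experiment designs
#'
#' Experiments 1-3 compare field strengths (1.5T vs 3T) within one
#' manufacturer's site (Site 1 Siemens, Site 2 GE, Site 3 Philips; two
#' groups, t-test). Experiments 4-5 compare the three manufacturers at a
#' fixed field strength (1.5T, 3T; three groups, ANOVA). Experiment 6
#' compares all six (manufacturer x field strength) batches jointly.
#'
#' @param spec Cohort spec whose arms the designs subset; default cohort.
#' @return A tibble with one row per design: `experiment` (1-6),
#'   `non_biological_variation`, `controlled` (description of the held-fixed
#'   variable), `group_var` (column the tests group by), `arms` (list column
#'   of included batch ids).
#' @export
builtin_designs <- function(spec = default_cohort_spec()) {
  spec <- validate_cohort_spec(spec)
  arm <- function(...) {
    dplyr::filter(spec, ...)$batch_id
  }
  tibble::tibble(
    experiment = 1:6,
    non_biological_variation = c(rep("Field strengths (1.5T vs 3T)", 3),
                                 rep("System manufacturers (Siemens vs GE vs Philips)", 2),
                                 "Field strengths and manufacturers"),
    controlled = c("Site 1 (Siemens)", "Site 2 (GE)", "Site 3 (Philips)",
                   "1.5T", "3T", "N/A"),
    group_var = c(rep("field_strength", 3), rep("manufacturer", 2),
                  "batch_id"),
    arms = list(
      arm(.data$site == "Site 1"),
      arm(.data$site == "Site 2"),
      arm(.data$site == "Site 3"),
      arm(.data$field_strength == "1.5T"),
      arm(.data$field_strength == "3T"),
      spec$batch_id
    )
  )
}

#' Configuration for a full study run
#'
#' Collects every knob of [run_study()] with defaults replicating the study
#' conditions: the default six-arm cohort at full sample sizes, strong
#' injected batch effects, empirical-Bayes ComBat with age and sex
#' covariates, Bonferroni-adjusted significance at 0.05.
#'
#' @param cohort_spec Cohort spec tibble.
#' @param feature_families Families to run (subset of `"radiomic_172"`,
#'   `"liver_86"`, `"spleen_86"`, `"deep_1024"`).
#' @param effect_strength `"null"`, `"moderate"` or `"strong"`.
#' @param seed Integer master seed; recorded in every output artifact.
#' @param designs Which of the six experiments to run.
#' @param combat_mode `"eb"` or `"noeb"`.
#' @param covariates Covariates preserved by harmonization.
#' @param tol,max_iter ComBat EB convergence controls.
#' @param alpha Family-wise significance level.
#' @param out_dir Optional directory; when set, [run_study()] writes summary
#'   and per-feature CSVs plus a provenance sidecar there.
#' @return A list of class `run_config`.
#' @export
study_config <- function(cohort_spec = default_cohort_spec(),
                         feature_families = c("radiomic_172", "deep_1024"),
                         effect_strength = c("strong", "moderate", "null"),
                         seed = 1L,
                         designs = 1:6,
                         combat_mode = c("eb", "noeb"),
                         covariates = c("age", "sex"),
                         tol = 1e-6, max_iter = 100L,
                         alpha = 0.05,
                         out_dir = NULL) {
  families <- match.arg(feature_families,
                        c("radiomic_172", "liver_86", "spleen_86", "deep_1024"),
                        several.ok = TRUE)
  structure(
    list(cohort_spec = validate_cohort_spec(cohort_spec),
         feature_families = families,
         effect_strength = match.arg(effect_strength),
         seed = stopifnot_scalar_int(seed, "seed"),
         designs = designs,
         combat_mode = match.arg(combat_mode),
         covariates = covariates,
         tol = tol, max_iter = max_iter, alpha = alpha,
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the six-experiment harmonization study on synthetic data
#'
#' For each requested feature family: generates the cohort metadata once and
#' one feature table (family-specific ground truth and sub-seed), then for
#' each requested design subsets the included arms, evaluates the original
#' table, ComBat-harmonizes across the included batches (a fresh fit per
#' experiment), and evaluates the harmonized table. A failure in one
#' experiment is logged as a warning and the remaining experiments continue.
#'
#' @param config A `run_config` from [study_config()].
#' @return An object of class `study_report`: list with `summary` (one row
#'   per family x experiment: significant counts and mean/SD Cohen's F,
#'   original and harmonized), `results` (named list of per-feature result
#'   tibbles, original and harmonized), `tables` (the simulated feature
#'   table per family), `metadata`, `demographics`, and `config`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "run_config"))
  designs <- dplyr::filter(builtin_designs(config$cohort_spec),
                           .data$experiment %in% config$designs)
  metadata <- generate_metadata(config$cohort_spec, config$seed)
  demographics <- compare_demographics(metadata)
  summary_rows <- list()
  results <- list()
  tables <- list()
  for (fam_i in seq_along(config$feature_families)) {
    fam <- config$feature_families[fam_i]
    fam_seed <- (config$seed + 1000L * fam_i) %% .Machine$integer.max
    effects <- default_effect_spec(fam, config$effect_strength,
                                   seed = fam_seed,
                                   batches = config$cohort_spec$batch_id)
    tab <- simulate_features(metadata, effects, seed = fam_seed + 1L)
    tables[[fam]] <- tab
    for (d in seq_len(nrow(designs))) {
      des <- designs[d, ]
      key <- sprintf("%s_exp%d", fam, des$experiment)
      res <- tryCatch({
        sub <- dplyr::filter(tab, .data$batch_id %in% des$arms[[1]])
        orig <- evaluate_features(sub, group = des$group_var,
                                  alpha = config$alpha)
        harm <- combat_harmonize(sub, batch = "batch_id",
                                 covariates = config$covariates,
                                 mode = config$combat_mode,
                                 tol = config$tol,
                                 max_iter = config$max_iter)
        post <- evaluate_features(harm$table, group = des$group_var,
                                  alpha = config$alpha)
        list(original = orig, harmonized = post, fit = harm$fit)
      }, error = function(e) {
        warn(sprintf("experiment %d (%s) failed: %s",
                     des$experiment, fam, conditionMessage(e)))
        NULL
      })
      if (is.null(res)) next
      results[[key]] <- res
      so <- summarize_evaluation(res$original)
      sh <- summarize_evaluation(res$harmonized)
      summary_rows[[key]] <- tibble::tibble(
        family = fam,
        experiment = des$experiment,
        non_biological_variation = des$non_biological_variation,
        controlled = des$controlled,
        n_features = so$n_features,
        n_tested = so$n_tested,
        n_significant_original = so$n_significant,
        n_significant_harmonized = sh$n_significant,
        mean_cohens_f_original = so$mean_cohens_f,
        sd_cohens_f_original = so$sd_cohens_f,
        mean_cohens_f_harmonized = sh$mean_cohens_f,
        sd_cohens_f_harmonized = sh$sd_cohens_f
      )
    }
  }
  report <- structure(
    list(summary = purrr::list_rbind(summary_rows),
         results = results, tables = tables, metadata = metadata,
         demographics = demographics, config = config),
    class = "study_report"
  )
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Harmonization study report (seed ", x$config$seed, ", strength ",
      x$config$effect_strength, ", mode ", x$config$combat_mode, ")\n",
      sep = "")
  print(dplyr::select(
    x$summary, "family", "experiment", "controlled",
    "n_significant_original", "n_significant_harmonized",
    "mean_cohens_f_original", "mean_cohens_f_harmonized"
  ), n = Inf)
  invisible(x)
}

#' Tidy a study report into its summary table
#'
#' @param x A `study_report`.
#' @param ... Unused.
#' @return The summary tibble (one row per family x experiment).
#' @export
tidy.study_report <- function(x, ...) x$summary

#' One-row overview of a study report
#'
#' @param x A `study_report`.
#' @param ... Unused.
#' @return A tibble with run dimensions and the overall significant-count
#'   totals before and after harmonization.
#' @export
glance.study_report <- function(x, ...) {
  tibble::tibble(
    n_families = length(unique(x$summary$family)),
    n_experiments = length(unique(x$summary$experiment)),
    n_exams = nrow(x$metadata),
    seed = x$config$seed,
    effect_strength = x$config$effect_strength,
    combat_mode = x$config$combat_mode,
    total_significant_original = sum(x$summary$n_significant_original),
    total_significant_harmonized = sum(x$summary$n_significant_harmonized)
  )
}
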