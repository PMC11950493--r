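#' Default multi-center cohort specification
#'
#' Six scanner arms (batches) across three study sites, two MRI system
#' manufacturers per site and two field strengths (1.5T, 3T), with the sample
#' sizes, female counts and age moments of a large multi-center abdominal MRI
#' chronic-liver-disease cohort: 3857 exams in total, 2304 of them at Site 1.
#' The batch identifier is the (site, manufacturer, field strength) triple.
#'
#' Female fractions are stored as exact printed female counts divided by the
#' arm size, so exact-count sex assignment in [generate_metadata()] reproduces
#' the printed counts.
#'
#' @return A cohort spec: a tibble with one row per arm and columns
#'   `batch_id`, `site`, `manufacturer`, `field_strength`, `n_exams`,
#'   `female_fraction`, `age_mean`, `age_sd`.
#' @examples
#' spec <- default_cohort_spec()
#' sum(spec$n_exams) # 3857
#' @export
default_cohort_spec <- function() {
  spec <- tibble::tibble(
    site           = rep(c("Site 1", "Site 2", "Site 3"), each = 2),
    manufacturer   = rep(c("Siemens", "GE", "Philips"), each = 2),
    field_strength = rep(c("1.5T", "3T"), times = 3),
    n_exams        = c(1614L, 690L, 427L, 799L, 315L, 12L),
    female_fraction = c(837 / 1614, 364 / 690, 214 / 427,
                        402 / 799, 166 / 315, 0.5),
    age_mean       = c(53.6, 53.8, 50.7, 51.9, 54.9, 54.2),
    age_sd         = c(14.1, 13.4, 15.2, 15.5, 13.8, 14.9)
  )
  new_cohort_spec(spec)
}

new_cohort_spec <- function(spec) {
  spec <- dplyr::mutate(
    spec,
    batch_id = paste(gsub(" ", "", .data$site), .data$manufacturer,
                     .data$field_strength, sep = "-"),
    .before = 1L
  )
  validate_cohort_spec(spec)
}

#' Validate a cohort specification
#'
#' Checks arm-level invariants: non-negative sample sizes, female fractions in
#' \[0, 1\], non-negative age SDs, and uniqueness of the
#' (site, manufacturer, field strength) batch identifier.
#'
#' @param spec A cohort spec tibble (see [default_cohort_spec()]); the
#'   `batch_id` column is rebuilt if absent.
#' @return The validated spec (invisibly usable in pipes).
#' @export
validate_cohort_spec <- function(spec) {
  required <- c("site", "manufacturer", "field_strength", "n_exams",
                "female_fraction", "age_mean", "age_sd")
  missing <- setdiff(required, names(spec))
  if (length(missing) > 0) {
    abort(paste0("cohort spec is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (!"batch_id" %in% names(spec)) {
    return(new_cohort_spec(spec))
  }
  if (any(spec$n_exams < 0)) abort("n_exams must be >= 0 for every arm")
  if (any(spec$female_fraction < 0 | spec$female_fraction > 1)) {
    abort("female_fraction must lie in [0, 1]")
  }
  if (any(spec$age_sd < 0)) abort("age_sd must be >= 0")
  if (anyDuplicated(spec$batch_id)) {
    abort("batch identifiers (site, manufacturer, field_strength) must be unique")
  }
  spec
}

#' Generate exam-level metadata from a cohort specification
#'
#' Realizes a cohort spec into one row per MRI exam. Sex is assigned by exact
#' count -- `round(n_exams * female_fraction)` exams per arm are female
#' (coded 1; male 0) -- so female counts are deterministic, with the female
#' positions shuffled within the arm. Age is drawn from
#' Normal(`age_mean`, `age_sd`) truncated below at 18 years (adult cohort) by
#' rejection sampling. The same seed always yields identical output.
#'
#' @param spec A cohort spec tibble, see [default_cohort_spec()].
#' @param seed Integer seed; one seeded stream per call.
#' @return A tibble with columns `exam_id`, `batch_id`, `site`,
#'   `manufacturer`, `field_strength`, `age`, `sex`.
#' @examples
#' md <- generate_metadata(default_cohort_spec(), seed = 1)
#' nrow(md) # 3857
#' @export
generate_metadata <- function(spec, seed) {
  spec <- validate_cohort_spec(spec)
  seed <- stopifnot_scalar_int(seed, "seed")
  withr::with_seed(seed, {
    purrr::pmap(spec, function(batch_id, site, manufacturer, field_strength,
                               n_exams, female_fraction, age_mean, age_sd) {
      n <- as.integer(n_exams)
      if (n == 0L) return(NULL)
      n_female <- as.integer(round(n * female_fraction))
      sex <- integer(n)
      if (n_female > 0L) sex[sample.int(n, n_female)] <- 1L
      tibble::tibble(
        exam_id = sprintf("%s-e%05d", batch_id, seq_len(n)),
        batch_id = batch_id,
        site = site,
        manufacturer = manufacturer,
        field_strength = field_strength,
        age = rtruncnorm_lower(n, age_mean, age_sd, lower = 18),
        sex = sex
      )
    }) |> purrr::list_rbind()
  })
}

# Truncated-normal draw by rejection; exact and adequate for cohort ages
# (truncation point is ~2.5 SD below the mean for every default arm).
rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) {
    if (mean < lower) abort("degenerate age distribution below truncation point")
    return(rep(mean, n))
  }
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
  }
  out
}

#' Default simulation ground truth for a feature family
#'
#' Builds an effect spec -- the ground truth of the linear batch-effect model
#' \deqn{Y_{ijf} = \alpha_f + \gamma_{if} + X\beta_f + \delta_{if}\epsilon_{ijf}}
#' for one of the study's feature families: the 172 radiomic features per exam
#' (86 liver + 86 spleen), either 86-feature organ subset, or the 1024 deep
#' features.
#'
#' Baselines and covariate effects emulate mild biology: `alpha_f ~ N(0, 2)`,
#' `beta_age_f ~ N(0, 0.01)` per year, `beta_sex_f ~ N(0, 0.1)` (female = 1),
#' `noise_sd_f ~ U(0.5, 1.5)`. Batch effects are zero-centered across batches:
#' `gamma_if ~ N(0, s_g * noise_sd_f)` and `log delta_if ~ N(0, s_d)` with
#' `(s_g, s_d) = (0.5, 0.25)` for `"moderate"` and `(1, 0.5)` for `"strong"`;
#' `"null"` sets every `gamma_if = 0` and `delta_if = 1`.
#'
#' @param kind Feature family: `"radiomic_172"`, `"liver_86"`, `"spleen_86"`
#'   or `"deep_1024"`.
#' @param strength Batch-effect strength: `"null"`, `"moderate"` or `"strong"`.
#' @param seed Integer seed for the ground-truth draws.
#' @param batches Character vector of batch ids the effects are defined for;
#'   defaults to the six default cohort arms.
#' @return An object of class `effect_spec`: a list with `features` (tibble
#'   with `feature`, `alpha`, `beta_age`, `beta_sex`, `noise_sd`), `gamma` and
#'   `delta` (batches x features matrices), `bimodal` (named list, empty by
#'   default), and `kind`, `strength`, `seed`.
#' @examples
#' es <- default_effect_spec("radiomic_172", "null", seed = 1)
#' length(es$features$feature) # 172
#' @export
default_effect_spec <- function(kind = c("radiomic_172", "liver_86",
                                         "spleen_86", "deep_1024"),
                                strength = c("null", "moderate", "strong"),
                                seed,
                                batches = default_cohort_spec()$batch_id) {
  kind <- match.arg(kind)
  strength <- match.arg(strength)
  seed <- stopifnot_scalar_int(seed, "seed")
  feats <- switch(kind,
    liver_86  = sprintf("liver_f%03d", 1:86),
    spleen_86 = sprintf("spleen_f%03d", 1:86),
    radiomic_172 = c(sprintf("liver_f%03d", 1:86), sprintf("spleen_f%03d", 1:86)),
    deep_1024 = sprintf("deep_%04d", 1:1024)
  )
  p <- length(feats)
  nb <- length(batches)
  scales <- switch(strength,
    null     = c(gamma = 0,   logdelta = 0),
    moderate = c(gamma = 0.5, logdelta = 0.25),
    strong   = c(gamma = 1,   logdelta = 0.5)
  )
  withr::with_seed(seed, {
    features <- tibble::tibble(
      feature  = feats,
      alpha    = rnorm(p, 0, 2),
      beta_age = rnorm(p, 0, 0.01),
      beta_sex = rnorm(p, 0, 0.1),
      noise_sd = runif(p, 0.5, 1.5)
    )
    if (strength == "null") {
      gamma <- matrix(0, nb, p)
      delta <- matrix(1, nb, p)
    } else {
      gamma <- matrix(rnorm(nb * p), nb, p) *
        rep(scales[["gamma"]] * features$noise_sd, each = nb)
      delta <- exp(matrix(rnorm(nb * p, 0, scales[["logdelta"]]), nb, p))
    }
    dimnames(gamma) <- dimnames(delta) <- list(batches, feats)
    structure(
      list(features = features, gamma = gamma, delta = delta,
           bimodal = list(), kind = kind, strength = strength, seed = seed),
      class = "effect_spec"
    )
  })
}

#' Mark batches whose residual noise is a bimodal mixture
#'
#' Replaces the Gaussian residual of the stated batches with a two-component
#' normal mixture (in units of `noise_sd_f`), emulating feature distributions
#' with two prominent peaks occasionally seen on individual scanners.
#'
#' @param effects An `effect_spec`.
#' @param batch_ids Batches whose residual becomes the mixture.
#' @param means Component means (length 2), in residual SD units.
#' @param sds Component SDs (length 2), in residual SD units.
#' @param weights Mixture weights (length 2, summing to 1).
#' @return The modified `effect_spec`.
#' @export
set_bimodal_batches <- function(effects, batch_ids,
                                means = c(-1.5, 1.5), sds = c(0.5, 0.5),
                                weights = c(0.5, 0.5)) {
  stopifnot(inherits(effects, "effect_spec"),
            length(means) == 2, length(sds) == 2, length(weights) == 2,
            abs(sum(weights) - 1) < 1e-8)
  for (b in batch_ids) {
    effects$bimodal[[b]] <- list(means = means, sds = sds, weights = weights)
  }
  effects
}

validate_effect_spec <- function(effects, batch_ids) {
  if (!inherits(effects, "effect_spec")) abort("`effects` must be an effect_spec")
  if (any(effects$delta <= 0)) abort("delta_if must be > 0 everywhere")
  if (any(effects$features$noise_sd < 0)) abort("noise_sd_f must be >= 0")
  missing <- setdiff(batch_ids, rownames(effects$gamma))
  if (length(missing) > 0) {
    abort(paste0("effect spec has no batch effects for: ",
                 paste(missing, collapse = ", ")))
  }
  invisible(effects)
}

#' Simulate a feature table from exam metadata and an effect spec
#'
#' Computes the value matrix exactly from the linear batch-effect model
#' `Y = alpha_f + gamma_if + beta_age_f * age + beta_sex_f * sex +
#' delta_if * eps`, with `eps ~ N(0, noise_sd_f)` (or the stated two-component
#' mixture for batches flagged via [set_bimodal_batches()]). With
#' `noise_sd_f = 0` the output is the deterministic mean surface; identical
#' (metadata, effects, seed) yield a bit-identical table.
#'
#' @param metadata Exam metadata tibble from [generate_metadata()].
#' @param effects An `effect_spec` covering every batch in `metadata`.
#' @param seed Integer seed for the residual draws.
#' @return A feature table: the metadata columns followed by one numeric
#'   column per feature.
#' @export
simulate_features <- function(metadata, effects, seed) {
  validate_effect_spec(effects, unique(metadata$batch_id))
  seed <- stopifnot_scalar_int(seed, "seed")
  n <- nrow(metadata)
  ft <- effects$features
  p <- nrow(ft)
  bi <- match(metadata$batch_id, rownames(effects$gamma))
  withr::with_seed(seed, {
    eps <- matrix(rnorm(n * p), n, p)
    for (b in names(effects$bimodal)) {
      rows <- which(metadata$batch_id == b)
      if (length(rows) == 0) next
      mx <- effects$bimodal[[b]]
      comp <- sample.int(2L, length(rows) * p, replace = TRUE, prob = mx$weights)
      eps[rows, ] <- rnorm(length(rows) * p, mx$means[comp], mx$sds[comp])
    }
    eps <- eps * rep(ft$noise_sd, each = n)
    y <- rep(ft$alpha, each = n) +
      effects$gamma[bi, , drop = FALSE] +
      outer(metadata$age, ft$beta_age) +
      outer(as.numeric(metadata$sex), ft$beta_sex) +
      effects$delta[bi, , drop = FALSE] * eps
    colnames(y) <- ft$feature
    dplyr::bind_cols(metadata, tibble::as_tibble(y))
  })
}

#' Simulate a complete synthetic study table in one call
#'
#' Convenience wrapper: metadata from the cohort spec, then features from the
#' effect spec, with derived sub-seeds so the pair is reproducible from one
#' seed.
#'
#' @inheritParams generate_metadata
#' @inheritParams simulate_features
#' @return A feature table (see [simulate_features()]).
#' @export
simulate_study_table <- function(spec, effects, seed) {
  seed <- stopifnot_scalar_int(seed, "seed")
  md <- generate_metadata(spec, seed)
  simulate_features(md, effects, seed = (seed + 1L) %% .Machine$integer.max)
}
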