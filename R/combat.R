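#' Standardize a feature table for ComBat estimation
#'
#' First stage of ComBat: per feature, fits the location model by least
#' squares with one indicator per batch plus the covariates, constrains the
#' intercept `alpha_hat_f` to the batch-size-weighted grand mean of the batch
#' locations, and pools the residual variance `sigma2_hat_f` over all exams
#' (denominator N). The standardized matrix
#' `Z = (Y - alpha_hat - X beta_hat) / sigma_hat` removes only the grand mean
#' and covariate fit, so the batch location/scale structure stays in `Z` for
#' the empirical-Bayes stage.
#'
#' Covariate columns collinear with the batch indicators (or constant) are
#' dropped with a warning. Features with zero pooled variance are flagged as
#' skipped and their `Z` column set to 0.
#'
#' @param table A feature table (see [simulate_features()] for the layout).
#' @param batch Name of the batch column (default `"batch_id"`).
#' @param covariates Character vector of covariate column names preserved by
#'   harmonization; default age and sex.
#' @return A list with `Z` (exams x features matrix), `batch` (factor),
#'   `n_per_batch`, `alpha_hat`, `beta_hat` (covariates x features),
#'   `gamma0_hat` (batches x features raw-scale batch locations relative to
#'   the grand mean), `sigma2_hat`, `stand_mean` (exams x features),
#'   `covariates` (those retained), `dropped_covariates`, and `skipped`
#'   (logical per feature).
#' @export
combat_standardize <- function(table, batch = "batch_id",
                               covariates = c("age", "sex")) {
  if (!batch %in% names(table)) abort(sprintf("no column `%s` in table", batch))
  b <- factor(table[[batch]])
  if (nlevels(b) < 2) abort("ComBat needs at least 2 batch levels")
  n_i <- table(b)
  if (any(n_i < 2)) {
    abort(paste0("every batch needs >= 2 exams; too small: ",
                 paste(names(n_i)[n_i < 2], collapse = ", ")))
  }
  missing_cov <- setdiff(covariates, names(table))
  if (length(missing_cov) > 0) {
    abort(paste0("covariate columns not in table: ",
                 paste(missing_cov, collapse = ", ")))
  }
  y <- feature_matrix(table)
  n <- nrow(y)
  p <- ncol(y)
  d_batch <- stats::model.matrix(~ 0 + b)
  colnames(d_batch) <- levels(b)

  # drop covariates that add no rank beyond the batch indicators
  kept <- character(0)
  dropped <- character(0)
  design <- d_batch
  for (cv in covariates) {
    x <- as.numeric(table[[cv]])
    cand <- cbind(design, x)
    if (qr(cand)$rank > qr(design)$rank) {
      design <- cand
      colnames(design)[ncol(design)] <- cv
      kept <- c(kept, cv)
    } else {
      dropped <- c(dropped, cv)
    }
  }
  if (length(dropped) > 0) {
    warn(paste0("dropping covariate(s) collinear with batch (or constant): ",
                paste(dropped, collapse = ", ")))
  }

  bhat <- solve(crossprod(design), crossprod(design, y))
  w <- as.numeric(n_i) / n
  alpha_hat <- drop(w %*% bhat[seq_len(nlevels(b)), , drop = FALSE])
  gamma0_hat <- sweep(bhat[seq_len(nlevels(b)), , drop = FALSE], 2, alpha_hat)
  stand_mean <- matrix(alpha_hat, n, p, byrow = TRUE)
  if (length(kept) > 0) {
    xc <- design[, kept, drop = FALSE]
    stand_mean <- stand_mean + xc %*% bhat[kept, , drop = FALSE]
  }
  resid <- y - design %*% bhat
  sigma2_hat <- colMeans(resid^2)
  constant <- apply(y, 2, max) == apply(y, 2, min)
  skipped <- !is.finite(sigma2_hat) | sigma2_hat <= 0 | constant
  z <- (y - stand_mean) / rep(sqrt(ifelse(skipped, 1, sigma2_hat)), each = n)
  z[, skipped] <- 0
  list(
    Z = z, batch = b, n_per_batch = as.numeric(n_i),
    alpha_hat = stats::setNames(alpha_hat, colnames(y)),
    beta_hat = bhat[kept, , drop = FALSE],
    gamma0_hat = gamma0_hat,
    sigma2_hat = stats::setNames(sigma2_hat, colnames(y)),
    stand_mean = stand_mean,
    covariates = kept, dropped_covariates = dropped,
    skipped = stats::setNames(skipped, colnames(y))
  )
}

#' Per-batch location and scale of a standardized matrix
#'
#' Second stage of ComBat: per batch and feature, the within-batch mean
#' `gamma_hat_if` and the within-batch sample variance `delta2_hat_if`
#' (denominator `n_i - 1`) of the standardized values.
#'
#' @param Z Standardized matrix from [combat_standardize()].
#' @param batch Factor of batch labels, one per row of `Z`.
#' @return List with matrices `gamma_hat` and `delta2_hat`
#'   (batches x features).
#' @export
batch_moments <- function(Z, batch) {
  batch <- as.factor(batch)
  n_i <- as.numeric(table(batch))
  if (any(n_i < 2)) abort("every batch needs >= 2 rows for a sample variance")
  sums <- rowsum(Z, batch)
  gamma_hat <- sums / n_i
  # centred two-pass variance: stable even when Z is far from the origin
  centred <- Z - gamma_hat[as.integer(batch), , drop = FALSE]
  delta2_hat <- rowsum(centred^2, batch) / (n_i - 1)
  list(gamma_hat = gamma_hat, delta2_hat = delta2_hat)
}

#' Empirical-Bayes hyperpriors for the batch effects
#'
#' Third stage of ComBat: per batch, method-of-moments hyperparameters pooled
#' across features. The additive effects get a normal prior with moments
#' `gamma_bar_i` (across-feature mean of `gamma_hat_if`) and `tau2_bar_i`
#' (across-feature sample variance). The multiplicative effects get an
#' inverse-gamma prior on `delta2` with shape `lambda_i = (m^2 + 2v)/v` and
#' scale `theta_i = (m^3 + m v)/v` from the across-feature mean `m` and
#' variance `v` of `delta2_hat_if`. If `v = 0` (all batch variances
#' identical) the inverse-gamma moments are undefined; the batch is flagged
#' for no scale shrinkage with a warning.
#'
#' @param gamma_hat,delta2_hat Matrices from [batch_moments()].
#' @return A tibble with one row per batch: `batch`, `gamma_bar`, `tau2_bar`,
#'   `lambda`, `theta`, `shrink_delta` (logical).
#' @export
eb_priors <- function(gamma_hat, delta2_hat) {
  if (ncol(gamma_hat) < 2) {
    abort("empirical-Bayes pooling needs >= 2 features")
  }
  g_bar <- rowMeans(gamma_hat)
  t2_bar <- apply(gamma_hat, 1, var)
  m <- rowMeans(delta2_hat)
  v <- apply(delta2_hat, 1, var)
  ok <- is.finite(v) & v > 0
  if (any(!ok)) {
    warn(paste0("no across-feature variance in delta2_hat for batch(es) ",
                paste(rownames(gamma_hat)[!ok], collapse = ", "),
                "; scale estimates left unshrunk"))
  }
  tibble::tibble(
    batch = rownames(gamma_hat) %||% as.character(seq_along(g_bar)),
    gamma_bar = unname(g_bar),
    tau2_bar = unname(t2_bar),
    lambda = unname(ifelse(ok, (m^2 + 2 * v) / v, NA_real_)),
    theta = unname(ifelse(ok, (m^3 + m * v) / v, NA_real_)),
    shrink_delta = unname(ok)
  )
}

#' Empirical-Bayes shrinkage of batch-effect estimates
#'
#' Fourth stage of ComBat: iterates the standard conditional posterior means
#' until convergence. `gamma_star` is the precision-weighted combination of
#' `gamma_hat` (weight `n_i / delta2_star`) and the prior mean `gamma_bar`
#' (weight `1 / tau2_bar`); `delta2_star` is the inverse-gamma posterior mean
#' `(theta + 0.5 * sum_j (Z_ijf - gamma_star)^2) / (n_i/2 + lambda - 1)`
#' given the current `gamma_star`. Iteration stops when the maximum absolute
#' parameter change falls below `tol` or at `max_iter` (then a warning flag
#' is set, not an error).
#'
#' @param gamma_hat,delta2_hat Matrices from [batch_moments()].
#' @param priors Tibble from [eb_priors()].
#' @param Z Standardized matrix.
#' @param batch Factor of batch labels per row of `Z`.
#' @param tol Convergence tolerance on the maximum absolute change.
#' @param max_iter Iteration cap.
#' @return List with `gamma_star`, `delta2_star` (batches x features),
#'   `iterations` (per batch), `converged` (per batch logical).
#' @export
eb_shrink <- function(gamma_hat, delta2_hat, priors, Z, batch,
                      tol = 1e-6, max_iter = 100L) {
  if (any(!is.finite(priors$gamma_bar)) || any(!is.finite(priors$tau2_bar))) {
    abort("EB priors must be finite")
  }
  batch <- as.factor(batch)
  levels_b <- levels(batch)
  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  iterations <- stats::setNames(integer(length(levels_b)), levels_b)
  converged <- stats::setNames(logical(length(levels_b)), levels_b)
  for (i in seq_along(levels_b)) {
    zi <- Z[batch == levels_b[i], , drop = FALSE]
    n_i <- nrow(zi)
    pr <- priors[match(levels_b[i], priors$batch), ]
    g_hat <- gamma_hat[i, ]
    g_old <- g_hat
    d_old <- delta2_hat[i, ]
    it <- 0L
    conv <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      if (pr$tau2_bar <= 0) {
        g_new <- rep(pr$gamma_bar, length(g_hat))
      } else {
        g_new <- (pr$tau2_bar * n_i * g_hat + d_old * pr$gamma_bar) /
          (pr$tau2_bar * n_i + d_old)
      }
      if (isTRUE(pr$shrink_delta)) {
        sum2 <- colSums(sweep(zi, 2, g_new)^2)
        d_new <- (pr$theta + 0.5 * sum2) / (n_i / 2 + pr$lambda - 1)
      } else {
        d_new <- d_old
      }
      change <- max(abs(g_new - g_old), abs(d_new - d_old))
      g_old <- g_new
      d_old <- d_new
      if (change < tol) {
        conv <- TRUE
        break
      }
    }
    if (!conv) {
      warn(sprintf("EB iteration for batch %s hit max_iter = %d without converging",
                   levels_b[i], max_iter))
    }
    gamma_star[i, ] <- g_old
    delta2_star[i, ] <- d_old
    iterations[i] <- it
    converged[i] <- conv
  }
  list(gamma_star = gamma_star, delta2_star = delta2_star,
       iterations = iterations, converged = converged)
}

#' ComBat harmonization of a feature table
#'
#' Removes additive and multiplicative batch effects from an exams x features
#' table while preserving covariate (age, sex) effects:
#' \deqn{Y^*_{ijf} = \frac{Y_{ijf} - \hat\alpha_f - \hat\gamma_{if} -
#'   X\hat\beta_f}{\hat\delta_{if}} + \hat\alpha_f + X\hat\beta_f}
#' In mode `"eb"` (the default) the per-batch location/scale estimates are
#' replaced by their empirical-Bayes posterior means `gamma_star` /
#' `delta2_star` ([eb_shrink()]); mode `"noeb"` uses the raw within-batch
#' estimates directly (plain location-scale adjustment). The whole chain is
#' deterministic.
#'
#' Features with zero pooled residual variance, or zero within-batch variance
#' in any batch, cannot be scale-adjusted: they are passed through unchanged
#' and listed in `skipped_features` (with a warning), never a hard failure.
#'
#' @inheritParams combat_standardize
#' @param mode `"eb"` (empirical-Bayes, default) or `"noeb"`
#'   (location-scale only).
#' @param tol,max_iter Convergence controls for [eb_shrink()].
#' @return An object of class `combat_harmonized`: a list with `table` (the
#'   harmonized feature table, same shape and exam order as the input),
#'   `fit` (a `combat_fit`), and `skipped_features`.
#' @examples
#' spec <- default_cohort_spec()
#' spec$n_exams <- rep(30L, 6)
#' tab <- simulate_study_table(spec, default_effect_spec("liver_86", "strong", 1), 1)
#' h <- combat_harmonize(tab)
#' h$fit
#' @export
combat_harmonize <- function(table, batch = "batch_id",
                             covariates = c("age", "sex"),
                             mode = c("eb", "noeb"),
                             tol = 1e-6, max_iter = 100L) {
  mode <- match.arg(mode)
  std <- combat_standardize(table, batch = batch, covariates = covariates)
  mom <- batch_moments(std$Z, std$batch)
  skipped <- std$skipped | apply(mom$delta2_hat <= 0, 2, any)
  if (any(skipped)) {
    warn(paste0(sum(skipped), " feature(s) with degenerate variance passed",
                " through unharmonized: ",
                paste(utils::head(names(which(skipped)), 5), collapse = ", "),
                if (sum(skipped) > 5) ", ..." else ""))
  }
  keep <- which(!skipped)
  features <- names(std$alpha_hat)
  priors <- NULL
  iterations <- NULL
  converged <- NULL
  gamma_use <- mom$gamma_hat
  delta2_use <- mom$delta2_hat
  if (mode == "eb" && length(keep) > 0) {
    priors <- eb_priors(mom$gamma_hat[, keep, drop = FALSE],
                        mom$delta2_hat[, keep, drop = FALSE])
    eb <- eb_shrink(mom$gamma_hat[, keep, drop = FALSE],
                    mom$delta2_hat[, keep, drop = FALSE],
                    priors, std$Z[, keep, drop = FALSE], std$batch,
                    tol = tol, max_iter = max_iter)
    gamma_use[, keep] <- eb$gamma_star
    delta2_use[, keep] <- eb$delta2_star
    iterations <- eb$iterations
    converged <- eb$converged
  }

  out <- feature_matrix(table)
  if (length(keep) > 0) {
    bi <- as.integer(std$batch)
    n <- nrow(out)
    zk <- std$Z[, keep, drop = FALSE]
    adj <- (zk - gamma_use[bi, keep, drop = FALSE]) /
      sqrt(delta2_use[bi, keep, drop = FALSE])
    out[, keep] <- adj * rep(sqrt(std$sigma2_hat[keep]), each = n) +
      std$stand_mean[, keep, drop = FALSE]
  }
  tab_out <- table
  tab_out[features] <- tibble::as_tibble(out)

  fit <- structure(
    list(
      batch_levels = levels(std$batch),
      n_per_batch = stats::setNames(std$n_per_batch, levels(std$batch)),
      features = features,
      alpha_hat = std$alpha_hat,
      beta_hat = std$beta_hat,
      gamma0_hat = std$gamma0_hat,
      sigma2_hat = std$sigma2_hat,
      gamma_hat = mom$gamma_hat,
      delta2_hat = mom$delta2_hat,
      priors = priors,
      gamma_star = if (mode == "eb") gamma_use else NULL,
      delta2_star = if (mode == "eb") delta2_use else NULL,
      mode = mode,
      tol = tol, max_iter = max_iter,
      iterations = iterations, converged = converged,
      covariates = std$covariates,
      dropped_covariates = std$dropped_covariates,
      skipped = stats::setNames(skipped, features)
    ),
    class = "combat_fit"
  )
  structure(
    list(table = tab_out, fit = fit,
         skipped_features = features[skipped]),
    class = "combat_harmonized"
  )
}

#' @export
print.combat_fit <- function(x, ...) {
  cat("ComBat fit (mode: ", x$mode, ")\n", sep = "")
  cat("  batches:  ", length(x$batch_levels), " (",
      paste0(x$batch_levels, " n=", x$n_per_batch, collapse = "; "), ")\n",
      sep = "")
  cat("  features: ", length(x$features),
      " (", sum(x$skipped), " skipped)\n", sep = "")
  cat("  covariates preserved: ",
      if (length(x$covariates)) paste(x$covariates, collapse = ", ") else "none",
      "\n", sep = "")
  if (!is.null(x$iterations)) {
    cat("  EB iterations per batch: ",
        paste(x$iterations, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.combat_harmonized <- function(x, ...) {
  cat("Harmonized feature table: ", nrow(x$table), " exams x ",
      length(feature_columns(x$table)), " features\n", sep = "")
  print(x$fit)
  invisible(x)
}

#' Tidy a ComBat fit into one row per batch-feature pair
#'
#' @param x A `combat_fit`.
#' @param ... Unused.
#' @return A tibble with `batch`, `feature`, `gamma_hat`, `delta2_hat` and,
#'   in EB mode, `gamma_star`, `delta2_star`.
#' @export
tidy.combat_fit <- function(x, ...) {
  long <- function(m, nm) {
    tibble::tibble(
      batch = rep(rownames(m), times = ncol(m)),
      feature = rep(colnames(m), each = nrow(m)),
      !!nm := as.vector(m)
    )
  }
  out <- dplyr::left_join(long(x$gamma_hat, "gamma_hat"),
                          long(x$delta2_hat, "delta2_hat"),
                          by = c("batch", "feature"))
  if (!is.null(x$gamma_star)) {
    out <- out |>
      dplyr::left_join(long(x$gamma_star, "gamma_star"),
                       by = c("batch", "feature")) |>
      dplyr::left_join(long(x$delta2_star, "delta2_star"),
                       by = c("batch", "feature"))
  }
  out
}

#' One-row summary of a ComBat fit
#'
#' @param x A `combat_fit`.
#' @param ... Unused.
#' @return A tibble with batch/feature counts, mode, iteration total and
#'   convergence flag.
#' @export
glance.combat_fit <- function(x, ...) {
  tibble::tibble(
    n_batches = length(x$batch_levels),
    n_features = length(x$features),
    n_skipped = sum(x$skipped),
    mode = x$mode,
    iterations = if (is.null(x$iterations)) NA_integer_ else sum(x$iterations),
    converged = if (is.null(x$converged)) NA else all(x$converged)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
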