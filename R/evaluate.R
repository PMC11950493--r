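#' One-way fixed-effects ANOVA for a single feature
#'
#' Decomposes the total sum of squares about the grand mean into the
#' between-group `SS_effect` and within-group `SS_error`; the p-value comes
#' from the F distribution with `(k - 1, N - k)` degrees of freedom.
#'
#' Degenerate inputs are flagged rather than fatal: `SS_error = 0` with
#' between-group variation gives `p = 0` with `degenerate = TRUE`; all values
#' identical gives `skipped = TRUE` (no test). A design with `N <= k` (no
#' residual degrees of freedom) is an error.
#'
#' @param values Numeric vector of feature values.
#' @param groups Group labels, same length as `values`; `k >= 2` non-empty
#'   groups required.
#' @return A one-row tibble: `ss_effect`, `ss_error`, `df1`, `df2`,
#'   `statistic` (F), `p_value`, `degenerate`, `skipped`.
#' @examples
#' feature_anova(c(1, 2, 3, 3, 4, 5), rep(c("a", "b"), each = 3))
#' @export
feature_anova <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) abort("need at least 2 groups")
  n <- length(values)
  k <- nlevels(g)
  if (n <= k) abort("no residual degrees of freedom: need total n > k groups")
  gm <- mean(values)
  means <- tapply(values, g, mean)
  n_g <- tapply(values, g, length)
  ss_effect <- sum(n_g * (means - gm)^2)
  ss_error <- sum((values - means[g])^2)
  df1 <- k - 1
  df2 <- n - k
  if (ss_effect + ss_error <= 0) {
    return(tibble::tibble(ss_effect = 0, ss_error = 0, df1 = df1, df2 = df2,
                          statistic = NA_real_, p_value = NA_real_,
                          degenerate = TRUE, skipped = TRUE))
  }
  if (ss_error <= 0) {
    return(tibble::tibble(ss_effect = ss_effect, ss_error = 0,
                          df1 = df1, df2 = df2, statistic = Inf, p_value = 0,
                          degenerate = TRUE, skipped = FALSE))
  }
  f <- (ss_effect / df1) / (ss_error / df2)
  tibble::tibble(ss_effect = ss_effect, ss_error = ss_error,
                 df1 = df1, df2 = df2, statistic = f,
                 p_value = pf(f, df1, df2, lower.tail = FALSE),
                 degenerate = FALSE, skipped = FALSE)
}

#' Two-sided equal-variance (Student's) t-test for a single feature
#'
#' Routed through the same sums-of-squares machinery as [feature_anova()], so
#' `t^2 = F` holds exactly and the p-value agrees with the 2-group ANOVA to
#' machine precision.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return A one-row tibble: `estimate` (mean difference a - b), `statistic`
#'   (t), `df`, `p_value`, `ss_effect`, `ss_error`, `degenerate`, `skipped`.
#' @export
feature_ttest <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("both groups need n >= 2")
  }
  a <- feature_anova(c(group_a, group_b),
                     rep(c("a", "b"), c(length(group_a), length(group_b))))
  t_stat <- sign(mean(group_a) - mean(group_b)) * sqrt(a$statistic)
  tibble::tibble(estimate = mean(group_a) - mean(group_b),
                 statistic = t_stat, df = a$df2, p_value = a$p_value,
                 ss_effect = a$ss_effect, ss_error = a$ss_error,
                 degenerate = a$degenerate, skipped = a$skipped)
}

#' Partial eta-squared and Cohen's F from sums of squares
#'
#' Evaluates the effect-size formulas
#' `eta_p2 = SS_effect / (SS_effect + SS_error)` and
#' `Cohen's F = sqrt(eta_p2 / (1 - eta_p2))`. Vectorized. `SS_error = 0`
#' with positive `SS_effect` yields an infinite F flagged as degenerate
#' (callers exclude it from mean/SD summaries).
#'
#' @param ss_effect,ss_error Non-negative sums of squares (not both 0).
#' @return A tibble with `eta_p2`, `cohens_f`, `degenerate`.
#' @examples
#' cohens_f(6, 4) # eta_p2 = 0.6, F ~= 1.2247
#' @export
cohens_f <- function(ss_effect, ss_error) {
  if (any(ss_effect < 0) || any(ss_error < 0)) {
    abort("sums of squares must be >= 0")
  }
  if (any(ss_effect + ss_error == 0)) {
    abort("SS_effect and SS_error cannot both be 0")
  }
  eta <- ss_effect / (ss_effect + ss_error)
  tibble::tibble(
    eta_p2 = eta,
    cohens_f = ifelse(ss_error == 0 & ss_effect > 0, Inf,
                      sqrt(eta / (1 - eta))),
    degenerate = ss_error == 0 & ss_effect > 0
  )
}

#' Bonferroni family-wise correction
#'
#' `p_adjusted = min(1, m * p)` with `m = length(p_values)` (the number of
#' tested features in the family), via [stats::p.adjust()]. Significance is
#' declared at adjusted p below `alpha`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param alpha Family-wise significance level (default 0.05).
#' @return A tibble with `p_value`, `p_adjusted`, `significant`; zero rows
#'   for empty input.
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) {
    return(tibble::tibble(p_value = numeric(0), p_adjusted = numeric(0),
                          significant = logical(0)))
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "bonferroni")
  tibble::tibble(p_value = p_values, p_adjusted = adj,
                 significant = !is.na(adj) & adj < alpha)
}

#' Per-feature batch-difference tests across a feature table
#'
#' For every feature column, tests the null hypothesis of no difference in
#' the feature distribution between the groups defined by `group`: a
#' two-sided equal-variance t-test when there are exactly 2 groups, a one-way
#' ANOVA otherwise (the two coincide for 2 groups since `t^2 = F`). Effect
#' sizes (partial eta-squared, Cohen's F) come from the same sums of squares,
#' and the Bonferroni correction is applied across the table's tested
#' features (`m` = number of non-skipped features).
#'
#' Features with no variation at all, or with zero within-group variance
#' (infinite F), are flagged (`skipped` / `degenerate`) and excluded from the
#' correction family and from downstream count and mean/SD summaries.
#'
#' @param table A feature table.
#' @param group Name of the grouping column (default `"batch_id"`).
#' @param alpha Family-wise significance level.
#' @return A tibble with one row per feature: `feature`, `test` (`"t"` or
#'   `"anova"`), `ss_effect`, `ss_error`, `eta_p2`, `cohens_f`, `p_value`,
#'   `p_adjusted`, `significant`, `degenerate`, `skipped`.
#' @export
evaluate_features <- function(table, group = "batch_id", alpha = 0.05) {
  if (!group %in% names(table)) abort(sprintf("no column `%s` in table", group))
  g <- factor(table[[group]])
  g <- droplevels(g)
  if (nlevels(g) < 2) abort("grouping must yield >= 2 non-empty groups")
  y <- feature_matrix(table)
  n <- nrow(y)
  k <- nlevels(g)
  if (n <= k) abort("no residual degrees of freedom: need total n > k groups")
  n_g <- as.numeric(table(g))
  gm <- colMeans(y)
  yc <- y - rep(gm, each = n) # centred two-pass sums: numerically stable
  ss_total <- unname(colSums(yc^2))
  means_c <- rowsum(yc, g) / n_g
  ss_effect <- pmax(unname(colSums(means_c^2 * n_g)), 0)
  ss_error <- pmax(ss_total - ss_effect, 0)
  skipped <- ss_total <= .Machine$double.eps * n * pmax(gm^2, 1)
  degenerate <- !skipped &
    ss_error <= .Machine$double.eps * n * pmax(gm^2, 1)
  f <- (ss_effect / (k - 1)) / (ss_error / (n - k))
  p <- pf(f, k - 1, n - k, lower.tail = FALSE)
  p[degenerate] <- 0
  p[skipped] <- NA_real_
  eta <- ifelse(skipped, NA_real_, ss_effect / (ss_effect + ss_error))
  fx <- ifelse(degenerate, Inf, sqrt(eta / (1 - eta)))
  tested <- !skipped & !degenerate
  p_adj <- rep(NA_real_, length(p))
  signif <- rep(NA, length(p))
  if (any(tested)) {
    bf <- bonferroni(p[tested], alpha = alpha)
    p_adj[tested] <- bf$p_adjusted
    signif[tested] <- bf$significant
  }
  # degenerate features (zero within-group variance) are reported separately,
  # outside the correction family and the significant counts
  tibble::tibble(
    feature = colnames(y),
    test = if (k == 2) "t" else "anova",
    ss_effect = ifelse(skipped, NA_real_, ss_effect),
    ss_error = ifelse(skipped, NA_real_, ss_error),
    eta_p2 = eta,
    cohens_f = fx,
    p_value = p,
    p_adjusted = p_adj,
    significant = signif,
    degenerate = degenerate,
    skipped = skipped
  )
}

#' Summarize a per-feature evaluation into count and effect-size totals
#'
#' @param results Tibble from [evaluate_features()].
#' @return One-row tibble: `n_features`, `n_tested`, `n_significant`,
#'   `mean_cohens_f`, `sd_cohens_f` (mean/SD over tested, non-degenerate
#'   features).
#' @export
summarize_evaluation <- function(results) {
  tested <- dplyr::filter(results, !.data$skipped, !.data$degenerate)
  tibble::tibble(
    n_features = nrow(results),
    n_tested = nrow(tested),
    n_significant = sum(tested$significant),
    mean_cohens_f = mean(tested$cohens_f),
    sd_cohens_f = sd(tested$cohens_f)
  )
}

#' Compare cohort demographics across study sites
#'
#' Pearson chi-square (no continuity correction) on the site x sex
#' contingency table, and one-way ANOVA of age on site, mirroring the usual
#' cohort-description tests of a multi-center study. Sites with zero exams
#' are excluded with a warning.
#'
#' @param metadata Exam metadata tibble (needs `age`, `sex` and the site
#'   column).
#' @param site Name of the site column (default `"site"`).
#' @return One-row tibble: `chi2_sex`, `p_sex`, `f_age`, `p_age`,
#'   `ss_effect_age`, `ss_error_age`.
#' @export
compare_demographics <- function(metadata, site = "site") {
  s <- metadata[[site]]
  if (!is.factor(s)) s <- factor(s)
  empty <- levels(s)[tabulate(s, nlevels(s)) == 0]
  if (length(empty) > 0) {
    warn(paste0("excluding site(s) with zero exams: ",
                paste(empty, collapse = ", ")))
    s <- droplevels(s)
  }
  if (nlevels(s) < 2) abort("need >= 2 sites")
  tab <- table(s, metadata$sex)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  av <- feature_anova(metadata$age, s)
  tibble::tibble(
    chi2_sex = unname(chi$statistic),
    p_sex = unname(chi$p.value),
    f_age = av$statistic,
    p_age = if (isTRUE(av$skipped)) NA_real_ else av$p_value,
    ss_effect_age = av$ss_effect,
    ss_error_age = av$ss_error
  )
}
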