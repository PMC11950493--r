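#' Z-score matrix for heatmap export
#'
#' Per feature, subtracts the overall mean and divides by the overall SD
#' (denominator N - 1), the normalization used for feature heatmaps; rows are
#' reordered by batch then exam id so exams from one scanner group are
#' contiguous. Zero-SD features become all-zero columns and are listed in the
#' `"flagged"` attribute.
#'
#' @param table A feature table with >= 2 exams.
#' @return A tibble `exam_id`, `batch_id`, then one z-scored column per
#'   feature, with attribute `flagged` (character vector of zero-SD
#'   features).
#' @export
zscore_matrix <- function(table) {
  if (nrow(table) < 2) abort("need >= 2 exams to z-score")
  table <- dplyr::arrange(table, .data$batch_id, .data$exam_id)
  y <- feature_matrix(table)
  mu <- colMeans(y)
  s <- apply(y, 2, sd)
  flagged <- colnames(y)[!is.finite(s) | s == 0]
  s[!is.finite(s) | s == 0] <- 1
  z <- sweep(sweep(y, 2, mu), 2, s, "/")
  z[, flagged] <- 0
  out <- dplyr::bind_cols(table[c("exam_id", "batch_id")],
                          tibble::as_tibble(z))
  attr(out, "flagged") <- flagged
  out
}

#' Per-group kernel density curves for a feature
#'
#' Gaussian-kernel density estimates on one shared grid so group
#' distributions can be overlaid: the grid spans the pooled min-max padded by
#' 3 bandwidths, the bandwidth is Silverman's rule of thumb
#' ([stats::bw.nrd0()]) per group, and each curve integrates to 1 within
#' about 1e-3 (trapezoidal). Groups with degenerate (zero) variance cannot be
#' smoothed: their curve is omitted with a warning and the group listed in
#' the `"omitted"` attribute.
#'
#' @param table A feature table.
#' @param feature Name of the feature column to estimate.
#' @param group Name of the grouping column (default `"batch_id"`); each
#'   group needs n >= 2.
#' @param grid_size Number of grid points (default 512).
#' @return A long tibble `x` (grid value), `group`, `density`, with
#'   attributes `bandwidths` (named per group) and `omitted`.
#' @export
kde_curves <- function(table, feature, group = "batch_id", grid_size = 512L) {
  if (!feature %in% names(table)) {
    abort(sprintf("no feature `%s` in table", feature))
  }
  g <- factor(table[[group]])
  x <- as.numeric(table[[feature]])
  splits <- split(x, g)
  if (any(lengths(splits) < 2)) abort("every group needs n >= 2")
  bw <- purrr::map_dbl(splits, function(v) {
    if (sd(v) == 0) NA_real_ else stats::bw.nrd0(v)
  })
  omitted <- names(bw)[is.na(bw)]
  if (length(omitted) > 0) {
    warn(paste0("omitting degenerate (zero-variance) group(s): ",
                paste(omitted, collapse = ", ")))
  }
  ok <- names(bw)[!is.na(bw)]
  if (length(ok) == 0) abort("no group with positive variance")
  pad <- 3 * max(bw, na.rm = TRUE)
  lo <- min(x) - pad
  hi <- max(x) + pad
  out <- purrr::map(ok, function(gr) {
    d <- stats::density(splits[[gr]], bw = bw[[gr]], kernel = "gaussian",
                        from = lo, to = hi, n = grid_size)
    tibble::tibble(x = d$x, group = gr, density = d$y)
  }) |> purrr::list_rbind()
  attr(out, "bandwidths") <- bw[ok]
  attr(out, "omitted") <- omitted
  out
}
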