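#' @importFrom rlang .data abort warn %||% :=
#' @importFrom stats pf pchisq rnorm runif var sd setNames
NULL

# Metadata columns of a feature table, in canonical CSV order.
META_COLS <- c("exam_id", "batch_id", "site", "manufacturer",
               "field_strength", "age", "sex")

#' Names of the feature columns of a feature table
#'
#' A feature table is a tibble whose first columns are the exam metadata
#' (`exam_id`, `batch_id`, `site`, `manufacturer`, `field_strength`, `age`,
#' `sex`) and whose remaining columns are one numeric column per feature.
#'
#' @param table A feature table (tibble).
#' @return Character vector of feature column names, in table order.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), META_COLS)
}

# Extract the numeric feature matrix (exams x features) from a feature table.
feature_matrix <- function(table, features = feature_columns(table)) {
  m <- as.matrix(table[features])
  if (!is.numeric(m)) {
    abort("feature columns must be numeric")
  }
  storage.mode(m) <- "double"
  rownames(m) <- table$exam_id
  m
}

stopifnot_scalar_int <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != trunc(x)) {
    abort(sprintf("`%s` must be a single integer", name))
  }
  as.integer(x)
}
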