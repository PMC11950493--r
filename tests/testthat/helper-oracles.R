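# Fixture builders and independent brute-force oracles used across the suite.
# The oracles deliberately share no code with the package: explicit loops and
# direct normal-equation solves only.

# A minimal feature table from a batch-label vector and a value matrix.
make_table <- function(batch, y, age = NULL, sex = NULL) {
  n <- length(batch)
  if (is.null(dim(y))) y <- matrix(y, ncol = 1, dimnames = list(NULL, "f1"))
  if (is.null(colnames(y))) colnames(y) <- paste0("f", seq_len(ncol(y)))
  tibble::tibble(
    exam_id = sprintf("e%04d", seq_len(n)),
    batch_id = as.character(batch),
    site = "s",
    manufacturer = "m",
    field_strength = "1.5T",
    age = age %||% rep(50, n),
    sex = sex %||% rep_len(c(0L, 1L), n)
  ) |>
    dplyr::bind_cols(tibble::as_tibble(y))
}

fmat <- function(table) as.matrix(table[feature_columns(table)])

# Random small table with batch effects, for property-style loops.
random_table <- function(n_batches = 3, n_features = 5, n_per_batch = 10,
                         with_covariates = TRUE) {
  batch <- rep(LETTERS[seq_len(n_batches)], each = n_per_batch)
  n <- length(batch)
  age <- runif(n, 25, 75)
  sex <- as.integer(runif(n) < 0.5)
  y <- matrix(rnorm(n * n_features, 0, 1), n, n_features)
  for (b in seq_len(n_batches)) {
    rows <- batch == LETTERS[b]
    y[rows, ] <- sweep(y[rows, , drop = FALSE], 2, rnorm(n_features, 0, 1), "+")
    y[rows, ] <- sweep(y[rows, , drop = FALSE], 2,
                       exp(rnorm(n_features, 0, 0.3)), "*")
  }
  if (with_covariates) {
    y <- y + outer(age, rnorm(n_features, 0, 0.02)) +
      outer(sex, rnorm(n_features, 0, 0.3))
  }
  make_table(batch, y, age = age, sex = sex)
}

# Brute-force location-scale (no-EB) ComBat: explicit per-feature loops,
# direct least squares via solve() on the normal equations.
oracle_combat_noeb <- function(table, covariates = c("age", "sex")) {
  batch <- as.character(table$batch_id)
  levels_b <- sort(unique(batch))
  y <- fmat(table)
  n <- nrow(y)
  d <- matrix(0, n, length(levels_b))
  for (i in seq_along(levels_b)) d[batch == levels_b[i], i] <- 1
  for (cv in covariates) d <- cbind(d, as.numeric(table[[cv]]))
  out <- y
  for (f in seq_len(ncol(y))) {
    b <- solve(t(d) %*% d, t(d) %*% y[, f])
    batch_locs <- b[seq_along(levels_b)]
    alpha <- 0
    for (i in seq_along(levels_b)) {
      alpha <- alpha + sum(batch == levels_b[i]) / n * batch_locs[i]
    }
    fitted_cov <- rep(0, n)
    if (length(covariates) > 0) {
      for (ci in seq_along(covariates)) {
        fitted_cov <- fitted_cov +
          as.numeric(table[[covariates[ci]]]) * b[length(levels_b) + ci]
      }
    }
    resid <- y[, f] - d %*% b
    sigma2 <- sum(resid^2) / n
    z <- (y[, f] - alpha - fitted_cov) / sqrt(sigma2)
    for (i in seq_along(levels_b)) {
      rows <- which(batch == levels_b[i])
      g <- mean(z[rows])
      d2 <- sum((z[rows] - g)^2) / (length(rows) - 1)
      out[rows, f] <- (z[rows] - g) / sqrt(d2) * sqrt(sigma2) +
        alpha + fitted_cov[rows]
    }
  }
  out
}

# Brute-force one-way ANOVA sums of squares, explicit loops.
oracle_anova <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  ss_effect <- 0
  ss_error <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ss_effect <- ss_effect + length(v) * (mean(v) - gm)^2
    ss_error <- ss_error + sum((v - mean(v))^2)
  }
  k <- length(unique(groups))
  n <- length(values)
  f <- (ss_effect / (k - 1)) / (ss_error / (n - k))
  list(ss_effect = ss_effect, ss_error = ss_error,
       p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# Small-cohort spec: default batch structure at reduced arm sizes so property
# tests run in seconds.
scaled_cohort_spec <- function(n_per_arm = 40L) {
  spec <- default_cohort_spec()
  spec$n_exams <- rep(as.integer(n_per_arm), nrow(spec))
  spec
}
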