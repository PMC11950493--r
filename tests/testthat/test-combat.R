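test_that("standardization solves the constrained location model", {
  # two symmetric batches: grand mean 1, no batch location difference
  tab <- make_table(rep(c("A", "B"), each = 2), c(0, 2, 0, 2))
  std <- combat_standardize(tab, covariates = character(0))
  expect_equal(unname(std$alpha_hat), 1)
  expect_equal(unname(std$gamma0_hat[, 1]), c(0, 0))

  # hand-solved example: A={1,2,3}, B={4,5,6}
  tab2 <- make_table(rep(c("A", "B"), each = 3), 1:6)
  std2 <- combat_standardize(tab2, covariates = character(0))
  expect_equal(unname(std2$alpha_hat), 3.5)
  expect_equal(unname(std2$sigma2_hat), 2 / 3)

  # injected covariate coefficient recovered exactly without noise
  age <- c(30, 40, 50, 35, 45, 55)
  y <- 1 + 0.1 * age + rep(c(0, 2), each = 3)
  tab3 <- make_table(rep(c("A", "B"), each = 3), y, age = age)
  std3 <- combat_standardize(tab3, covariates = "age")
  expect_equal(unname(std3$beta_hat["age", 1]), 0.1, tolerance = 1e-12)
})

test_that("standardization rejects degenerate designs and drops collinear covariates", {
  tab <- make_table(rep("A", 4), rnorm(4))
  expect_error(combat_standardize(tab), "2 batch")
  tab2 <- make_table(c("A", "B", "B", "B"), rnorm(4))
  expect_error(combat_standardize(tab2), ">= 2 exams")
  # constant covariate is collinear with the batch indicators
  tab3 <- make_table(rep(c("A", "B"), each = 3), rnorm(6), age = rep(50, 6))
  expect_warning(std <- combat_standardize(tab3, covariates = c("age", "sex")),
                 "age")
  expect_equal(std$covariates, "sex")
  expect_equal(std$dropped_covariates, "age")
})

test_that("batch moments are the within-batch mean and n-1 variance", {
  z <- matrix(c(-1, 1, -1, 1), ncol = 1)
  mom <- batch_moments(z, rep(c("A", "B"), each = 2))
  expect_equal(unname(mom$gamma_hat[, 1]), c(0, 0))
  expect_equal(unname(mom$delta2_hat[, 1]), c(2, 2))

  tab <- make_table(rep(c("A", "B"), each = 3), 1:6)
  std <- combat_standardize(tab, covariates = character(0))
  mom2 <- batch_moments(std$Z, std$batch)
  expect_equal(unname(mom2$delta2_hat[, 1]), c(1.5, 1.5))
  expect_error(batch_moments(z, c("A", "A", "A", "B")), ">= 2")
})

test_that("EB hyperpriors follow the stated method-of-moments formulas", {
  # delta2 across features with m = 1, v = 0.5 -> lambda = 4, theta = 3
  d2 <- matrix(c(1 - sqrt(0.5 / 2) * sqrt(2), 1 + sqrt(0.5 / 2) * sqrt(2)),
               nrow = 1)
  # simpler: pick two values with mean 1 and sample variance 0.5
  d2 <- matrix(c(0.5, 1.5), nrow = 1)
  g <- matrix(c(0, 2), nrow = 1)
  rownames(d2) <- rownames(g) <- "A"
  pr <- eb_priors(g, d2)
  expect_equal(pr$gamma_bar, 1)
  expect_equal(pr$tau2_bar, 2) # sample variance, n - 1
  expect_equal(pr$lambda, (1 + 2 * 0.5) / 0.5)
  expect_equal(pr$theta, (1 + 0.5) / 0.5)

  # all gamma_hat equal -> zero prior variance
  g2 <- matrix(3, 1, 4, dimnames = list("A", NULL))
  d22 <- matrix(c(1, 2, 1.5, 0.5), 1, 4, dimnames = list("A", NULL))
  pr2 <- eb_priors(g2, d22)
  expect_equal(pr2$gamma_bar, 3)
  expect_equal(pr2$tau2_bar, 0)

  # identical batch variances -> scale shrinkage disabled with a warning
  d23 <- matrix(1, 1, 4, dimnames = list("A", NULL))
  expect_warning(pr3 <- eb_priors(g2, d23), "unshrunk")
  expect_false(pr3$shrink_delta)
  expect_error(eb_priors(matrix(1, 1, 1), matrix(1, 1, 1)), "2 features")
})

test_that("EB shrinkage respects its limiting cases and convex ordering", {
  withr::local_seed(11)
  tab <- random_table(n_batches = 3, n_features = 20, n_per_batch = 15)
  std <- combat_standardize(tab)
  mom <- batch_moments(std$Z, std$batch)
  pr <- eb_priors(mom$gamma_hat, mom$delta2_hat)

  # tau2 = 0 forces full shrinkage to the prior mean
  pr0 <- pr
  pr0$tau2_bar <- 0
  eb0 <- eb_shrink(mom$gamma_hat, mom$delta2_hat, pr0, std$Z, std$batch)
  for (i in 1:3) {
    expect_true(all(abs(eb0$gamma_star[i, ] - pr0$gamma_bar[i]) < 1e-12))
  }

  # huge tau2: essentially no shrinkage
  prInf <- pr
  prInf$tau2_bar <- rep(1e6, 3)
  ebInf <- eb_shrink(mom$gamma_hat, mom$delta2_hat, prInf, std$Z, std$batch)
  expect_true(max(abs(ebInf$gamma_star - mom$gamma_hat)) < 1e-3)

  # convex-combination ordering for every batch and feature
  eb <- eb_shrink(mom$gamma_hat, mom$delta2_hat, pr, std$Z, std$batch)
  for (i in 1:3) {
    lo <- pmin(mom$gamma_hat[i, ], pr$gamma_bar[i])
    hi <- pmax(mom$gamma_hat[i, ], pr$gamma_bar[i])
    expect_true(all(eb$gamma_star[i, ] >= lo - 1e-12))
    expect_true(all(eb$gamma_star[i, ] <= hi + 1e-12))
  }
  expect_true(all(eb$delta2_star > 0))
  expect_true(all(eb$converged))
  expect_true(all(eb$iterations >= 1))

  # max_iter exhaustion warns (once per batch) but still returns values
  w <- testthat::capture_warnings(
    eb1 <- eb_shrink(mom$gamma_hat, mom$delta2_hat, pr, std$Z, std$batch,
                     tol = 0, max_iter = 3L)
  )
  expect_true(all(grepl("max_iter", w)))
  expect_false(any(eb1$converged))
})

test_that("location-scale harmonization matches the closed-form worked example", {
  tab <- make_table(rep(c("A", "B"), each = 3), 1:6)
  h <- combat_harmonize(tab, covariates = character(0), mode = "noeb")
  # standardized batch values rescaled to unit batch variance:
  # offsets +/- sigma = sqrt(2/3) about the grand mean 3.5
  expect_equal(fmat(h$table)[, 1],
               rep(3.5 + c(-1, 0, 1) * sqrt(2 / 3), 2),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(fmat(h$table)[1:3, 1]), c(2.683, 3.500, 4.317),
               tolerance = 1e-3)
})

test_that("noeb harmonization equals the brute-force oracle on random tables", {
  withr::local_seed(202)
  for (rep_i in 1:8) {
    tab <- random_table(n_batches = 3, n_features = 5, n_per_batch = 10)
    h <- combat_harmonize(tab, mode = "noeb")
    expect_lt(max(abs(fmat(h$table) - oracle_combat_noeb(tab))), 1e-10)
    # and without covariates
    h0 <- combat_harmonize(tab, covariates = character(0), mode = "noeb")
    expect_lt(max(abs(fmat(h0$table) -
                        oracle_combat_noeb(tab, covariates = character(0)))),
              1e-10)
  }
})

test_that("harmonization removes batch moments and approaches identity on clean data", {
  withr::local_seed(31)
  tab <- random_table(n_batches = 3, n_features = 6, n_per_batch = 40,
                      with_covariates = FALSE)
  h <- combat_harmonize(tab, covariates = character(0), mode = "noeb")
  y <- fmat(h$table)
  b <- h$table$batch_id
  # refit the location model on harmonized data: per-batch residual means 0,
  # equal residual variances across batches
  resid_var <- numeric(0)
  for (bb in unique(b)) {
    r <- sweep(y[b == bb, , drop = FALSE], 2,
               colMeans(y[b == bb, , drop = FALSE]))
    expect_lt(max(abs(colMeans(r))), 1e-8)
    resid_var <- rbind(resid_var, apply(y[b == bb, , drop = FALSE], 2, var))
  }
  expect_lt(max(abs(resid_var[1, ] - resid_var[2, ])), 1e-8)
  expect_lt(max(abs(resid_var[1, ] - resid_var[3, ])), 1e-8)

  # a second pass only rescales the centred part by sqrt((N-k)/N); at large N
  # repeated harmonization converges to a fixed point
  n <- 3 * 1000
  tab_big <- random_table(n_batches = 3, n_features = 4, n_per_batch = 1000,
                          with_covariates = FALSE)
  h1 <- combat_harmonize(tab_big, covariates = character(0), mode = "noeb")
  h2 <- combat_harmonize(h1$table, covariates = character(0), mode = "noeb")
  centred <- abs(sweep(fmat(h1$table), 2, colMeans(fmat(h1$table))))
  expect_lt(max(abs(fmat(h2$table) - fmat(h1$table))),
            (1 - sqrt((n - 3) / n)) * max(centred) * 1.05 + 1e-10)

  # batch-effect-free symmetric batches pass through almost unchanged at
  # moderate n (exactly so in the large-n limit)
  sym <- make_table(rep(c("A", "B"), each = 200), rep(rnorm(200, 0, 1), 2))
  hs <- combat_harmonize(sym, covariates = character(0), mode = "noeb")
  expect_lt(max(abs(fmat(hs$table) - fmat(sym))),
            0.02 * max(abs(fmat(sym))))
})

test_that("covariate effects survive harmonization in the zero-noise limit", {
  withr::local_seed(77)
  n <- 120
  batch <- rep(c("A", "B", "C"), each = n / 3)
  age <- runif(n, 20, 80)
  sex <- as.integer(runif(n) < 0.5)
  b_true <- c(0.1, -0.05, 0.02)
  y <- sapply(b_true, function(b) {
    2 + b * age + 0.3 * sex + c(A = -1, B = 0.5, C = 2)[batch] +
      exp(c(A = 0.3, B = 0, C = -0.2)[batch]) * rnorm(n, 0, 1e-8)
  })
  tab <- make_table(batch, y, age = age, sex = sex)
  for (mode in c("noeb", "eb")) {
    h <- combat_harmonize(tab, mode = mode)
    for (f in 1:3) {
      fit <- stats::lm(fmat(h$table)[, f] ~ age + sex)
      expect_equal(unname(stats::coef(fit)["age"]), b_true[f],
                   tolerance = 1e-6)
    }
  }
})

test_that("zero-variance features are passed through and listed, not fatal", {
  withr::local_seed(5)
  tab <- random_table(n_batches = 2, n_features = 3, n_per_batch = 6)
  tab$f2 <- 7 # exactly constant
  expect_warning(h <- combat_harmonize(tab, mode = "noeb"), "degenerate")
  expect_equal(h$skipped_features, "f2")
  expect_equal(fmat(h$table)[, "f2"], fmat(tab)[, "f2"])
  expect_false(identical(fmat(h$table)[, "f1"], fmat(tab)[, "f1"]))
})

test_that("EB harmonization agrees with the reference sva implementation", {
  skip_if_not_installed("sva")
  withr::local_seed(404)
  tab <- random_table(n_batches = 3, n_features = 10, n_per_batch = 20)
  h <- combat_harmonize(tab, mode = "eb")
  mod <- stats::model.matrix(~ age + sex, data = tab)
  ref <- suppressMessages(t(sva::ComBat(dat = t(fmat(tab)),
                                        batch = tab$batch_id, mod = mod,
                                        par.prior = TRUE)))
  expect_lt(max(abs(fmat(h$table) - ref)), 1e-4)
})

test_that("combat fit tidiers expose the estimates", {
  withr::local_seed(6)
  tab <- random_table(n_batches = 2, n_features = 4, n_per_batch = 8)
  h <- combat_harmonize(tab, mode = "eb")
  td <- tidy(h$fit)
  expect_equal(nrow(td), 2 * 4)
  expect_true(all(c("gamma_hat", "delta2_hat", "gamma_star", "delta2_star")
                  %in% names(td)))
  expect_true(all(td$delta2_star > 0))
  gl <- glance(h$fit)
  expect_equal(gl$n_batches, 2)
  expect_equal(gl$n_features, 4)
  expect_true(gl$converged)
})
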