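Package: combatfx
Title: ComBat Harmonization and Batch-Effect Evaluation for Multi-Center
    Imaging Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric empirical-Bayes ComBat harmonization of multi-center
    imaging feature tables (exams by features, e.g. radiomic or deep features
    from abdominal MRI) across scanner batches defined by manufacturer and
    field strength, preserving age and sex covariate effects. Includes a
    per-feature batch-effect evaluation framework (equal-variance t-test and
    one-way ANOVA, partial eta-squared and Cohen's F effect sizes, Bonferroni
    family-wise correction), a synthetic multi-center cohort generator with
    injected additive and multiplicative batch effects, a six-experiment
    study-design runner, and export helpers for z-score heatmap matrices and
    kernel density grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
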