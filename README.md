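# combatfx

Batch-effect harmonization and evaluation for multi-center imaging feature
tables.

Pooling quantitative image features (radiomic descriptors, deep-network
feature vectors) across MRI scanners introduces non-biological variation —
batch effects — along the manufacturer and field-strength axes. `combatfx`
implements parametric empirical-Bayes **ComBat** harmonization of
exams-by-features tables with age/sex covariate preservation, plus the
standard evaluation framework for quantifying batch effects before and after
harmonization, on a synthetic multi-center cohort with a known ground truth.

## The model

A feature $f$ of exam $j$ in scanner batch $i$ is modeled as

$$Y_{ijf} = \alpha_f + \gamma_{if} + X_j\beta_f + \delta_{if}\,\epsilon_{ijf}$$

with additive ($\gamma_{if}$) and multiplicative ($\delta_{if}$) batch
effects and covariates $X$ (age, sex). Batch effects are estimated per
batch and feature, stabilized by empirical-Bayes shrinkage across features
(normal prior on $\gamma$, inverse-gamma on $\delta^2$, method-of-moments
hyperparameters, iterated conditional posterior means), and removed:

$$Y^*_{ijf} = \frac{Y_{ijf} - \hat\alpha_f - \gamma^*_{if} - X_j\hat\beta_f}{\delta^*_{if}} + \hat\alpha_f + X_j\hat\beta_f.$$

Batch differences per feature are tested with an equal-variance t-test
(2 groups) or one-way ANOVA (3+), with effect size
$\eta_p^2 = SS_{effect}/(SS_{effect}+SS_{error})$ and Cohen's
$F = \sqrt{\eta_p^2/(1-\eta_p^2)}$, Bonferroni-corrected across the feature
family, significance at adjusted $p < 0.05$.

## Worked example

Six scanner arms (Siemens/GE/Philips × 1.5T/3T, 3857 exams), 172
radiomic-like features with strong injected batch effects, the six-experiment
comparison grid, empirical-Bayes ComBat with age and sex covariates:

```r
library(combatfx)
report <- run_study(study_config(
  feature_families = "radiomic_172",
  effect_strength  = "strong",
  seed = 1
))
report
#> Harmonization study report (seed 1, strength strong, mode eb)
#>   family       experiment controlled       n_significant_original n_significant_harmonized
#> 1 radiomic_172          1 Site 1 (Siemens)                    156                        0
#> 2 radiomic_172          2 Site 2 (GE)                         152                        0
#> 3 radiomic_172          3 Site 3 (Philips)                     70                        0
#> 4 radiomic_172          4 1.5T                                166                        0
#> 5 radiomic_172          5 3T                                  158                        0
#> 6 radiomic_172          6 N/A                                 172                        0
```

Before harmonization 70–172 of the 172 features differ significantly
between scanners (depending on the comparison); after ComBat none do, and
the mean per-feature Cohen's F drops from 0.21–0.70 to 0.004–0.014:

```r
dplyr::select(tidy(report), experiment, mean_cohens_f_original, mean_cohens_f_harmonized)
#>   experiment mean_cohens_f_original mean_cohens_f_harmonized
#> 1          1                  0.513                  0.00450
#> 2          2                  0.588                  0.00637
#> 3          3                  0.213                  0.01417
#> 4          4                  0.561                  0.01171
#> 5          5                  0.583                  0.01199
#> 6          6                  0.702                  0.01152
```

Lower-level entry points: `combat_harmonize()` for one table,
`evaluate_features()` for the per-feature tests, `simulate_study_table()` /
`default_effect_spec()` for synthetic data, `zscore_matrix()` /
`kde_curves()` for heatmap and density exports, `autoplot()` /
`plot_feature_density()` / `plot_zscore_heatmap()` for figures. A thin CLI
over the same functions lives at `inst/cli/combatfx.R`
(subcommands `simulate`, `harmonize`, `evaluate`, `run-study`,
`export-heatmap`, `export-kde`).

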