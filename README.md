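# radrobust

Radiomic features extracted from [18F]-FDG-PET tumour images are
notoriously sensitive to image-processing choices that precede feature
extraction: the intensity-discretisation setting (fixed bin width in SUV,
or fixed bin number) and the isotropic voxel size and interpolator used
for resampling. `radrobust` quantifies that sensitivity per feature,
identifies parameter ranges within which a feature can still be trusted,
and removes well-behaved parameter dependencies by invertible regression —
so that radiomics studies can either restrict their settings or correct
their features instead of discarding them.

It is aimed at quantitative-imaging researchers who already have feature
tables (e.g. PyRadiomics output reshaped to long format): one value per
subject × feature × processing scenario × parameter value. No imaging data
are required; a seeded synthetic-cohort generator and a miniature PET
phantom are included so every stage can be exercised end-to-end.

## The method

For one feature observed on `n` subjects across an ordered parameter grid
`x_1 < … < x_m`, two robustness metrics are computed:

- **Agreement** — the within-subject percentage coefficient of variation,
  `CV_i = 100 · s_i / |m_i|` (sample SD over the subject's values across
  the grid, divided by their mean), averaged across subjects to give
  `CV_mean`.
- **Reliability** — the magnitude of the repeated-measures correlation
  `|r_rm|` between feature value and parameter, estimated by the ANCOVA
  formulation with subject-specific intercepts and a common slope, which
  respects the non-independence of repeated measurements per subject.

A feature is **robust** when `CV_mean < 10%` and `|r_rm| < 0.5` (strict
inequalities; both thresholds configurable). For features that fail, two
mitigation strategies run in parallel:

1. **Range conditions.** Both metrics are recomputed for every start–end
   sub-range of the grid (`choose(m, 2)` tiles: 435 for the 30-value
   bin-width grid, 496 for the 32-value bin-number grid, 378 per 28-value
   voxel-size grid). The largest square region of contiguous robust tiles
   defines the *robust range*; the outermost parameter values touched by
   any robust tile define the *robustness margin*. A feature with at least
   one robust tile is *conditionally robust*. Margins of all conditionally
   robust features are aggregated into a histogram, and the longest run of
   grid values recovering at least half of them is the scenario's *global
   robustness range*.
2. **Dependency correction.** The cohort mean curve is fitted with eight
   invertible forms `f(x) = α·g(x) + β`, `g ∈ {x, x², x³, 1/x, 1/x², 1/x³,
   log(s·x), 1/log(s·x)}` (s = 100 for bin widths, 10 for voxel sizes, to
   keep the log argument away from 1), by iteratively reweighted least
   squares with Huber downweighting and intrinsic weights `1/Var` across
   subjects. The lowest-AIC fit is inverted per subject:
   `f_corrected(x) = (f(x) − β) / g(x)`. The correction is *correctable*
   when the paired Wilcoxon test on per-subject CVs gives p < 0.05, the
   95% CIs of `|r_rm|` before/after do not overlap, both metrics decrease,
   and the corrected metrics satisfy the robust criteria; *moderately
   correctable* when significantly improved but still above the criteria;
   otherwise *not correctable*.

## Worked example

```r
library(radrobust)
library(dplyr)

fbw <- parameter_grid("discretisation", "FBW")   # 0.05–1.50 SUV, 30 values

spec <- cohort_spec(
  fbw,
  features = list(
    shape_like   = profile_flat(beta = 12),
    plateau_like = profile_plateau(1.00, "inv", alpha = 4, beta = 5),
    glcm_like    = profile_dependency("inv2", alpha = 1, beta = 3)
  ),
  n_subjects = 25, noise_sd = 0.03, seed = 2024)

cohort <- generate_cohort(spec)     # long tibble, 25 × 3 × 30 rows
report <- run_scenario(cohort, fbw)
report
#> <radr_report> discretisation/FBW: 3 features | robust 1, conditionally robust 1,
#>   non-robust 1 | correctable 1, moderately 1, not 0

tidy(report) |>
  select(feature_name, robust, conditional_category, margin,
         correctability_category)
#> # A tibble: 3 × 5
#>   feature_name robust conditional_category margin      correctability_category
#>   <chr>        <lgl>  <chr>                <chr>       <chr>
#> 1 glcm_like    FALSE  non_robust           <NA>        correctable
#> 2 plateau_like FALSE  conditionally_robust [0.95, 1.5] moderately_correctable
#> 3 shape_like   TRUE   not_applicable       <NA>        not_applicable

glance(report$corrections[["glcm_like"]])
#> # A tibble: 1 × 7
#>   feature_name algorithm category    best_function wilcoxon_p delta_cv delta_rrm
#>   <chr>        <chr>     <chr>       <chr>              <dbl>    <dbl>     <dbl>
#> 1 glcm_like    FBW       correctable inv2             5.96e-8    -295.    -0.440
```

Reading the output: the flat feature passes both criteria on the whole
grid (robust — like shape features, which do not depend on discretisation
at all). The plateau feature stabilises above 1.0 SUV; its robustness
margin `[0.95, 1.50]` says it can be used if bin widths stay in that
range. The `1/x²`-dependent feature has no robust range, but its
dependency is cleanly invertible: after correction the per-subject CVs
drop by ~295 percentage points (Wilcoxon p ≈ 6e-8) and the corrected
feature meets the robust criteria, so it is correctable. The scenario's
global robustness range (here `[0.95, 1.50]` SUV, cutoff 1 of 1
conditionally robust feature) is the bin-width window a study could adopt
wholesale.

Plots: `autoplot(matrix)` draws the tile correlogram with the nested
robust range/margin squares, `autoplot(report$global_range)` the
aggregation histogram, and `autoplot(correction)` the before/after
per-subject CV dumbbells.

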