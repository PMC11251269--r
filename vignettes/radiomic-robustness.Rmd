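---
title: "Robustness and correction of PET radiomic features: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robustness and correction of PET radiomic features: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radrobust)
```

## The problem

A radiomic feature is only useful as a biomarker if its value reflects
the tumour rather than the pipeline that produced it. Two pre-extraction
choices are especially influential for [18F]-FDG-PET: how SUV intensities
are discretised (a fixed bin width in SUV, or a fixed number of bins) and
which isotropic voxel size and interpolator the image is resampled to.
`radrobust` takes long-format feature tables — one value per subject,
feature, processing scenario and parameter value — and answers three
questions per feature: *is it robust to the parameter at all*, *over
which parameter sub-range would it become robust*, and *can its
dependency be removed by an invertible regression*.

The default parameter grids mirror a dense exploration of these settings:
bin widths 0.05–1.50 SUV in 0.05 steps (30 values), bin numbers 8–256 in
steps of 8 (32 values), and voxel sizes 0.8–3.5 mm in 0.1 steps for four
interpolator labels (4 × 28 values), 174 parameter settings in all.
Grids are constructed from integer step counts and then scaled (e.g. the
k-th bin width is `5k/100` SUV), so every value is exactly
`start + k·step` and tile indexing can rely on exact equality after
canonical rounding (2 decimals for SUV, integers for bins, 1 decimal for
mm). Feature-table parameter values are matched to grids by that same
canonical rounding — never by nearest-neighbour matching, which can
silently absorb unit errors.

## Robustness metrics

**Within-subject CV.** For one subject's values `y_1 … y_m` across a
range, `CV = 100 · sd(y) / |mean(y)|` with the sample (n−1) standard
deviation — the standard within-subject CV convention; the denominator
choice is documented here because it is not forced by the definition.
Constant input gives exactly 0. Features such as skewness cross zero, so
subjects with `|mean| < 1e-8` (feature units) are flagged *degenerate*
and excluded from the across-subject average `CV_mean`, with the excluded
count reported; `strict = TRUE` turns the exclusion into an error for
auditing.

**Repeated-measures correlation.** `r_rm` is the common within-subject
correlation between parameter and feature value, estimated by the ANCOVA
formulation: centre `x` and `y` within each subject, fit the shared slope
`b` by least squares, and set
`r_rm = sign(b) · sqrt(SS_measure / (SS_measure + SS_error))` on
`df = N − k − 1` degrees of freedom (`N` observations, `k` subjects).
This is algebraically the Pearson correlation of the within-subject
centred data, which is how the implementation computes it; the test suite
checks it against an explicit design-matrix (subject indicators + x)
least-squares solve to 1e-10. The 95% CI uses the Fisher z-transform
with standard error `1/sqrt(df − 1)` — the usual `1/sqrt(n − 3)` rule at
effective sample size `df + 2` — and is folded onto the magnitude scale
(an interval straddling zero maps to `[0, max |bound|]`), because the
correction stage compares CIs of `|r_rm|`. When `df < 2` the CI is `NA`.

Degenerate inputs are defined, not fudged: a feature with zero
within-subject variance everywhere (all shape features under
discretisation) gets `r_rm = 0` and `CV = 0` with a
`zero_variance_feature` flag, and is therefore robust — the scientifically
correct verdict for a feature the parameter cannot touch. A parameter
constant within every subject is an error, since the slope is undefined.

**Criteria.** `CV_mean < 10%` and `|r_rm| < 0.5`, both strict: a feature
sitting exactly on a threshold is not robust. Both thresholds are
arguments of `robust_criteria()`.

## Range analysis

Every ordered pair of grid values defines a candidate range; the tile for
`(i, j)` holds the metrics recomputed over the **full inclusive
sub-range** `x_i … x_j`, per subject — not just the two endpoints. Tiles
are ranges, and the metrics should reflect everything a study using that
range would encounter; endpoint-only semantics would let an interior
spike hide. The robust mask applies the criteria per tile.

The **robust range** is the longest index interval `[a, b]` whose every
interior tile is robust, found by an interval recurrence equivalent to
run-length encoding along rows and columns of the mask; the test suite
verifies exact agreement with exhaustive interval search over all 1024
masks on a 5-value grid and 200 random masks on an 8-value grid. Ties
between equal-length intervals go to the one with larger parameter
values, consistent with the empirical tendency of PET feature robustness
to concentrate at coarser bin widths and voxel sizes; the tie-break is
deterministic and documented rather than silent. The **margin** is the
interval spanned by the outermost robust-tile endpoints. At least one
robust tile makes the feature *conditionally robust*; the robust range
can still be absent (a single isolated robust tile defines a margin but
no contiguous square).

**Global range.** Margins of the conditionally robust features are
counted per grid value; the cut-off is `ceiling(n/2)` — the literal
reading of "at least half" for odd counts — and the global range is the
longest contiguous run of grid values meeting it. Run-length ties prefer
the run containing the histogram maximum, then larger parameter values.
Both the margin-based and robust-range-based histograms are emitted,
since either aggregation is defensible; the margin variant drives the
chosen range because margins are what a study would actually restrict to.

## Dependency correction

The cohort mean curve (one point per grid value) is fitted with all eight
forms `α·g(x) + β`. Fitting targets the mean curve, not individual
subjects: the correction must be a single cohort-level transform, or it
would leak subject-specific information into the corrected feature.
Intrinsic weights are the reciprocal cross-subject variances, floored at
1e-12 to avoid infinite weights where subjects agree exactly (the floored
count is logged). The robust loss is Huber with tuning constant 1.345
(95% Gaussian efficiency), applied multiplicatively on top of the
intrinsic weights by transforming to the weighted problem and
downweighting standardised residuals against a MAD scale; convergence is
a coefficient change below 1e-8 or 50 iterations, initialised at the
weighted least-squares solution. A `g(x)` constant on the grid is a
singular design; the fit is marked non-converged and excluded from
selection. With equal weights and no outliers the fit reproduces
closed-form weighted least squares to 1e-8, and it is cross-checked
against an independent IRLS implementation (`MASS::rlm`) in the tests.

AIC is `n·ln(wRSS/n) + 2k` with `k = 3` (α, β, noise scale), computed
from the intrinsically weighted residuals at convergence. The constant
`k` cancels across candidates, so only relative values matter; exact ties
(e.g. two perfect fits) resolve by the canonical function order
lin, quad, cub, inv, inv2, inv3, log, invlog.

The log-family forms use `g(x) = log(s·x)` with `s = 100` for bin widths
and `s = 10` for voxel sizes, so the argument never approaches 1 (where
`1/log` diverges); bin numbers start at 8 and need no scaling. The
correction still validates `|g(x)| > 1e-12` at every grid value rather
than trusting the rule, so custom grids cannot divide by zero silently.

Correction inverts the chosen fit per subject:
`corrected(x) = (value − β)/g(x)` with the cohort-level `β`. For data
generated exactly as `α·g(x) + β` the corrected series is the constant
`α` (up to floating-point solve error, ~1e-14 in CV). Corrected tables
are tagged, and a tagged table is refused as correction input — the
transform is not idempotent.

**Categorisation.** The paired Wilcoxon signed-rank test on per-subject
CVs is two-sided, with an explicit directional requirement
(`ΔCV_mean < 0` and `Δ|r_rm| < 0`) so that a significant *increase* can
never count as a correction. Sidedness is a genuine free choice here; the
two-sided test plus direction is the conservative combination.
Significance additionally requires non-overlapping 95% CIs of `|r_rm|`; a
zero-variance corrected feature, whose CI is undefined, contributes a
degenerate point interval. Significant and robust afterwards →
*correctable*; significant only → *moderately correctable*; otherwise
*not correctable* (all paired CV differences zero yields an undefined
p-value and is reported as not correctable with a reason). No
multiplicity adjustment is applied across features; the per-feature
p-values are reported so users can apply their own.

## The synthetic cohort generator

`generate_cohort()` draws
`value(i, x) = (α + a_i)·g(x) + (β + b_i) + ε`, with per-subject slope
and intercept effects `a_i ~ N(0, (slope_sd·α)²)`, `b_i ~ N(0,
intercept_sd²)` and noise `ε ~ N(0, noise_sd(x)²)` (scalar or per grid
value). Three profiles cover the behaviours the pipeline must
distinguish: flat (`α = 0`, robust), a pure dependency from the
eight-form library (correctable), and a plateau — the dependency below a
breakpoint, constant above it, continuous at it — which produces genuine
conditional robustness at the coarse end of the grid, where real PET
features tend to stabilise. Subject effects are drawn before noise per
feature, so refining the grid preserves subject effects; identical spec
and seed give bit-identical tables.

Default magnitudes are desk-scale design choices: 30 subjects (the test
and acceptance cohort size; large enough for stable Wilcoxon and rmcorr
CIs, small enough that the full tile analysis of a 30-value grid runs in
seconds), intercept SD 0.1, slope SD 5% of α, noise SD 0.01 in feature
units. The generator emulates the statistical structure the analysis
assumes — smooth cohort-level dependency, additive subject effects,
Gaussian noise. It does **not** emulate inter-feature correlation,
non-Gaussian or multiplicative noise, lesion-size effects, or the
discreteness artefacts of real texture matrices; passing tests therefore
validate the machinery, not any claim about a particular clinical
dataset.

The designed end-to-end scenario used in the acceptance tests pairs two
flat features, two plateaus (breakpoints 1.00 and 1.20 SUV, inverse
dependency with α = 4 and 6), two pure dependencies (linear α = 8;
log α = 2), and one pathological feature (noise SD 3 against a mean of
5). These magnitudes come from the noiseless geometry of the tile
correlations: for a plateau at 1.00 SUV, tiles starting two or more grid
steps below the breakpoint retain `|r_rm| ≥ 0.60` even before noise, so
the derived margin cannot creep more than one step below the break,
whereas a breakpoint at 0.75 SUV puts that geometric value at ~0.52 —
indistinguishable from the 0.5 threshold under any realistic noise. The
linear dependency's α = 8 keeps the corrected residual scatter (noise is
amplified by `1/x` at small bin widths) well inside the 10% CV criterion.

## The phantom fixture

`generate_phantom()` builds a small SUV volume with spherical lesions on
a noisy background plus the lesion mask; `fbw_discretise()` implements
the IBSI fixed-bin-size rule anchored at the mask minimum (the common
extractor default — anchoring at 0 SUV is a documented alternative the
user can emulate by shifting values), `fbn_discretise()` the
fixed-bin-number rule with the maximum clipped into bin n. Entropy and
uniformity of the occupied-bin histogram are the two first-order features
most sensitive to discretisation, which is all the smoke test needs.
`resample_volume()` does centre-aligned nearest-neighbour or trilinear
resampling onto an isotropic grid (`round(extent/target)` voxels per
axis); B-spline and Gaussian interpolators exist only as grid labels —
image-level support for them is out of scope. NIfTI export is available
via `RNifti` for interoperability with external extractors.

## Problem sizes and runtime

The shipped tests run the full tile analysis on 30-value grids with
25–30 subjects, enumerate all 1024 robust masks on 5-value grids, fit
8 × 20 seeded recovery cohorts, and complete in about a minute on one
core; the acceptance script recomputes its quantities in ~15 s. These
sizes are the package's validation scale, chosen so the whole suite can
run on a laptop; nothing in the implementation caps the number of
subjects or features.

## Known limitations

- The correction library is single-term; piecewise (plateau-like)
  dependencies are fitted imperfectly by design, and typically land in
  *moderately correctable*.
- `CV_mean` is undefined for genuinely zero-mean features; such subjects
  are excluded and counted rather than rescued by an offset.
- The Wilcoxon p-values are unadjusted across features.
- Mixed-effects harmonisation across scanners/centres is a different
  problem and out of scope; the correction here removes a
  within-pipeline parameter dependency only.
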