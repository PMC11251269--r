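Package: radrobust
Title: Robustness and Correction of PET Radiomic Features Under Image
    Processing Parameter Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the sensitivity of tumour [18F]-FDG-PET radiomic
    features to intensity-discretisation (fixed bin width, fixed bin
    number) and voxel-interpolation parameter choices, and mitigates it.
    Implements the two robustness metrics (mean within-subject percentage
    coefficient of variation and the magnitude of the repeated-measures
    correlation coefficient), pairwise robustness-range matrices over all
    start-end parameter ranges with robust-range and robustness-margin
    derivation, global robustness-range aggregation across features, and
    invertible-regression dependency correction (eight candidate
    functional forms fitted by variance-weighted iteratively reweighted
    least squares, selected by AIC) with correctable / moderately
    correctable / not correctable categorisation. Ships a seeded
    synthetic-cohort generator and a miniature PET phantom with
    IBSI-style discretisation so the full pipeline can be exercised
    without imaging data.
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
    yaml
Suggests:
    jsonlite,
    MASS,
    optparse,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
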