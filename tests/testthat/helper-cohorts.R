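# Small fixture builders shared across test files.

tiny_grid <- function(n = 5, scheme = "interpolation", algorithm = "linear") {
  parameter_grid(scheme, algorithm, values = (8:(7 + n)) / 10)
}

# Hand-built long table: one feature over a grid, values given as a
# subjects x parameters matrix.
table_from_matrix <- function(Y, grid, feature = "f1") {
  subjects <- sprintf("P%02d", seq_len(nrow(Y)))
  feature_table(tidyr::expand_grid(
    subject_id = subjects,
    parameter_value = grid$values
  ) |>
    dplyr::mutate(
      feature_name = feature, scheme = grid$scheme,
      algorithm = grid$algorithm,
      value = as.vector(t(Y))
    ))
}

# The designed end-to-end scenario: two flat (robust), two plateau
# (conditionally robust), two pure-dependency (correctable), one
# pathological high-noise feature (non-robust, not correctable).
designed_scenario <- function(seed = 7L, n_subjects = 30L) {
  g <- parameter_grid("discretisation", "FBW")
  main <- cohort_spec(
    g,
    features = list(
      flat_a = profile_flat(beta = 5),
      flat_b = profile_flat(beta = 20),
      plat_a = profile_plateau(1.00, "inv", alpha = 4, beta = 5),
      plat_b = profile_plateau(1.20, "inv", alpha = 6, beta = 8),
      dep_a = profile_dependency("lin", alpha = 8, beta = 5),
      dep_b = profile_dependency("log", alpha = 2, beta = 8, scale_s = 100)
    ),
    n_subjects = n_subjects, intercept_sd = 0.05, slope_sd = 0.02,
    noise_sd = 0.03, seed = seed
  )
  noisy <- cohort_spec(
    g, features = list(path_a = profile_flat(beta = 5)),
    n_subjects = n_subjects, intercept_sd = 0.05, slope_sd = 0,
    noise_sd = 3, seed = seed + 1L
  )
  list(grid = g,
       table = feature_table(dplyr::bind_rows(generate_cohort(main),
                                              generate_cohort(noisy))))
}
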