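test_that("within-subject CV matches the n-1 closed form", {
  expect_equal(within_subject_cv(c(2, 2, 2)), 0)
  expect_equal(within_subject_cv(c(1, 2, 3)), 50)  # 100 * sd([1,2,3]) / 2
  expect_error(within_subject_cv(3), "at least 2")
})

test_that("CV is scale invariant and flags near-zero means", {
  set.seed(11)
  for (i in 1:20) {
    v <- rnorm(6, mean = 10, sd = 2)
    expect_equal(within_subject_cv(10 * v), within_subject_cv(v))
  }
  expect_true(is.na(within_subject_cv(c(-1e-10, 1e-10))))
})

test_that("CV_mean averages per-subject CVs and excludes degenerate subjects", {
  g <- tiny_grid(3)
  Y <- rbind(c(0.9, 1.0, 1.1),   # CV 10%
             c(0.7, 1.0, 1.3))   # CV 30%
  m <- feature_metrics(table_from_matrix(Y, g), "f1", g)
  expect_equal(m$cv_mean, 20)
  expect_equal(unname(m$cv_per_subject), c(10, 30))

  Y2 <- rbind(c(0.9, 1.0, 1.1), c(-0.1, 0, 0.1))  # second subject mean 0
  m2 <- feature_metrics(table_from_matrix(Y2, g), "f1", g)
  expect_equal(m2$cv_mean, 10)
  expect_equal(m2$n_cv_degenerate, 1L)
  expect_true("zero_mean_subjects" %in% m2$flags)
  expect_error(
    feature_metrics(table_from_matrix(Y2, g), "f1", g, strict = TRUE),
    "strict")
})

test_that("perfect common-slope data gives |r_rm| = 1", {
  x <- rep(1:5, 3)
  id <- rep(c("a", "b", "c"), each = 5)
  y <- 3 * rep(1:5, 3) + rep(c(0, 10, 20), each = 5)
  r <- rmcorr(x, y, id)
  expect_equal(r$rrm, 1)
  expect_equal(r$ci_low, 1)
  y_neg <- -3 * rep(1:5, 3) + rep(c(0, 10, 20), each = 5)
  expect_equal(rmcorr(x, y_neg, id)$rrm, -1)
})

test_that("rmcorr matches the design-matrix ANCOVA oracle", {
  set.seed(42)
  for (i in 1:30) {
    n_sub <- sample(2:6, 1)
    n_par <- sample(2:8, 1)
    x <- rep(seq_len(n_par), n_sub)
    id <- rep(sprintf("s%d", seq_len(n_sub)), each = n_par)
    y <- rnorm(n_sub * n_par) + 0.3 * x + as.numeric(factor(id))
    got <- rmcorr(x, y, id)
    want <- rmcorr_oracle(x, y, id)
    expect_equal(got$rrm, want$rrm, tolerance = 1e-10)
    expect_equal(got$df, want$df)
  }
})

test_that("rmcorr is invariant to per-subject intercept shifts and affine x", {
  set.seed(5)
  x <- rep(1:6, 4)
  id <- rep(letters[1:4], each = 6)
  y <- 0.5 * x + rnorm(24)
  base <- rmcorr(x, y, id)$rrm
  shifted <- y + rep(c(100, -50, 3, 7), each = 6)
  expect_equal(rmcorr(x, shifted, id)$rrm, base)
  expect_equal(rmcorr(2 * x + 5, y, id)$rrm, base)
  expect_equal(rmcorr(-x, y, id)$rrm, -base)
})

test_that("x-independent noise gives r_rm near 0 within its CI", {
  set.seed(99)
  n_sub <- 50; n_par <- 10
  x <- rep(seq_len(n_par), n_sub)
  id <- rep(sprintf("s%02d", seq_len(n_sub)), each = n_par)
  y <- rep(rnorm(n_sub, sd = 5), each = n_par) + rnorm(n_sub * n_par)
  r <- rmcorr(x, y, id)
  expect_lt(r$rrm_abs, 0.15)
  expect_lte(r$ci_low, r$rrm_abs)
  expect_gte(r$ci_high, r$rrm_abs)
  expect_equal(r$ci_low, 0)  # CI of |r_rm| reaches 0 for a null effect
})

test_that("a feature with zero within-subject variance is robust by definition", {
  g <- tiny_grid(4)
  Y <- matrix(rep(c(3, 7, 11), each = 4), nrow = 3, byrow = TRUE)
  m <- feature_metrics(table_from_matrix(Y, g, feature = "shape_vol"),
                       "shape_vol", g)
  expect_equal(m$rrm, 0)
  expect_equal(m$cv_mean, 0)
  expect_true("zero_variance_feature" %in% m$flags)
  expect_true(is_robust(m, robust_criteria()))
})

test_that("rmcorr errors when x never varies within subjects", {
  expect_error(rmcorr(rep(1, 6), rnorm(6), rep(c("a", "b"), each = 3)),
               "constant")
})

test_that("cv_mean of noisy flat cohorts matches the analytic expectation", {
  # E[CV] = 100 * sigma * c4(n) / mu for small sigma/mu; c4 from the
  # chi distribution of the sample sd.
  g <- parameter_grid("discretisation", "FBW")
  n <- length(g$values)
  c4 <- sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2)
  spec <- cohort_spec(g, features = list(f = profile_flat(beta = 10)),
                      n_subjects = 200, intercept_sd = 0, slope_sd = 0,
                      noise_sd = 0.5, seed = 314)
  m <- feature_metrics(generate_cohort(spec), "f", g)
  expect_equal(m$cv_mean, 100 * 0.5 * c4 / 10, tolerance = 0.02)
})

test_that("the robust criteria are strict inequalities on both metrics", {
  crit <- robust_criteria()
  expect_true(is_robust(list(cv_mean = 0, rrm_abs = 0), crit))
  expect_false(is_robust(list(cv_mean = 10, rrm_abs = 0.1), crit))
  expect_false(is_robust(list(cv_mean = 5, rrm_abs = 0.5), crit))
  expect_false(is_robust(list(cv_mean = 12, rrm_abs = 0.7), crit))
  expect_error(robust_criteria(cv_threshold = 0), "positive")
})
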