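test_that("first eigenvariate recovers the shared component of rank-1 voxel data", {
  set.seed(1)
  t_len <- 80
  signal <- sin(seq(0, 6 * pi, length.out = t_len))
  loadings <- runif(30, 0.5, 2)
  vox <- outer(loadings, signal)  # voxels x time, exactly rank 1
  ev <- extract_eigenvariate(vox)
  expect_equal(abs(cor(ev, signal)), 1, tolerance = 1e-10)
  expect_equal(sd(ev), 1, tolerance = 1e-10)
  # sign aligned with the across-voxel mean
  expect_gte(cor(ev, colMeans(vox - rowMeans(vox))), 0)
  expect_error(extract_eigenvariate(matrix(1, 3, 10)), "constant")
})

test_that("initial-scan discard trims exactly the equilibration volumes", {
  ts <- session_time_series(matrix(rnorm(165 * 4), 165, 4))
  out <- discard_initial_scans(ts, 5)
  expect_equal(nrow(out$values), 160)
  expect_identical(out$values, ts$values[-(1:5), ])
  expect_error(discard_initial_scans(ts, 165), "cannot discard")
})

test_that("high-pass set contains exactly the discrete frequencies at or below the cutoff", {
  hp <- build_highpass_regressors(160, 2, cutoff_hz = 0.009)
  # f_k = k / (160 * 2); k = 1, 2 qualify (f_2 = 0.00625, f_3 = 0.009375)
  expect_equal(ncol(hp), 4)
  expect_identical(colnames(hp), c("sin1", "cos1", "sin2", "cos2"))
  expect_warning(build_highpass_regressors(20, 2, cutoff_hz = 0.009),
                 "no discrete frequency")
})

test_that("regression removes slow drift but keeps fast fluctuations", {
  set.seed(2)
  t_len <- 160; tr <- 2
  tt <- (seq_len(t_len) - 1) * tr
  slow <- 3 * sin(2 * pi * 0.005 * tt + 0.3)     # below the cutoff
  fast <- sin(2 * pi * 0.08 * tt)                # well above it
  y <- slow + fast + rnorm(t_len, sd = 0.1)
  ts <- session_time_series(cbind(y = y), tr_seconds = tr)
  hp <- build_highpass_regressors(t_len, tr)
  X <- build_nuisance_matrix(NULL, n_timepoints = t_len, extra = hp)
  res <- regress_out(ts, X)$values[, 1]
  expect_lt(abs(cor(res, slow)), 0.1)
  expect_gt(cor(res, fast), 0.9)
})

test_that("nuisance design has the canonical columns and drops exact collinearity", {
  cfg <- cohort_config(n_subjects = 1, n_timepoints = 60, n_nodes = 6)
  nuis <- simulate_nuisance(cfg, seed = 3)
  X <- build_nuisance_matrix(nuis)
  # intercept + 2 trends + 6 motion + 6 derivatives + 3 tissue
  expect_equal(ncol(X), 18)
  expect_identical(attr(X, "dropped"), character(0))
  dup <- cbind(nuis$motion[, 1, drop = FALSE])
  colnames(dup) <- "copy_of_motion1"
  expect_warning(X2 <- build_nuisance_matrix(nuis, extra = dup),
                 "collinear")
  expect_identical(attr(X2, "dropped"), "copy_of_motion1")
})

test_that("single-projection residuals are orthogonal to every regressor", {
  cfg <- cohort_config(n_subjects = 1, n_timepoints = 165, n_nodes = 6)
  gt <- ground_truth_network(chain_precision(6, 0.45))
  nuis <- simulate_nuisance(cfg, seed = 5)
  ts <- simulate_session_bold(gt, cfg, seed = 5, nuisance = nuis)
  clean <- preprocess_session(ts, nuis)
  expect_equal(nrow(clean$values), 160)
  expect_identical(clean$state, "clean")
  trim <- function(m) m[-(1:5), , drop = FALSE]
  hp <- build_highpass_regressors(160, 2)
  X <- cbind(1, poly(1:160, 2), trim(nuis$motion),
             trim(nuis$motion_derivatives), trim(nuis$tissue_components), hp)
  expect_lt(max(abs(crossprod(X, clean$values))), 1e-6)
})

test_that("cleaning recovers the true connectivity hidden under contamination", {
  # property: correlations from the cleaned series are closer to the truth
  # than correlations from the raw contaminated series
  gt <- ground_truth_network(chain_precision(8, 0.45))
  cfg <- cohort_config(n_subjects = 1, n_timepoints = 165, n_nodes = 8,
                       drift_amplitude = 1.5, motion_artifact_amplitude = 0.8,
                       random_seed = 11)
  true_r <- stats::cov2cor(gt$covariance)
  err <- function(vals) max(abs(cor(vals) - true_r))
  errs_raw <- errs_clean <- numeric(5)
  for (k in 1:5) {
    nuis <- simulate_nuisance(cfg, seed = 100 + k)
    ts <- simulate_session_bold(gt, cfg, seed = 200 + k, nuisance = nuis)
    errs_raw[k] <- err(ts$values)
    errs_clean[k] <- err(preprocess_session(ts, nuis)$values)
  }
  expect_true(all(errs_clean < errs_raw))
})
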