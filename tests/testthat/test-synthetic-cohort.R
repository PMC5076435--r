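test_that("ground truth network enforces its invariants", {
  om <- chain_precision(6, 0.4)
  gt <- ground_truth_network(om)
  expect_lt(max(abs(gt$covariance %*% gt$precision - diag(6))), 1e-8)
  expect_error(ground_truth_network(matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")
  expect_error(ground_truth_network(matrix(c(1, 0, 0.5, 1), 2)), "symmetric")
  expect_error(ground_truth_network(diag(4),
                                    homotopic_pair = c(2L, 3L, 4L, 1L)),
               "involution")
})

test_that("modular precision is reproducible, unit-scaled, and denser within modules", {
  mods <- rep(c("motor", "other"), each = 20)
  a <- make_modular_precision(40, mods, within_module_density = 0.4,
                              between_module_density = 0.05, seed = 11)
  b <- make_modular_precision(40, mods, within_module_density = 0.4,
                              between_module_density = 0.05, seed = 11)
  expect_identical(a$precision, b$precision)
  expect_lt(max(abs(diag(a$covariance) - 1)), 1e-10)
  supp <- a$precision != 0
  same <- outer(mods, mods, "==")
  ut <- upper.tri(supp)
  dens_within <- mean(supp[ut & same])
  dens_between <- mean(supp[ut & !same])
  expect_gt(dens_within, dens_between)
})

test_that("hemisphere-symmetric truth has mirrored partial correlation blocks", {
  mods <- rep(c(rep("motor", 3), rep("other", 5)), 2)
  gt <- make_modular_precision(16, mods, symmetry = TRUE, seed = 5)
  expect_identical(gt$hemisphere, rep(c("left", "right"), each = 8))
  expect_identical(gt$homotopic_pair, c(9:16, 1:8))
  pc <- -gt$precision / sqrt(diag(gt$precision) %o% diag(gt$precision))
  left <- 1:8; right <- 9:16
  expect_lt(max(abs(pc[left, left] - pc[right, right])), 1e-10)
  # swap-invariance of the whole matrix, not just the diagonal blocks
  swap <- c(right, left)
  expect_lt(max(abs(pc[swap, swap] - pc)), 1e-10)
})

test_that("lesion trajectory attenuates persistently and reverts transient edges bitwise", {
  mods <- rep(c(rep("motor", 3), rep("other", 3)), 2)
  gt <- make_modular_precision(12, mods, symmetry = TRUE, seed = 3,
                               within_module_density = 0.6,
                               between_module_density = 0.2)
  trans <- matrix(c(4, 5, 10, 11), 2, byrow = TRUE)
  les <- lesion_trajectory(persistent_scale = 0.5, transient_scale = 0.4,
                           transient_edges = trans)
  per <- apply_lesion_trajectory(gt, les)
  expect_named(per, c("op-1d", "op+1d", "op+7d", "op+3m"))
  expect_identical(per[["op-1d"]]$precision, gt$precision)
  motor <- which(gt$module_id == "motor")
  m <- motor[1:2]
  for (s in c("op+1d", "op+7d", "op+3m"))
    expect_equal(per[[s]]$precision[m[1], m[2]],
                 0.5 * gt$precision[m[1], m[2]])
  # transient (non-motor) edges scaled only acutely, then bitwise baseline
  expect_equal(per[["op+1d"]]$precision[4, 5], 0.4 * gt$precision[4, 5])
  expect_identical(per[["op+7d"]]$precision[4, 5], gt$precision[4, 5])
  expect_identical(per[["op+3m"]]$precision[4, 5], gt$precision[4, 5])
  nonprog <- which(gt$module_id == "other")
  expect_identical(per[["op+7d"]]$precision[nonprog, nonprog],
                   gt$precision[nonprog, nonprog])
  expect_error(lesion_trajectory(persistent_scale = 0), "persistent_scale")
  expect_error(lesion_trajectory(persistent_scale = 2.5), "persistent_scale")
})

test_that("simulated BOLD has the ground-truth cross-sectional covariance", {
  gt <- ground_truth_network(chain_precision(6, 0.45))
  cfg <- cohort_config(n_subjects = 1, n_timepoints = 20000, n_nodes = 6,
                       ar_coefficient = 0.4, drift_amplitude = 0,
                       motion_artifact_amplitude = 0,
                       observation_noise_sd = 0, random_seed = 2)
  ts <- simulate_session_bold(gt, cfg, seed = 2)
  expect_identical(ts$state, "clean")
  expect_lt(max(abs(cov(ts$values) - gt$covariance)), 0.06)
  # lag-1 autocorrelation close to the configured AR coefficient
  ac <- mean(sapply(1:6, function(j)
    cor(ts$values[-1, j], ts$values[-nrow(ts$values), j])))
  expect_lt(abs(ac - 0.4), 0.05)
  # same seed, same draw
  ts2 <- simulate_session_bold(gt, cfg, seed = 2)
  expect_identical(ts$values, ts2$values)
})

test_that("contaminated sessions carry drift power at low frequencies", {
  gt <- ground_truth_network(chain_precision(6, 0.45))
  cfg <- cohort_config(n_subjects = 1, n_timepoints = 165, n_nodes = 6,
                       random_seed = 4)
  nuis <- simulate_nuisance(cfg, seed = 9)
  ts <- simulate_session_bold(gt, cfg, seed = 4, nuisance = nuis)
  expect_identical(ts$state, "raw")
  expect_equal(dim(ts$values), c(165L, 6L))
  X <- cbind(nuis$motion, nuis$motion_derivatives, nuis$tissue_components)
  expect_equal(dim(X), c(165L, 15L))
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(qr(Xc, tol = 1e-10)$rank, 15L)
})

test_that("ordinal scores stay in range and track motor strength", {
  sc <- simulate_scores(c(0.5, 0.1, 0.1, 0.1), coupling_slope = 1.5,
                        noise_sd = 0, seed = 1)
  expect_true(all(sc$action %in% 0:4) && all(sc$posture %in% 0:4))
  # strongest session has the largest expected score at zero noise
  expect_gt(sc$action[1], max(sc$action[-1]))
  sc2 <- simulate_scores(c(0.5, 0.1, 0.1, 0.1), noise_sd = 0, seed = 99)
  expect_identical(sc$action, sc2$action)
})

test_that("generated cohort has the designed structure and support-preserving jitter", {
  cfg <- cohort_config(n_subjects = 3, n_timepoints = 40, n_nodes = 12,
                       random_seed = 7)
  co <- generate_cohort(cfg, seed = 7)
  expect_length(co$subjects, 3)
  expect_named(co$subjects[[1]]$sessions,
               c("op-1d", "op+1d", "op+7d", "op+3m"))
  base_supp <- co$truth$precision != 0
  for (s in co$subjects) {
    subj_base <- s$sessions[["op-1d"]]$truth$precision
    expect_identical(subj_base != 0, base_supp)
    expect_length(s$action_score, 4)
  }
  # distinct subjects get distinct jitters and series
  expect_false(identical(co$subjects[[1]]$sessions[[1]]$time_series$values,
                         co$subjects[[2]]$sessions[[1]]$time_series$values))
  co2 <- generate_cohort(cfg, seed = 7)
  expect_identical(co$subjects[[2]]$sessions[[3]]$time_series$values,
                   co2$subjects[[2]]$sessions[[3]]$time_series$values)
})
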