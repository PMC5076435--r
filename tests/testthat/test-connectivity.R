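test_that("Fisher-z FC equals atanh of the Pearson correlations", {
  set.seed(1)
  x <- matrix(rnorm(200 * 5), 200, 5)
  colnames(x) <- sprintf("r%d", 1:5)
  fc <- pearson_fc(session_time_series(x))
  r <- cor(x); diag(r) <- 0
  expect_equal(fc$values, atanh(r), tolerance = 1e-12)
  expect_identical(fc$kind, "FC_z")
  x[, 2] <- 1
  expect_error(pearson_fc(x), "constant node series")
  expect_error(fisher_z(matrix(c(1, 1, 1, 1), 2)), "magnitude 1")
})

test_that("FDR thresholding keeps strong positive edges and drops null edges", {
  set.seed(2)
  # strongly coupled pair among independent nodes
  z <- matrix(rnorm(300 * 6), 300, 6)
  z[, 2] <- 0.8 * z[, 1] + sqrt(1 - 0.64) * rnorm(300)
  fc <- pearson_fc(z)
  g <- fdr_threshold_network(fc, t_effective = 300, q = 0.05)
  expect_gt(g$weights[1, 2], 0)
  # retained weights are exactly the z-values
  keep <- g$weights > 0
  expect_equal(g$weights[keep], fc$values[keep])
  # independent noise: typically nothing survives; never a negative weight
  z0 <- matrix(rnorm(300 * 6), 300, 6)
  g0 <- suppressWarnings(fdr_threshold_network(pearson_fc(z0), 300))
  expect_true(all(g0$weights >= 0))
})

test_that("graphical lasso at lambda 0 recovers the matrix inverse", {
  set.seed(3)
  x <- matrix(rnorm(500 * 6), 500, 6)
  S <- cor(x)
  fit <- glasso_fit(S, 0)
  expect_lt(max(abs(fit$precision - solve(S))), 1e-6)
})

test_that("graphical lasso satisfies the KKT conditions at convergence", {
  set.seed(4)
  x <- rmvn_from_precision(400, chain_precision(8, 0.4), seed = 4)
  S <- cor(x)
  lambda <- 0.1
  fit <- glasso_fit(S, lambda)
  W <- fit$covariance
  # subgradient: |W - S| <= lambda off-diagonal, equality where Omega != 0
  off <- abs(W - S); diag(off) <- 0
  expect_lt(max(off), lambda + 1e-4)
  active <- fit$support & !diag(TRUE, 8)
  if (any(active))
    expect_lt(max(abs(off[active] - lambda)), 1e-4)
  # diagonal unpenalised: W_ii = S_ii exactly
  expect_lt(max(abs(diag(W) - diag(S))), 1e-10)
  # penalty at or above lambda_max empties the off-diagonal support
  fit2 <- glasso_fit(S, glasso_lambda_max(S) * 1.01)
  expect_true(all(fit2$precision[upper.tri(fit2$precision)] == 0))
})

test_that("constrained refit matches S on the support and de-shrinks the lasso", {
  set.seed(5)
  om <- chain_precision(7, 0.4)
  x <- rmvn_from_precision(600, om, seed = 5)
  S <- cor(x)
  supp <- om != 0
  refit <- refit_constrained_mle(S, supp)
  on <- supp | diag(TRUE, 7)
  expect_lt(max(abs(refit$covariance - S)[on]), 1e-6)
  expect_true(all(refit$precision[!on] == 0))
  # full support reduces to the unconstrained MLE, the plain inverse
  full <- refit_constrained_mle(S, matrix(TRUE, 7, 7))
  expect_lt(max(abs(full$precision - solve(S))), 1e-5)
  # de-shrinkage: refitted edges are closer to the truth than lasso edges.
  # fitting on the correlation matrix targets the precision of the
  # standardised variables, D^(1/2) Omega D^(1/2) with D = diag(Sigma)
  d_ <- sqrt(diag(solve(om)))
  om_std <- om * (d_ %o% d_)
  las <- glasso_fit(S, 0.1)
  refit2 <- refit_constrained_mle(S, las$support)
  act <- las$support & supp & upper.tri(supp)
  expect_lt(mean(abs(refit2$precision[act] - om_std[act])),
            mean(abs(las$precision[act] - om_std[act])))
})

test_that("StARS selection is deterministic in the seed and lies on the grid", {
  x <- rmvn_from_precision(160, chain_precision(10, 0.45), seed = 6)
  s1 <- stars_select_lambda(x, n_subsamples = 15, seed = 42)
  s2 <- stars_select_lambda(x, n_subsamples = 15, seed = 42)
  expect_identical(s1$lambda, s2$lambda)
  expect_true(s1$lambda %in% s1$lambda_grid)
  expect_equal(s1$subsample_size, min(floor(10 * sqrt(160)), 159))
  expect_true(all(s1$instability >= 0 & s1$instability <= 0.5))
})

test_that("StARS on independent noise selects an empty or near-empty graph", {
  set.seed(7)
  x <- matrix(rnorm(160 * 10), 160, 10)
  # with no true edges there may be no stable sparse penalty at all, in
  # which case the selector warns and falls back to the empty-graph end
  sel <- tryCatch(stars_select_lambda(x, n_subsamples = 15, seed = 7),
                  warning = function(w) {
                    expect_match(conditionMessage(w), "instability bound")
                    suppressWarnings(stars_select_lambda(x, n_subsamples = 15,
                                                         seed = 7))
                  })
  fit <- glasso_fit(cor(x), sel$lambda)
  n_edges <- sum(fit$precision[upper.tri(fit$precision)] != 0)
  expect_lte(n_edges, 2)
})

test_that("partial correlations have the right sign, scale and sparsity", {
  om <- chain_precision(5, 0.4)
  pc <- precision_to_partial_corr(om)
  expect_equal(pc$values[1, 2], -0.4, tolerance = 1e-12)
  expect_identical(pc$values[1, 3], 0)
  expect_true(all(diag(pc$values) == 0))
  # unregularised sample version approaches the truth at large T
  x <- rmvn_from_precision(20000, om, seed = 8)
  spc <- sample_partial_corr(x)
  expect_lt(max(abs(spc$values - pc$values)), 0.05)
  expect_error(sample_partial_corr(matrix(rnorm(20), 4, 5)), "more time points")
})

test_that("full pFC pipeline recovers a chain support from ample data", {
  om <- chain_precision(8, 0.45)
  x <- rmvn_from_precision(800, om, seed = 9)
  est <- estimate_pfc(x, seed = 9, n_subsamples = 20)
  expect_s3_class(est$pfc, "connectivity_matrix")
  expect_gt(support_f1(est$pfc$values, om - diag(8)), 0.9)
  g <- threshold_pfc_network(est$pfc, tau = 1e-5)
  expect_true(all(g$weights >= 0))
})
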