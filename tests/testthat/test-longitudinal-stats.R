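test_that("repeated-measures ANOVA matches the aov error decomposition", {
  set.seed(1)
  n <- 8; k <- 4
  Y <- matrix(rnorm(n * k), n, k,
              dimnames = list(sprintf("s%d", 1:n), sprintf("t%d", 1:k)))
  res <- rm_anova_oneway(Y)
  d <- data.frame(y = as.vector(Y),
                  subj = factor(rep(rownames(Y), k)),
                  sess = factor(rep(colnames(Y), each = n)))
  fit <- summary(stats::aov(y ~ sess + Error(subj / sess), data = d))
  tab <- fit[["Error: subj:sess"]][[1]]
  expect_equal(res$F, tab["sess", "F value"], tolerance = 1e-10)
  expect_equal(res$p_uncorrected, tab["sess", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(res$ss_sessions, tab["sess", "Sum Sq"], tolerance = 1e-10)
  expect_equal(res$ss_error, tab["Residuals", "Sum Sq"], tolerance = 1e-10)
  expect_equal(res$df, c(k - 1, (k - 1) * (n - 1)))
})

test_that("sphericity epsilons respect their bounds and the two-session identity", {
  set.seed(2)
  Y <- matrix(rnorm(24), 8, 3)
  res <- rm_anova_oneway(Y)
  expect_gte(res$epsilon_gg, 1 / 2)
  expect_lte(res$epsilon_gg, 1)
  expect_gte(res$epsilon_hf, res$epsilon_gg)  # HF is the less severe correction
  # with two sessions sphericity holds trivially: epsilon = 1
  res2 <- rm_anova_oneway(Y[, 1:2])
  expect_equal(res2$epsilon_gg, 1)
  expect_equal(res2$epsilon_hf, 1)
  expect_error(rm_anova_oneway(matrix(c(1, 2, NA, 4), 2)), "incomplete")
})

test_that("ANOVA is invariant to subject shifts and session relabelling", {
  set.seed(3)
  Y <- matrix(rnorm(32), 8, 4)
  base <- rm_anova_oneway(Y)
  shifted <- Y + rnorm(8)  # per-subject constant absorbed by the blocks
  expect_equal(rm_anova_oneway(shifted)$F, base$F, tolerance = 1e-9)
  perm <- Y[, c(3, 1, 4, 2)]
  expect_equal(rm_anova_oneway(perm)$F, base$F, tolerance = 1e-9)
})

test_that("Tukey HSD uses the studentized range with the within-subject error", {
  set.seed(4)
  Y <- matrix(rnorm(24, mean = rep(c(0, 1, 0), each = 8)), 8, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  an <- rm_anova_oneway(Y)
  tk <- tukey_hsd(Y, an)
  expect_equal(nrow(tk), 3)
  i <- which(tk$session_a == "a" & tk$session_b == "b")
  q_manual <- abs(mean(Y[, 1]) - mean(Y[, 2])) / sqrt(an$ms_error / 8)
  expect_equal(tk$q[i], q_manual, tolerance = 1e-12)
  expect_equal(tk$p_adj[i],
               ptukey(q_manual, nmeans = 3, df = 14, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(all(tk$p_adj >= 0 & tk$p_adj <= 1))
})

test_that("BH step-up matches the definition and p.adjust", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.21, 0.5)
  res <- bh_fdr(p, q = 0.05)
  # largest i with p_(i) <= i q / m is i = 5 (0.042 <= 0.025? no...)
  m <- length(p)
  brute <- rep(FALSE, m)
  io <- order(p)
  ks <- which(p[io] <= seq_len(m) * 0.05 / m)
  if (length(ks)) brute[io[seq_len(max(ks))]] <- TRUE
  expect_identical(res$reject, brute)
  expect_equal(res$p_adjusted, p.adjust(p, "BH"), tolerance = 1e-12)
  expect_equal(res$critical_p, max(p[brute]))
  na_res <- bh_fdr(c(0.01, NA, 0.9))
  expect_identical(na_res$reject[2], FALSE)
})

test_that("mixed model recovers a known fixed effect with subject heterogeneity", {
  set.seed(6)
  n_sub <- 10; n_obs <- 4
  subj <- rep(sprintf("s%02d", 1:n_sub), each = n_obs)
  score <- rnorm(n_sub * n_obs, 2, 1)
  u <- rep(rnorm(n_sub, sd = 1), each = n_obs)
  y <- 1 + 0.5 * score + u + rnorm(n_sub * n_obs, sd = 0.3)
  tab <- longitudinal_table(subj, rep(sprintf("t%d", 1:n_obs), n_sub), y,
                            action_score = score)
  fit <- lmm_fit(tab, fixed_terms = "action_score")
  expect_lt(abs(fit$beta[["action_score"]] - 0.5), 0.15)
  expect_false(fit$degenerate)
  expect_gt(fit$sigma2_subject, 0.2)
  # matches a direct lmerTest fit
  d <- data.frame(value = y, subject_id = subj, action_score = score)
  ref <- lmerTest::lmer(value ~ action_score + (1 | subject_id), data = d)
  expect_equal(unname(fit$beta), unname(lme4::fixef(ref)), tolerance = 1e-8)
  expect_error(lmm_fit(tab, fixed_terms = "missing_col"), "not in table")
})

test_that("bundled tremor scores are complete, ordinal, and reproduce the published layout", {
  d <- crst_example_scores()
  expect_equal(nrow(d), 24)  # 8 patients x 3 assessment points
  expect_true(all(d$action %in% 0:4) && all(d$posture %in% 0:4))
  expect_identical(levels(d$session_id), c("pre", "post7d", "post3m"))
  expect_equal(length(unique(d$subject_id)), 8)
  # tremor improves after treatment in the great majority of patients
  wide <- table_to_matrix(longitudinal_table(d$subject_id, d$session_id,
                                             d$action))
  expect_gte(sum(wide[, "post7d"] < wide[, "pre"]), 7)
})
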