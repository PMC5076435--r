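#' Build a longitudinal table
#'
#' Tidy subject x session table of one outcome, optionally with clinical
#' score covariates, the input format for the statistical layer.
#'
#' @param subject_id,session_id,value equal-length vectors; `session_id` is
#'   coerced to an ordered factor in order of first appearance unless
#'   already a factor.
#' @param action_score,posture_score optional covariates.
#' @return `data.frame` of class `longitudinal_table`.
#' @export
longitudinal_table <- function(subject_id, session_id, value,
                               action_score = NULL, posture_score = NULL) {
  if (!is.factor(session_id))
    session_id <- factor(session_id, levels = unique(session_id))
  d <- data.frame(subject_id = as.character(subject_id),
                  session_id = session_id, value = as.numeric(value),
                  stringsAsFactors = FALSE)
  if (!is.null(action_score)) d$action_score <- as.numeric(action_score)
  if (!is.null(posture_score)) d$posture_score <- as.numeric(posture_score)
  class(d) <- c("longitudinal_table", "data.frame")
  d
}

table_to_matrix <- function(table) {
  subjects <- unique(table$subject_id)
  sessions <- levels(table$session_id)
  Y <- matrix(NA_real_, length(subjects), length(sessions),
              dimnames = list(subjects, sessions))
  for (i in seq_len(nrow(table)))
    Y[table$subject_id[i], as.character(table$session_id[i])] <- table$value[i]
  Y
}

#' One-way repeated-measures ANOVA with sphericity corrections
#'
#' Subjects-as-blocks decomposition: `SS_total = SS_sessions + SS_subjects
#' + SS_error`, `F = MS_sessions / MS_error` with uncorrected df
#' `(k - 1, (k - 1)(n - 1))`. The Greenhouse-Geisser epsilon is estimated
#' from the sample covariance of the session vectors and the Huynh-Feldt
#' epsilon derived from it; p-values are reported at uncorrected,
#' GG-corrected and HF-corrected df (epsilon-scaled).
#'
#' @param table a [longitudinal_table()] (complete crossing required) or a
#'   subjects x sessions numeric matrix.
#' @return List of class `rm_anova`: sums of squares, df (uncorrected and
#'   corrected), `F`, `epsilon_gg`, `epsilon_hf`, `p_uncorrected`, `p_gg`,
#'   `p_hf`, `ms_error`, session `means` and `sds`, `n_subjects`.
#' @export
rm_anova_oneway <- function(table) {
  Y <- if (is.matrix(table)) table else table_to_matrix(table)
  if (anyNA(Y)) {
    miss <- which(is.na(Y), arr.ind = TRUE)
    stop("incomplete crossing; missing cells: ",
         paste(sprintf("%s/%s", rownames(Y)[miss[, 1]],
                       colnames(Y)[miss[, 2]]), collapse = ", "))
  }
  n <- nrow(Y); k <- ncol(Y)
  stopifnot(n >= 2, k >= 2)
  gm <- mean(Y)
  ss_sessions <- n * sum((colMeans(Y) - gm)^2)
  ss_subjects <- k * sum((rowMeans(Y) - gm)^2)
  ss_total <- sum((Y - gm)^2)
  ss_error <- ss_total - ss_sessions - ss_subjects
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_error <- ss_error / df2
  if (ms_error <= .Machine$double.eps * max(1, abs(gm))) {
    warning("zero within-subject error variance; F is infinite (exact ties)")
    Fstat <- if (ss_sessions > 0) Inf else 0
  } else Fstat <- (ss_sessions / df1) / ms_error

  # Greenhouse-Geisser epsilon from the session covariance matrix
  S <- cov(Y)
  mS <- mean(S); rowm <- rowMeans(S)
  num <- (k * (mean(diag(S)) - mS))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowm^2) + k^2 * mS^2)
  eps_gg <- if (den > 0) num / den else 1
  eps_gg <- min(1, max(1 / (k - 1), eps_gg))
  # Huynh-Feldt correction of the GG estimate
  eps_hf <- (n * df1 * eps_gg - 2) / (df1 * (n - 1 - df1 * eps_gg))
  eps_hf <- min(1, max(1 / (k - 1), eps_hf))

  pval <- function(eps) {
    if (!is.finite(Fstat)) return(if (Fstat > 0) 0 else 1)
    pf(Fstat, df1 * eps, df2 * eps, lower.tail = FALSE)
  }
  structure(list(
    ss_sessions = ss_sessions, ss_subjects = ss_subjects,
    ss_error = ss_error, ss_total = ss_total,
    df = c(df1, df2),
    df_gg = c(df1 * eps_gg, df2 * eps_gg),
    df_hf = c(df1 * eps_hf, df2 * eps_hf),
    F = Fstat, epsilon_gg = eps_gg, epsilon_hf = eps_hf,
    p_uncorrected = pval(1), p_gg = pval(eps_gg), p_hf = pval(eps_hf),
    ms_error = ms_error,
    means = colMeans(Y), sds = apply(Y, 2, sd),
    n_subjects = n, n_sessions = k), class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("repeated-measures ANOVA: F(%g, %g) = %.2f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p_uncorrected))
  cat(sprintf("  GG: eps = %.3f, F(%.2f, %.2f), p = %.4g\n",
              x$epsilon_gg, x$df_gg[1], x$df_gg[2], x$p_gg))
  cat(sprintf("  HF: eps = %.3f, F(%.2f, %.2f), p = %.4g\n",
              x$epsilon_hf, x$df_hf[1], x$df_hf[2], x$p_hf))
  invisible(x)
}

#' Tukey HSD post hoc comparisons between sessions
#'
#' For every session pair, the studentized-range statistic
#' `q = |mean difference| / sqrt(MS_error / n)` with the within-subject
#' `MS_error` and `df_error = (k - 1)(n - 1)` from the repeated-measures
#' ANOVA; p-values from the studentized-range distribution with `k` groups.
#'
#' @param table the [longitudinal_table()] (or matrix) the ANOVA was run on.
#' @param anova the matching [rm_anova_oneway()] result.
#' @return `data.frame`: `session_a`, `session_b`, `diff` (a minus b), `q`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(table, anova) {
  stopifnot(inherits(anova, "rm_anova"))
  Y <- if (is.matrix(table)) table else table_to_matrix(table)
  n <- nrow(Y); k <- ncol(Y)
  stopifnot(n == anova$n_subjects, k == anova$n_sessions)
  m <- colMeans(Y)
  se <- sqrt(anova$ms_error / n)
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    session_a = colnames(Y)[pairs[1, ]],
    session_b = colnames(Y)[pairs[2, ]],
    diff = m[pairs[1, ]] - m[pairs[2, ]],
    stringsAsFactors = FALSE)
  out$q <- abs(out$diff) / se
  out$p_adj <- ptukey(out$q, nmeans = k, df = anova$df[2],
                      lower.tail = FALSE)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR step-up
#'
#' Sorts p-values ascending, finds the largest `i` with
#' `p_(i) <= i * q / m`, and rejects all hypotheses at or below it.
#'
#' @param p_values numeric vector in `[0, 1]` (`NA` allowed, never
#'   rejected).
#' @param q FDR level.
#' @return List: `reject` (logical, in input order), `critical_p` (largest
#'   rejected p-value, 0 if none), `p_adjusted` (BH-adjusted p-values).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  padj <- p.adjust(p_values, method = "BH")
  reject <- !is.na(padj) & padj <= q
  critical_p <- if (any(reject)) max(p_values[reject]) else 0
  list(reject = reject, critical_p = critical_p, p_adjusted = padj)
}

#' Random-intercept linear mixed model for longitudinal outcomes
#'
#' Fits `value ~ fixed terms + (1 | subject)` by REML, the standard model
#' for relating a network property to clinical scores with patients as
#' random effects. Per-fixed-effect F statistics use the Satterthwaite
#' denominator-df approximation.
#'
#' @param table a [longitudinal_table()] (incomplete crossings allowed).
#' @param fixed_terms character vector of fixed-effect column names in
#'   `table` (e.g. `c("time", "action_score")`); interactions may be given
#'   as `"time:action_score"`.
#' @return List of class `lmm_fit`: `beta` (fixed effects), `se`,
#'   `df_satterthwaite` (per coefficient), `sigma2_subject`,
#'   `sigma2_residual`, `reml_loglik`, `anova` (per-term F table),
#'   `degenerate` (TRUE when the subject variance collapses to ~0),
#'   `model` (the underlying fit).
#' @export
lmm_fit <- function(table, fixed_terms = c("action_score")) {
  d <- as.data.frame(table)
  stopifnot(all(c("subject_id", "value") %in% names(d)))
  base_vars <- unique(unlist(strsplit(fixed_terms, ":", fixed = TRUE)))
  missing_vars <- setdiff(base_vars, names(d))
  if (length(missing_vars))
    stop("fixed-effect columns not in table: ",
         paste(missing_vars, collapse = ", "))
  d <- d[complete.cases(d[, c("subject_id", "value", base_vars)]), ]
  if (length(unique(d$subject_id)) < 2 || nrow(d) < 4)
    stop("need >= 2 observations for >= 2 subjects")
  fml <- stats::as.formula(paste(
    "value ~", paste(fixed_terms, collapse = " + "), "+ (1 | subject_id)"))
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(fml, data = d, REML = TRUE)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_subject <- vc$vcov[vc$grp == "subject_id"]
  sigma2_residual <- vc$vcov[vc$grp == "Residual"]
  cf <- stats::coef(summary(fit))  # lmerTest: Estimate, SE, df, t, p
  aov_tab <- suppressMessages(stats::anova(fit))  # Satterthwaite type III
  structure(list(
    beta = cf[, "Estimate"], se = cf[, "Std. Error"],
    df_satterthwaite = cf[, "df"], t = cf[, "t value"],
    p = cf[, "Pr(>|t|)"],
    sigma2_subject = sigma2_subject, sigma2_residual = sigma2_residual,
    reml_loglik = as.numeric(stats::logLik(fit)),
    anova = as.data.frame(aov_tab),
    degenerate = sigma2_subject < 1e-8 * max(sigma2_residual, 1e-12),
    model = fit), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("random-intercept linear mixed model (REML)\n")
  cat(sprintf("  subject variance %.4g, residual variance %.4g%s\n",
              x$sigma2_subject, x$sigma2_residual,
              if (x$degenerate) " [random effect degenerate]" else ""))
  tab <- data.frame(beta = x$beta, se = x$se, df = x$df_satterthwaite,
                    t = x$t, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Demographic tremor scores of the emulated eight-patient cohort
#'
#' Right-hand CRST Part A postural and action scores (ordinal 0-4) for
#' eight essential-tremor patients treated with unilateral focused-
#' ultrasound thalamotomy, at the pre-operative baseline and 7 days and 3
#' months after treatment (no scores were collected at the day-1 scan).
#' This is the published demographic table of the study design the
#' synthetic cohort emulates, and the reference input for the behavioral
#' repeated-measures analysis.
#'
#' @return `data.frame`: `subject_id`, `session_id` (ordered factor
#'   pre/post7d/post3m), `posture`, `action`.
#' @export
crst_example_scores <- function() {
  path <- system.file("extdata", "crst_scores.tsv", package = "longconn")
  d <- read.delim(path, stringsAsFactors = FALSE)
  d$session_id <- factor(d$session_id, levels = c("pre", "post7d", "post3m"))
  d
}
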