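#' Validate a cohort directory
#'
#' Checks file presence, consistent node labels and order across sessions,
#' consistent row counts, ordinal score ranges, and completeness of the
#' atlas homotopic pairing. Never throws for content problems; everything
#' is collected into a machine-readable report.
#'
#' @param dir cohort directory (layout of [write_cohort()]).
#' @return List of class `cohort_report`: `ok` (logical) and `failures`
#'   (character vector, empty when valid).
#' @export
validate_cohort <- function(dir) {
  failures <- character(0)
  note <- function(...) failures <<- c(failures, sprintf(...))
  for (f in c("atlas.json", "scores.tsv"))
    if (!file.exists(file.path(dir, f))) note("missing file: %s", f)
  if (length(failures))
    return(structure(list(ok = FALSE, failures = failures),
                     class = "cohort_report"))
  atlas <- jsonlite::read_json(file.path(dir, "atlas.json"),
                               simplifyVector = TRUE)
  scores <- read.delim(file.path(dir, "scores.tsv"), stringsAsFactors = FALSE)
  for (col in c("action", "posture")) {
    bad <- scores[[col]] < 0 | scores[[col]] > 4 |
      scores[[col]] != round(scores[[col]])
    if (any(bad)) note("score out of ordinal range 0-4: %s, rows %s", col,
                       paste(which(bad), collapse = ","))
  }
  pair <- as.integer(atlas$homotopic_pair)
  paired <- which(!is.na(pair))
  if (length(paired) && any(pair[pair[paired]] != paired))
    note("atlas homotopic pairing is not an involution")

  session_ids <- unique(scores$session_id)
  subject_ids <- unique(scores$subject_id)
  nrows <- NULL
  for (sid in subject_ids) for (sess in session_ids) {
    tsf <- session_file(dir, sid, sess, "timeseries")
    nuf <- session_file(dir, sid, sess, "nuisance")
    if (!file.exists(tsf)) { note("missing time series: %s/%s", sid, sess); next }
    if (!file.exists(nuf)) note("missing nuisance set: %s/%s", sid, sess)
    hdr <- names(read.delim(tsf, nrows = 1, check.names = FALSE))
    if (!identical(hdr, as.character(atlas$node_labels)))
      note("node labels/order mismatch in %s/%s", sid, sess)
    nr <- nrow(read.delim(tsf, check.names = FALSE))
    if (is.null(nrows)) nrows <- nr
    else if (nr != nrows) note("row count %d != %d in %s/%s", nr, nrows, sid, sess)
  }
  structure(list(ok = length(failures) == 0, failures = failures),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  if (x$ok) cat("cohort valid\n")
  else cat("cohort INVALID:\n", paste(" -", x$failures, collapse = "\n"), "\n")
  invisible(x)
}

#' Pipeline configuration
#'
#' @param cohort_dir cohort directory.
#' @param out_dir output directory.
#' @param subnetworks named list of node-label vectors analysed as
#'   subnetworks (e.g. the motor-tremor network).
#' @param n_discard,cutoff_hz preprocessing options.
#' @param fc_q FDR level for positive-FC thresholding.
#' @param pfc_tau partial-correlation threshold.
#' @param run_pfc logical; estimate sparse partial-correlation networks
#'   (the expensive StARS + graphical-lasso stage).
#' @param stars_subsamples,stars_beta StARS settings.
#' @param seed master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_dir, out_dir,
                            subnetworks = list(),
                            n_discard = 5L, cutoff_hz = 0.009,
                            fc_q = 0.05, pfc_tau = 1e-5,
                            run_pfc = TRUE, stars_subsamples = 20L,
                            stars_beta = 0.05, seed = 1L) {
  structure(list(cohort_dir = cohort_dir, out_dir = out_dir,
                 subnetworks = subnetworks, n_discard = n_discard,
                 cutoff_hz = cutoff_hz, fc_q = fc_q, pfc_tau = pfc_tau,
                 run_pfc = run_pfc, stars_subsamples = stars_subsamples,
                 stars_beta = stars_beta, seed = seed),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML or JSON file
#' @param path configuration file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full longitudinal connectome pipeline
#'
#' Orchestrates, per subject and session: temporal preprocessing, FC
#' (Pearson + Fisher z + positive-edge FDR thresholding) and optionally
#' pFC (graphical lasso + StARS + constrained-MLE refit + fixed threshold)
#' for the whole atlas and every configured subnetwork; computes nodal and
#' network graph metrics into a tidy table; then runs the longitudinal
#' statistics (repeated-measures ANOVA with sphericity corrections, Tukey
#' HSD, BH-FDR across nodes, random-intercept mixed models against the
#' clinical scores) per metric. Stage outputs are files under `out_dir`, a
#' JSON manifest with per-file digests is written last.
#'
#' @param config a [pipeline_config()] (or path to a YAML/JSON one).
#' @return Invisibly, a list with `metrics` (tidy data.frame), `stats`
#'   (per-metric results), `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  report <- validate_cohort(config$cohort_dir)
  if (!report$ok)
    stop("cohort validation failed:\n", paste("-", report$failures,
                                              collapse = "\n"))
  cohort <- read_cohort(config$cohort_dir)
  atlas <- cohort$atlas
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  scopes <- c(list(whole = atlas$node_labels), config$subnetworks)
  for (sc in names(config$subnetworks)) {
    missing <- setdiff(config$subnetworks[[sc]], atlas$node_labels)
    if (length(missing))
      stop("subnetwork ", sc, " has labels not in the atlas: ",
           paste(missing, collapse = ", "))
  }

  metrics <- list()
  stream <- 0L
  for (sid in names(cohort$subjects)) {
    for (sess in cohort$session_ids) {
      stream <- stream + 1L
      rec <- cohort$subjects[[sid]][[sess]]
      clean <- withCallingHandlers(
        preprocess_session(rec$time_series, rec$nuisance,
                           n_discard = config$n_discard,
                           cutoff_hz = config$cutoff_hz),
        warning = function(w) {
          warnings_log <<- c(warnings_log,
                             paste0(sid, "/", sess, ": ", conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      sdir <- file.path(config$out_dir, sid)
      dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
      write.table(clean$values,
                  file.path(sdir, sprintf("ses-%s_clean.tsv", sess)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      T_eff <- nrow(clean$values)

      fc_full <- pearson_fc(clean)
      write_matrix_tsv(fc_full$values,
                       file.path(sdir, sprintf("ses-%s_fc.tsv", sess)))
      pfc_full <- NULL
      if (config$run_pfc) {
        pfc_full <- estimate_pfc(clean,
                                 seed = child_seed(config$seed, stream),
                                 n_subsamples = config$stars_subsamples,
                                 beta = config$stars_beta)$pfc
        write_matrix_tsv(pfc_full$values,
                         file.path(sdir, sprintf("ses-%s_pfc.tsv", sess)))
      }

      for (scope in names(scopes)) {
        nodes <- scopes[[scope]]
        fc <- if (scope == "whole") fc_full else subnetwork(fc_full, nodes)
        g_fc <- withCallingHandlers(
          fdr_threshold_network(fc, t_effective = T_eff, q = config$fc_q),
          warning = function(w) {
            warnings_log <<- c(warnings_log,
                               paste0(sid, "/", sess, "/", scope, ": ",
                                      conditionMessage(w)))
            invokeRestart("muffleWarning")
          })
        metrics[[length(metrics) + 1]] <-
          metric_rows(sid, sess, scope, "FC", g_fc, fc, atlas)
        if (!is.null(pfc_full)) {
          pfc <- if (scope == "whole") pfc_full else subnetwork(pfc_full, nodes)
          g_pfc <- threshold_pfc_network(pfc, tau = config$pfc_tau)
          metrics[[length(metrics) + 1]] <-
            metric_rows(sid, sess, scope, "pFC", g_pfc, pfc, atlas)
        }
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  write.table(metrics, file.path(config$out_dir, "metrics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  stats <- withCallingHandlers(
    pipeline_stats(metrics, cohort$scores),
    warning = function(w) {
      warnings_log <<- c(warnings_log,
                         paste0("stats: ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  write.table(stats$network_table,
              file.path(config$out_dir, "stats_network.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(stats$nodal_table,
              file.path(config$out_dir, "stats_nodal.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    config = unclass(config),
    version = as.character(utils::packageVersion("longconn")),
    warnings = warnings_log,
    digests = as.list(tools::md5sum(sort(files))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(metrics = metrics, stats = stats, manifest = manifest))
}

metric_rows <- function(sid, sess, scope, kind, g, m, atlas) {
  deg <- node_degree(g); str_ <- node_strength(g); pl <- nodal_path_length(g)
  sub_atlas <- atlas
  if (scope != "whole") {
    # similarity needs the full homotopic pairing; only defined whole-brain
    sub_atlas <- NULL
  }
  ns <- network_summary(g, m = m, atlas = sub_atlas)
  nodal <- data.frame(
    subject = sid, session = sess, scope = scope, kind = kind,
    metric = rep(c("degree", "strength", "path_length"), each = length(deg)),
    node = rep(names(deg), 3),
    value = c(deg, str_, pl), stringsAsFactors = FALSE)
  net <- data.frame(
    subject = sid, session = sess, scope = scope, kind = kind,
    metric = c("average_degree", "average_strength", "global_efficiency",
               "interhemispheric_similarity"),
    node = "network",
    value = c(ns$average_degree, ns$average_strength, ns$global_efficiency,
              ns$interhemispheric_similarity), stringsAsFactors = FALSE)
  rbind(nodal, net)
}

pipeline_stats <- function(metrics, scores) {
  scores$time <- as.numeric(factor(scores$session_id,
                                   levels = unique(scores$session_id))) - 1
  network_rows <- metrics[metrics$node == "network" & !is.na(metrics$value), ]
  net_out <- list()
  for (key in unique(paste(network_rows$scope, network_rows$kind,
                           network_rows$metric))) {
    parts <- strsplit(key, " ")[[1]]
    d <- network_rows[network_rows$scope == parts[1] &
                        network_rows$kind == parts[2] &
                        network_rows$metric == parts[3], ]
    merged <- merge(d, scores, by.x = c("subject", "session"),
                    by.y = c("subject_id", "session_id"))
    tab <- longitudinal_table(merged$subject, merged$session, merged$value,
                              action_score = merged$action,
                              posture_score = merged$posture)
    res <- tryCatch({
      an <- rm_anova_oneway(tab)
      tk <- tukey_hsd(tab, an)
      lm_a <- lmm_fit(cbind(tab, time = merged$time),
                      fixed_terms = c("time", "action_score"))
      lm_p <- lmm_fit(cbind(tab, time = merged$time),
                      fixed_terms = c("time", "posture_score"))
      data.frame(scope = parts[1], kind = parts[2], metric = parts[3],
                 F = an$F, df1 = an$df[1], df2 = an$df[2],
                 p_uncorrected = an$p_uncorrected, p_gg = an$p_gg,
                 epsilon_gg = an$epsilon_gg,
                 min_tukey_p = min(tk$p_adj),
                 action_beta = unname(lm_a$beta["action_score"]),
                 action_p = unname(lm_a$p["action_score"]),
                 posture_beta = unname(lm_p$beta["posture_score"]),
                 posture_p = unname(lm_p$p["posture_score"]),
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(scope = parts[1], kind = parts[2], metric = parts[3],
                 F = NA, df1 = NA, df2 = NA, p_uncorrected = NA, p_gg = NA,
                 epsilon_gg = NA, min_tukey_p = NA, action_beta = NA,
                 action_p = NA, posture_beta = NA, posture_p = NA,
                 stringsAsFactors = FALSE))
    net_out[[key]] <- res
  }
  network_table <- do.call(rbind, net_out)

  nodal_rows <- metrics[metrics$node != "network", ]
  nod_out <- list()
  for (key in unique(paste(nodal_rows$scope, nodal_rows$kind,
                           nodal_rows$metric))) {
    parts <- strsplit(key, " ")[[1]]
    d <- nodal_rows[nodal_rows$scope == parts[1] &
                      nodal_rows$kind == parts[2] &
                      nodal_rows$metric == parts[3], ]
    per_node <- lapply(split(d, d$node), function(dn) {
      if (any(is.na(dn$value))) return(NULL)
      tab <- longitudinal_table(dn$subject, dn$session, dn$value)
      an <- tryCatch(rm_anova_oneway(tab), error = function(e) NULL)
      if (is.null(an)) return(NULL)
      data.frame(scope = parts[1], kind = parts[2], metric = parts[3],
                 node = dn$node[1], F = an$F, p_uncorrected = an$p_uncorrected,
                 p_gg = an$p_gg, stringsAsFactors = FALSE)
    })
    per_node <- do.call(rbind, per_node)
    if (!is.null(per_node) && nrow(per_node)) {
      fdr <- bh_fdr(per_node$p_gg)
      per_node$significant_fdr <- fdr$reject
      nod_out[[key]] <- per_node
    }
  }
  nodal_table <- do.call(rbind, nod_out)
  rownames(network_table) <- rownames(nodal_table) <- NULL
  list(network_table = network_table, nodal_table = nodal_table)
}

#' Classify longitudinal edge trajectories as persistent or transient
#'
#' Given group-mean connectivity matrices per session (baseline first,
#' acute post-operative session second), each edge is classified by
#' comparing its acute deviation `|acute - baseline|` and its late
#' deviation `|mean(later sessions) - baseline|` against a threshold
#' `delta`: `"persistent"` when the late deviation exceeds `delta`,
#' `"transient"` when only the acute deviation does (the edge returns to
#' baseline), `"stable"` otherwise. Deviations are taken in absolute value
#' so that attenuation of negative and positive couplings is treated alike.
#'
#' @param session_means 3-D array `n x n x k` of group-mean connectivity
#'   (k sessions in chronological order, baseline first).
#' @param delta classification threshold, a scalar or an `n x n` matrix of
#'   per-edge thresholds; when `NULL` it is set per edge to `3 * standard
#'   error of the group mean` estimated from `subject_values` (floored at
#'   the median standard error so near-degenerate edges do not fire).
#' @param subject_values optional 4-D array `n x n x k x n_subjects` of
#'   per-subject matrices used to estimate the threshold.
#' @return Character matrix `n x n` (diagonal `"stable"`), plus the
#'   threshold used as attribute `"delta"`.
#' @export
classify_edge_trajectories <- function(session_means, delta = NULL,
                                       subject_values = NULL) {
  stopifnot(length(dim(session_means)) == 3, dim(session_means)[3] >= 3)
  k <- dim(session_means)[3]
  b <- session_means[, , 1]
  acute <- session_means[, , 2]
  late <- apply(session_means[, , 3:k, drop = FALSE], c(1, 2), mean)
  if (is.null(delta)) {
    if (is.null(subject_values))
      stop("supply either delta or subject_values to estimate it")
    nsub <- dim(subject_values)[4]
    se <- apply(subject_values, c(1, 2, 3), sd)[, , 1] / sqrt(nsub)
    delta <- 3 * pmax(se, median(se[upper.tri(se)]))
  }
  dev_acute <- abs(acute - b)
  dev_late <- abs(late - b)
  cls <- matrix("stable", nrow(b), ncol(b), dimnames = dimnames(b))
  cls[dev_late > delta] <- "persistent"
  cls[dev_acute > delta & dev_late <= delta] <- "transient"
  diag(cls) <- "stable"
  attr(cls, "delta") <- delta
  cls
}

#' Classify the longitudinal trajectory of an edge set
#'
#' Set-level counterpart of [classify_edge_trajectories()], designed for
#' small cohorts where single edges are underpowered. For every subject and
#' session the mean absolute connectivity over the edge set is computed,
#' then paired within-subject contrasts against baseline give an acute
#' deviation (second session minus baseline) and a late deviation (mean of
#' the remaining sessions minus baseline), each summarised as a one-sample
#' t statistic across subjects. The pairing removes stable between-subject
#' differences in overall connectivity strength, which would otherwise
#' dominate the standard error at this sample size.
#'
#' Decision rule: if neither |t| exceeds `crit` the set is `"stable"`. If
#' the late deviation is significant *and* its mean magnitude is at least
#' half the acute mean magnitude, the change has not meaningfully receded
#' and the set is `"persistent"`. Otherwise a significant acute deviation
#' makes it `"transient"` (the set moved and then returned towards
#' baseline); a significant late deviation alone, with a small magnitude
#' relative to the acute one, is still classified `"persistent"`. The
#' magnitude comparison matters because a perturbation that truly reverts
#' can leave a small but statistically detectable late residual (estimation
#' coupling with other, persistent changes elsewhere in the network); the
#' trajectory shape — late effect comparable to acute versus late effect
#' collapsed — is what distinguishes the two regimes.
#'
#' @param subject_values 4-D array `n x n x k x n_subjects` of per-subject
#'   connectivity matrices, sessions in chronological order with baseline
#'   first (k >= 3).
#' @param edges two-column integer matrix of node-index pairs defining the
#'   set (at least one edge).
#' @param crit t-statistic cutoff (default 2, roughly a two-sided 0.08
#'   level at 7 degrees of freedom).
#' @return Character scalar `"persistent"`, `"transient"` or `"stable"`,
#'   with attributes `"t_acute"`, `"t_late"`, `"mean_acute"`, `"mean_late"`.
#' @export
classify_set_trajectory <- function(subject_values, edges, crit = 2) {
  stopifnot(length(dim(subject_values)) == 4, dim(subject_values)[3] >= 3)
  edges <- as.matrix(edges)
  stopifnot(ncol(edges) == 2, nrow(edges) >= 1)
  k <- dim(subject_values)[3]
  nsub <- dim(subject_values)[4]
  m <- vapply(seq_len(nsub), function(s)
    vapply(seq_len(k), function(j)
      mean(abs(subject_values[, , j, s][edges])), numeric(1)),
    numeric(k))
  d_acute <- m[2, ] - m[1, ]
  d_late <- colMeans(m[3:k, , drop = FALSE]) - m[1, ]
  t_acute <- mean(d_acute) / (sd(d_acute) / sqrt(nsub))
  t_late <- mean(d_late) / (sd(d_late) / sqrt(nsub))
  cls <- if (abs(t_acute) <= crit && abs(t_late) <= crit) "stable"
  else if (abs(t_late) > crit &&
           abs(mean(d_late)) > abs(mean(d_acute)) / 2) "persistent"
  else if (abs(t_acute) > crit) "transient"
  else "persistent"
  structure(cls, t_acute = t_acute, t_late = t_late,
            mean_acute = mean(d_acute), mean_late = mean(d_late))
}
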