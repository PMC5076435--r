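# Plain-text serialisation of cohorts, matrices and graphs. All tables are
# TSV with headers; the atlas and ground-truth sidecar are JSON.

#' Write a numeric matrix as TSV with row and column labels
#' @param m matrix with dimnames.
#' @param path output file.
#' @export
write_matrix_tsv <- function(m, path) {
  d <- data.frame(label = rownames(m), m, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled matrix TSV written by [write_matrix_tsv()]
#' @param path input file.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Export a network graph as an edge list
#' @param g a [network_graph()].
#' @return `data.frame` with `node_a`, `node_b`, `weight` (upper triangle,
#'   present edges only).
#' @export
graph_edge_list <- function(g) {
  stopifnot(inherits(g, "network_graph"))
  w <- g$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  data.frame(node_a = g$node_labels[idx[, 1]],
             node_b = g$node_labels[idx[, 2]],
             weight = w[idx], stringsAsFactors = FALSE)
}

session_file <- function(dir, subject, session, what) {
  file.path(dir, subject, sprintf("ses-%s_%s.tsv", session, what))
}

#' Write a synthetic cohort to a directory tree
#'
#' Layout: `atlas.json`, `scores.tsv` (subject, session, action, posture),
#' `truth.json` (ground-truth sidecar: per-subject per-session precision
#' matrices for parameter-recovery tests), and one directory per subject
#' holding `ses-<id>_timeseries.tsv` (header = node labels, rows = time
#' points) and `ses-<id>_nuisance.tsv`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(cohort$atlas, file.path(out_dir, "atlas.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  sessions <- cohort$lesion$session_ids
  scores <- do.call(rbind, lapply(cohort$subjects, function(s)
    data.frame(subject_id = s$subject_id, session_id = sessions,
               action = s$action_score, posture = s$posture_score,
               stringsAsFactors = FALSE)))
  write.table(scores, file.path(out_dir, "scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  truth_sidecar <- list(
    config = unclass(cohort$config),
    lesion = list(session_ids = sessions,
                  persistent_scale = cohort$lesion$persistent_scale,
                  transient_scale = cohort$lesion$transient_scale,
                  target_node = cohort$lesion$target_node,
                  lesion_module = cohort$lesion$lesion_module,
                  transient_edges = cohort$lesion$transient_edges),
    subjects = lapply(cohort$subjects, function(s)
      list(subject_id = s$subject_id,
           precision = lapply(s$sessions, function(ss) ss$truth$precision))))
  jsonlite::write_json(truth_sidecar, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)

  for (s in cohort$subjects) {
    dir.create(file.path(out_dir, s$subject_id), showWarnings = FALSE)
    for (sess in names(s$sessions)) {
      ts <- s$sessions[[sess]]$time_series
      write.table(ts$values, session_file(out_dir, s$subject_id, sess,
                                          "timeseries"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      nu <- s$sessions[[sess]]$nuisance
      nm <- cbind(nu$motion, nu$motion_derivatives, nu$tissue_components)
      write.table(nm, session_file(out_dir, s$subject_id, sess, "nuisance"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(out_dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @param tr_seconds sampling interval to stamp on the series.
#' @return List with `atlas`, `scores`, `subjects` (per subject: session
#'   list of `time_series` and `nuisance`), `session_ids`.
#' @export
read_cohort <- function(dir, tr_seconds = 2) {
  atlas <- jsonlite::read_json(file.path(dir, "atlas.json"),
                               simplifyVector = TRUE)
  atlas$homotopic_pair <- as.integer(atlas$homotopic_pair)
  scores <- read.delim(file.path(dir, "scores.tsv"),
                       stringsAsFactors = FALSE)
  session_ids <- unique(scores$session_id)
  subject_ids <- unique(scores$subject_id)
  subjects <- lapply(subject_ids, function(sid) {
    sessions <- lapply(session_ids, function(sess) {
      tsfile <- session_file(dir, sid, sess, "timeseries")
      nufile <- session_file(dir, sid, sess, "nuisance")
      if (!file.exists(tsfile)) stop("missing time series for ", sid, "/", sess)
      vals <- as.matrix(read.delim(tsfile, check.names = FALSE))
      nu <- as.matrix(read.delim(nufile, check.names = FALSE))
      list(time_series = session_time_series(vals, tr_seconds = tr_seconds),
           nuisance = structure(
             list(motion = nu[, 1:6, drop = FALSE],
                  motion_derivatives = nu[, 7:12, drop = FALSE],
                  tissue_components = nu[, 13:15, drop = FALSE],
                  labels = colnames(nu)), class = "nuisance_set"))
    })
    names(sessions) <- session_ids
    sessions
  })
  names(subjects) <- subject_ids
  list(atlas = atlas, scores = scores, subjects = subjects,
       session_ids = session_ids)
}
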