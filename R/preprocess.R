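#' Region-level session time series
#'
#' @param values T x n numeric matrix (time points by nodes); column names
#'   are node labels.
#' @param tr_seconds sampling interval (repetition time) in seconds.
#' @param state `"raw"` or `"clean"`.
#' @return Object of class `session_time_series`.
#' @export
session_time_series <- function(values, tr_seconds = 2, state = "raw") {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("time series contains non-finite values")
  state <- match.arg(state, c("raw", "clean"))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("node%03d", seq_len(ncol(values)))
  structure(list(values = values, tr_seconds = tr_seconds,
                 node_labels = colnames(values), state = state),
            class = "session_time_series")
}

#' @export
print.session_time_series <- function(x, ...) {
  cat("session_time_series:", nrow(x$values), "time points x",
      ncol(x$values), "nodes, TR =", x$tr_seconds, "s, state =", x$state, "\n")
  invisible(x)
}

#' First-eigenvariate summary of a region's voxel time series
#'
#' Returns the first principal-component ("mode") time series of a set of
#' voxel series, the standard region summary that is more robust to
#' heterogeneous voxels than the plain mean. Voxel series are demeaned
#' before the decomposition; the output is scaled to unit variance and
#' sign-aligned so that its correlation with the across-voxel mean series is
#' non-negative.
#'
#' @param voxel_by_time voxels x T numeric matrix.
#' @return Numeric vector of length T.
#' @export
extract_eigenvariate <- function(voxel_by_time) {
  m <- as.matrix(voxel_by_time)
  if (nrow(m) < 1 || ncol(m) < 2) stop("need >= 1 voxel and >= 2 time points")
  mc <- m - rowMeans(m)
  if (max(abs(mc)) == 0) stop("all voxel series are constant (zero variance)")
  sv <- svd(mc, nu = 1, nv = 1)
  ev <- as.numeric(sv$v[, 1])
  ev <- ev / sd(ev)
  ref <- colMeans(mc)
  if (sd(ref) > 0 && cor(ev, ref) < 0) ev <- -ev
  ev
}

#' Discard initial volumes of a session
#'
#' Removes the first `n_discard` time points (magnetisation-equilibration
#' volumes); 165 volumes become 160 at the defaults.
#'
#' @param ts a [session_time_series()].
#' @param n_discard number of leading rows to drop.
#' @return A [session_time_series()].
#' @export
discard_initial_scans <- function(ts, n_discard = 5L) {
  stopifnot(inherits(ts, "session_time_series"), n_discard >= 0)
  T_ <- nrow(ts$values)
  if (T_ <= n_discard)
    stop("cannot discard ", n_discard, " scans from a series of length ", T_)
  if (n_discard == 0) return(ts)
  session_time_series(ts$values[-seq_len(n_discard), , drop = FALSE],
                      tr_seconds = ts$tr_seconds, state = ts$state)
}

#' Discrete sine/cosine high-pass regressor set
#'
#' Builds sine and cosine columns at the discrete frequencies
#' `f_k = k / (T * TR)` for all integers `k >= 1` with `f_k <= cutoff_hz`.
#' Regressing these out removes fluctuations at and below the cutoff while
#' deliberately retaining all higher frequencies.
#'
#' @param n_timepoints number of retained time points T.
#' @param tr_seconds sampling interval in seconds.
#' @param cutoff_hz high-pass cutoff (default 0.009 Hz).
#' @return T x K matrix (K = 2 x number of qualifying frequencies); a
#'   zero-column matrix with a warning when no frequency qualifies.
#' @export
build_highpass_regressors <- function(n_timepoints, tr_seconds,
                                      cutoff_hz = 0.009) {
  stopifnot(n_timepoints >= 10, cutoff_hz >= 0)
  kmax <- floor(cutoff_hz * n_timepoints * tr_seconds)
  if (kmax < 1) {
    warning("no discrete frequency at or below the cutoff; returning empty matrix")
    return(matrix(numeric(0), n_timepoints, 0))
  }
  tt <- seq_len(n_timepoints) - 1
  cols <- lapply(seq_len(kmax), function(k) {
    w <- 2 * pi * k * tt / n_timepoints
    cbind(sin(w), cos(w))
  })
  out <- do.call(cbind, cols)
  colnames(out) <- as.vector(t(outer(seq_len(kmax), c("sin", "cos"),
                                     function(k, f) paste0(f, k))))
  out
}

#' Assemble the full nuisance design matrix
#'
#' Concatenates an intercept, orthogonalised linear and quadratic time
#' trends, the six motion parameters, their derivatives, the three tissue
#' components, and (optionally) extra columns such as high-pass regressors.
#' Exactly collinear columns (singular values below `1e-10` relative
#' tolerance) are dropped with a warning.
#'
#' @param nuisance a `nuisance_set` (see [simulate_nuisance()]) or `NULL`.
#' @param n_timepoints required when `nuisance` is `NULL`.
#' @param include_detrend add intercept + linear + quadratic trend columns.
#' @param extra optional additional columns (e.g.
#'   [build_highpass_regressors()] output).
#' @return Design matrix with attribute `"dropped"` naming removed columns.
#' @export
build_nuisance_matrix <- function(nuisance = NULL, n_timepoints = NULL,
                                  include_detrend = TRUE, extra = NULL) {
  if (!is.null(nuisance)) {
    T_ <- nrow(nuisance$motion)
    base <- cbind(nuisance$motion, nuisance$motion_derivatives,
                  nuisance$tissue_components)
  } else {
    stopifnot(!is.null(n_timepoints))
    T_ <- n_timepoints
    base <- matrix(numeric(0), T_, 0)
  }
  if (!is.null(extra)) {
    stopifnot(nrow(extra) == T_)
    base <- cbind(base, extra)
  }
  if (include_detrend) {
    trends <- poly(seq_len(T_), 2)  # orthogonal, zero-mean
    colnames(trends) <- c("trend_linear", "trend_quadratic")
    X <- cbind(intercept = 1, trends, base)
  } else {
    X <- cbind(intercept = 1, base)
  }
  # drop exactly-collinear columns, keeping earlier ones
  qx <- qr(X, tol = 1e-10)
  dropped <- character(0)
  if (qx$rank < ncol(X)) {
    keep <- sort(qx$pivot[seq_len(qx$rank)])
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    warning("dropping collinear design columns: ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  attr(X, "dropped") <- dropped
  X
}

#' Regress a design out of every node series
#'
#' Single ordinary-least-squares projection of each node series onto the
#' combined design; residuals are orthogonal to every design column and the
#' result is marked `"clean"`. All regressors are removed in one projection
#' (order-invariant), not sequentially.
#'
#' @param ts a [session_time_series()].
#' @param design T x K design matrix (must be full column rank).
#' @return A [session_time_series()] of residuals.
#' @export
regress_out <- function(ts, design) {
  stopifnot(inherits(ts, "session_time_series"))
  design <- as.matrix(design)
  if (nrow(design) != nrow(ts$values))
    stop("design has ", nrow(design), " rows but series has ",
         nrow(ts$values))
  if (ncol(design) == 0) return(ts)
  qx <- qr(design, tol = 1e-10)
  if (qx$rank < ncol(design))
    stop("design matrix is rank-deficient; drop collinear columns first")
  res <- qr.resid(qx, ts$values)
  colnames(res) <- colnames(ts$values)
  session_time_series(res, tr_seconds = ts$tr_seconds, state = "clean")
}

#' Full temporal cleaning of one session
#'
#' Convenience wrapper applying the canonical order: discard initial scans,
#' build the combined design (intercept, trends, motion + derivatives +
#' tissue, sine/cosine high-pass at the retained length), and remove it in
#' a single projection.
#'
#' @param ts a [session_time_series()].
#' @param nuisance matching `nuisance_set` (rows are trimmed identically).
#' @param n_discard leading volumes to drop.
#' @param cutoff_hz high-pass cutoff; `NULL` disables the trig regressors.
#' @return Cleaned [session_time_series()].
#' @export
preprocess_session <- function(ts, nuisance = NULL, n_discard = 5L,
                               cutoff_hz = 0.009) {
  ts2 <- discard_initial_scans(ts, n_discard)
  T_ <- nrow(ts2$values)
  nuis2 <- nuisance
  if (!is.null(nuisance)) {
    trim <- function(m) m[-seq_len(n_discard), , drop = FALSE]
    if (n_discard > 0)
      nuis2 <- structure(list(motion = trim(nuisance$motion),
                              motion_derivatives = trim(nuisance$motion_derivatives),
                              tissue_components = trim(nuisance$tissue_components),
                              labels = nuisance$labels),
                         class = "nuisance_set")
  }
  hp <- if (!is.null(cutoff_hz) && cutoff_hz > 0)
    build_highpass_regressors(T_, ts2$tr_seconds, cutoff_hz) else NULL
  X <- build_nuisance_matrix(nuis2, n_timepoints = T_, include_detrend = TRUE,
                             extra = hp)
  regress_out(ts2, X)
}
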