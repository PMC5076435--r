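#' Connectivity matrix container
#'
#' @param values symmetric n x n matrix, diagonal stored as zero.
#' @param kind `"FC_z"` (Fisher-z Pearson correlations, unbounded) or
#'   `"pFC"` (partial correlations in (-1, 1)).
#' @return Object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, kind = c("FC_z", "pFC")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!is_square_symmetric(values, tol = 1e-10))
    stop("connectivity values must be a symmetric square matrix")
  diag(values) <- 0
  if (kind == "pFC" && any(abs(upper_tri_values(values)) >= 1))
    stop("partial correlations must lie strictly inside (-1, 1)")
  if (is.null(colnames(values)))
    colnames(values) <- rownames(values) <- sprintf("node%03d", seq_len(ncol(values)))
  structure(list(values = values, kind = kind,
                 node_labels = colnames(values)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("connectivity_matrix (", x$kind, "): ", ncol(x$values), " nodes\n",
      sep = "")
  invisible(x)
}

#' Thresholded weighted network
#'
#' @param weights n x n non-negative symmetric matrix; zero means no edge.
#' @param kind connectivity kind the weights came from.
#' @param provenance character note recording the threshold rule applied.
#' @return Object of class `network_graph`.
#' @export
network_graph <- function(weights, kind = "FC_z", provenance = "") {
  weights <- as.matrix(weights)
  if (!is_square_symmetric(weights, tol = 1e-10))
    stop("weights must be symmetric")
  if (any(weights < 0)) stop("network weights must be non-negative")
  diag(weights) <- 0
  if (is.null(colnames(weights)))
    colnames(weights) <- rownames(weights) <- sprintf("node%03d", seq_len(ncol(weights)))
  structure(list(weights = weights, kind = kind, provenance = provenance,
                 node_labels = colnames(weights)),
            class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  cat("network_graph (", x$kind, "): ", ncol(x$weights), " nodes, ",
      sum(x$weights[upper.tri(x$weights)] > 0), " edges [",
      x$provenance, "]\n", sep = "")
  invisible(x)
}

#' Pairwise Pearson functional connectivity with Fisher z-transform
#'
#' Computes the Pearson cross-correlation between every pair of node series
#' and maps it through the Fisher z-transform (`atanh`).
#'
#' @param ts a [session_time_series()] (or plain T x n matrix).
#' @return A [connectivity_matrix()] of kind `"FC_z"`.
#' @export
pearson_fc <- function(ts) {
  x <- if (inherits(ts, "session_time_series")) ts$values else as.matrix(ts)
  if (nrow(x) < 3) stop("need at least 3 time points")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("constant node series: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  r <- cor(x)
  fisher_z(r)
}

#' Fisher z-transform of a correlation matrix
#'
#' `Z = atanh(r)` elementwise; the diagonal is set to zero. Off-diagonal
#' correlations of magnitude 1 are degenerate and rejected.
#'
#' @param r_matrix symmetric correlation matrix.
#' @return A [connectivity_matrix()] of kind `"FC_z"`.
#' @export
fisher_z <- function(r_matrix) {
  r <- as.matrix(r_matrix)
  diag(r) <- 0
  if (any(abs(upper_tri_values(r)) >= 1))
    stop("off-diagonal correlation of magnitude 1: degenerate node pair")
  z <- atanh(r)
  connectivity_matrix(z, kind = "FC_z")
}

#' FDR-thresholded positive functional connectivity network
#'
#' Tests each upper-triangle edge for positive correlation using the normal
#' approximation to the Fisher z statistic (`Z * sqrt(T_eff - 3)`), applies
#' Benjamini-Hochberg across all edges at level `q`, and retains surviving
#' positive edges with their z-values as weights.
#'
#' @param z_matrix a [connectivity_matrix()] of kind `"FC_z"`.
#' @param t_effective effective number of time points behind the
#'   correlations.
#' @param q FDR level (default 0.05).
#' @return A [network_graph()]; empty (with a warning) when nothing
#'   survives.
#' @export
fdr_threshold_network <- function(z_matrix, t_effective, q = 0.05) {
  stopifnot(inherits(z_matrix, "connectivity_matrix"),
            z_matrix$kind == "FC_z", t_effective > 3)
  z <- z_matrix$values
  ut <- upper.tri(z)
  stat <- z[ut] * sqrt(t_effective - 3)
  p <- pnorm(stat, lower.tail = FALSE)  # one-sided: r > 0
  rej <- bh_fdr(p, q = q)$reject
  w <- matrix(0, nrow(z), ncol(z), dimnames = dimnames(z))
  keep <- ut
  keep[ut] <- rej & z[ut] > 0
  w[keep] <- z[keep]
  w <- w + t(w)
  if (all(w == 0)) warning("no edge survives FDR thresholding; empty graph")
  network_graph(w, kind = "FC_z",
                provenance = sprintf("positive edges, BH FDR q < %g, T_eff = %g",
                                     q, t_effective))
}

#' Graphical lasso estimate of a sparse precision matrix
#'
#' L1-penalised Gaussian maximum likelihood: maximises
#' `log det(Omega) - tr(S Omega) - lambda * sum_{i != j} |Omega_ij|`
#' (diagonal unpenalised) by block coordinate descent with an inner lasso
#' solved by coordinate-wise soft-thresholding. Convergence is declared when
#' the largest parameter change in a sweep falls below `tol`.
#'
#' @param S symmetric sample covariance (typically a correlation matrix).
#' @param lambda penalty, `>= 0`.
#' @param maxit maximum sweeps (default 500).
#' @param tol convergence tolerance on the max absolute change (default 1e-5).
#' @return List of class `glasso_fit`: `precision` (Omega-hat), `covariance`
#'   (its estimated inverse), `support` (logical edge matrix), `lambda`,
#'   `iterations`.
#' @export
glasso_fit <- function(S, lambda, maxit = 500L, tol = 1e-5) {
  S <- as.matrix(S)
  stopifnot(is_square_symmetric(S, tol = 1e-8), lambda >= 0,
            all(diag(S) > 0))
  fit <- glasso_cd(S, lambda, maxit = maxit, tol = tol)
  if (!fit$converged)
    stop("graphical lasso did not converge: final max change ",
         signif(fit$max_change, 4), " after ", fit$iterations, " sweeps")
  omega <- fit$wi
  dimnames(omega) <- dimnames(S)
  support <- abs(omega) > 1e-10
  diag(support) <- TRUE
  structure(list(precision = omega, covariance = fit$w, support = support,
                 lambda = lambda, iterations = fit$iterations,
                 B = fit$B),
            class = "glasso_fit")
}

#' Penalty-path helper: smallest lambda giving an empty off-diagonal support
#' @param S sample covariance/correlation matrix.
#' @return `max |S_ij|` over `i != j` (the KKT bound for the
#'   diagonal-unpenalised graphical lasso).
#' @export
glasso_lambda_max <- function(S) max(abs(S[upper.tri(S)]))

#' Default 30-point log-spaced penalty grid
#' @param S sample covariance/correlation matrix.
#' @param n_lambda grid size.
#' @param ratio smallest / largest penalty.
#' @return Decreasing numeric vector from `lambda_max` to
#'   `lambda_max * ratio`.
#' @export
glasso_lambda_grid <- function(S, n_lambda = 30L, ratio = 0.01) {
  lmax <- glasso_lambda_max(S)
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

#' StARS penalty selection for the graphical lasso
#'
#' Stability Approach to Regularization Selection: draws `n_subsamples` row
#' subsets of size `floor(10 * sqrt(T))` (capped at T - 1) without
#' replacement, fits the graphical lasso over the penalty grid on each
#' subsample's correlation matrix (warm starts along the path), computes
#' per-edge selection frequencies `theta`, edge instabilities
#' `2 * theta * (1 - theta)`, the mean instability `D(lambda)`, monotonises
#' it from the sparse end (`Dbar(lambda) = max over lambdas >= lambda`), and
#' selects the smallest penalty with `Dbar <= beta`.
#'
#' @param ts a [session_time_series()] or T x n matrix (rows = time).
#' @param lambda_grid decreasing penalty grid; default
#'   [glasso_lambda_grid()] of the full-sample correlation matrix.
#' @param n_subsamples number of subsamples (default 50).
#' @param beta instability bound (default 0.05).
#' @param seed integer seed for the subsampling.
#' @return List of class `stars_selection`: `lambda` (selected),
#'   `lambda_grid`, `instability` (raw D), `instability_monotone` (Dbar),
#'   `subsample_size`.
#' @export
stars_select_lambda <- function(ts, lambda_grid = NULL, n_subsamples = 50L,
                                beta = 0.05, seed = 1L) {
  x <- if (inherits(ts, "session_time_series")) ts$values else as.matrix(ts)
  T_ <- nrow(x); n <- ncol(x)
  stopifnot(T_ >= 20)
  if (is.null(lambda_grid)) lambda_grid <- glasso_lambda_grid(cor(x))
  if (is.unsorted(rev(lambda_grid)))
    stop("lambda_grid must be sorted in decreasing order")
  b <- min(floor(10 * sqrt(T_)), T_ - 1)

  n_off <- n * (n - 1) / 2
  sel_count <- matrix(0, length(lambda_grid), n_off)
  with_seed(seed, {
    for (s in seq_len(n_subsamples)) {
      rows <- sample.int(T_, b)
      Ssub <- cor(x[rows, , drop = FALSE])
      warm <- NULL
      for (li in seq_along(lambda_grid)) {
        fit <- glasso_cd(Ssub, lambda_grid[li], maxit = 500L, tol = 1e-4,
                         warm_B = warm)
        warm <- fit$B
        supp <- abs(fit$wi[upper.tri(fit$wi)]) > 1e-10
        sel_count[li, ] <- sel_count[li, ] + supp
      }
    }
  })
  theta <- sel_count / n_subsamples
  D <- rowMeans(2 * theta * (1 - theta))
  density <- rowMeans(theta)
  # Monotonised instability: running max over coarser-or-equal penalties,
  # anchored at the most stable point of the sparse regime (mean selection
  # frequency <= 0.5). With a clean sparse end (instability ~ 0 at the top
  # of the grid, the usual large-atlas situation) the anchor is the first
  # grid point and this is the canonical rule; on small atlases it keeps
  # edge flicker at the support-vanishing boundary from masking the stable
  # valley, while the running max still blocks the trivially stable dense
  # end.
  sparse_idx <- which(density <= 0.5)
  Dbar <- rep(Inf, length(D))
  sel <- NA_integer_
  if (length(sparse_idx)) {
    i0 <- sparse_idx[which.min(D[sparse_idx])]
    Dbar[i0:length(D)] <- cummax(D[i0:length(D)])
    Dbar[seq_len(i0 - 1)] <- D[seq_len(i0 - 1)]
    ok <- which(seq_along(D) >= i0 & Dbar <= beta)
    if (length(ok)) sel <- max(ok)  # smallest lambda satisfying the bound
  }
  if (is.na(sel)) {
    warning("no penalty satisfies the instability bound; returning the largest")
    sel <- 1L
  }
  structure(list(lambda = lambda_grid[sel], lambda_grid = lambda_grid,
                 instability = D, instability_monotone = Dbar,
                 density = density, subsample_size = b,
                 n_subsamples = n_subsamples, beta = beta),
            class = "stars_selection")
}

#' Covariance-selection refit of a sparse precision matrix
#'
#' Gaussian maximum likelihood of the precision matrix constrained to zeros
#' off the given support ("de-shrinkage"): the implied covariance matches
#' the sample covariance exactly on every support edge and on the diagonal,
#' removing the downward bias the L1 penalty puts on retained edges.
#'
#' @param S symmetric positive-definite sample covariance.
#' @param support logical/0-1 symmetric matrix of allowed off-diagonal
#'   entries (the diagonal is always free).
#' @param maxit maximum sweeps (default 1000).
#' @param tol tolerance on `max |implied covariance - S|` over
#'   support-union-diagonal (default 1e-6).
#' @return List: `precision` (Omega-tilde, exact zeros off support),
#'   `covariance` (implied), `iterations`, `max_deviation`.
#' @export
refit_constrained_mle <- function(S, support, maxit = 1000L, tol = 1e-6) {
  S <- as.matrix(S)
  support <- as.matrix(support) != 0
  stopifnot(is_square_symmetric(S, tol = 1e-8),
            nrow(support) == nrow(S))
  if (any(support != t(support))) stop("support must be symmetric")
  sup <- support
  diag(sup) <- FALSE
  fit <- cov_select_refit(S, matrix(as.integer(sup), nrow(S)),
                          maxit = maxit, tol = tol)
  if (!fit$converged)
    stop("constrained MLE refit did not converge: max deviation ",
         signif(fit$max_deviation, 4), " after ", fit$iterations, " cycles")
  omega <- fit$wi
  dimnames(omega) <- dimnames(fit$w) <- dimnames(S)
  list(precision = omega, covariance = fit$w,
       iterations = fit$iterations, max_deviation = fit$max_deviation)
}

#' Partial correlations from a precision matrix
#'
#' `rho_ij = -Omega_ij / sqrt(Omega_ii * Omega_jj)`, diagonal zeroed.
#'
#' @param omega symmetric positive-definite precision matrix.
#' @return A [connectivity_matrix()] of kind `"pFC"`.
#' @export
precision_to_partial_corr <- function(omega) {
  omega <- as.matrix(omega)
  if (any(diag(omega) <= 0)) stop("precision diagonal must be positive")
  pc <- partial_corr_from_precision(omega)
  connectivity_matrix(pc, kind = "pFC")
}

#' Unregularised sample partial correlations
#'
#' Inverts the sample correlation matrix directly (no sparsity penalty) and
#' converts it to partial correlations. Only sensible when the number of
#' time points comfortably exceeds the number of nodes; used by the
#' trajectory-classification analysis where an unbiased (if noisy) per-edge
#' estimate matters more than a sparse support.
#'
#' @param ts a [session_time_series()] or T x n matrix.
#' @return A [connectivity_matrix()] of kind `"pFC"`.
#' @export
sample_partial_corr <- function(ts) {
  x <- if (inherits(ts, "session_time_series")) ts$values else as.matrix(ts)
  if (nrow(x) <= ncol(x))
    stop("need more time points than nodes for an unregularised inverse")
  precision_to_partial_corr(solve(cor(x)))
}

#' Threshold a partial-correlation matrix into a network
#'
#' Retains edges with `rho > tau` (strictly; positive side only, mirroring
#' the positive-FC convention), with the partial correlations as weights.
#'
#' @param pfc a [connectivity_matrix()] of kind `"pFC"`.
#' @param tau threshold (default 1e-5, just above the exact zeros the
#'   graphical lasso produces).
#' @return A [network_graph()].
#' @export
threshold_pfc_network <- function(pfc, tau = 1e-5) {
  stopifnot(inherits(pfc, "connectivity_matrix"), pfc$kind == "pFC")
  w <- pfc$values
  w[w <= tau] <- 0
  network_graph(w, kind = "pFC",
                provenance = sprintf("positive edges, pFC > %g", tau))
}

#' Full sparse partial-correlation pipeline for one session
#'
#' Standardises the node series, computes the sample correlation matrix,
#' selects the penalty by StARS, fits the graphical lasso, refits the
#' precision by constrained MLE on the selected support, and returns the
#' partial-correlation matrix.
#'
#' @param ts a [session_time_series()] or T x n matrix.
#' @param seed seed for the StARS subsampling.
#' @param n_subsamples,beta,lambda_grid passed to [stars_select_lambda()].
#' @return List: `pfc` ([connectivity_matrix()]), `stars`, `glasso`,
#'   `refit`.
#' @export
estimate_pfc <- function(ts, seed = 1L, n_subsamples = 50L, beta = 0.05,
                         lambda_grid = NULL) {
  x <- if (inherits(ts, "session_time_series")) ts$values else as.matrix(ts)
  xs <- scale(x)
  S <- cor(xs)
  stars <- stars_select_lambda(xs, lambda_grid = lambda_grid,
                               n_subsamples = n_subsamples, beta = beta,
                               seed = seed)
  gfit <- glasso_fit(S, stars$lambda)
  refit <- refit_constrained_mle(S, gfit$support)
  list(pfc = precision_to_partial_corr(refit$precision),
       stars = stars, glasso = gfit, refit = refit)
}
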