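#' Ground-truth Gaussian graphical model for a synthetic cohort
#'
#' Bundles a symmetric positive-definite precision matrix, its covariance
#' inverse, and the atlas-style node annotation (hemisphere, homotopic
#' pairing, subnetwork membership) that downstream connectivity estimators
#' try to recover.
#'
#' @param precision symmetric positive-definite node x node matrix.
#' @param node_labels character vector of node names.
#' @param hemisphere per-node tag in `c("left", "right", "midline")`.
#' @param homotopic_pair per-node integer index of the mirror node, or `NA`.
#' @param module_id per-node subnetwork label (e.g. `"motor"`, `"other"`).
#'
#' @return An object of class `ground_truth_network` with elements
#'   `precision`, `covariance`, `node_labels`, `hemisphere`,
#'   `homotopic_pair`, `module_id`.
#' @export
ground_truth_network <- function(precision, node_labels = NULL,
                                 hemisphere = NULL, homotopic_pair = NULL,
                                 module_id = NULL) {
  n <- nrow(precision)
  if (!is_square_symmetric(precision, tol = 1e-8))
    stop("precision must be a symmetric square matrix")
  ev <- eigen(precision, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("precision matrix is not positive-definite (min eigenvalue ",
         signif(min(ev), 4), ")")
  if (is.null(node_labels)) node_labels <- sprintf("node%03d", seq_len(n))
  if (is.null(hemisphere)) hemisphere <- rep("midline", n)
  if (is.null(homotopic_pair)) homotopic_pair <- rep(NA_integer_, n)
  if (is.null(module_id)) module_id <- rep("other", n)
  stopifnot(length(node_labels) == n, length(hemisphere) == n,
            length(homotopic_pair) == n, length(module_id) == n)
  paired <- which(!is.na(homotopic_pair))
  if (length(paired) &&
      any(homotopic_pair[homotopic_pair[paired]] != paired))
    stop("homotopic pairing must be an involution")
  covariance <- chol2inv(chol(precision))
  dimnames(covariance) <- dimnames(precision) <- list(node_labels, node_labels)
  structure(
    list(precision = precision, covariance = covariance,
         node_labels = node_labels, hemisphere = hemisphere,
         homotopic_pair = as.integer(homotopic_pair), module_id = module_id),
    class = "ground_truth_network")
}

#' @export
print.ground_truth_network <- function(x, ...) {
  n <- length(x$node_labels)
  nedge <- sum(x$precision[upper.tri(x$precision)] != 0)
  cat("ground_truth_network:", n, "nodes,", nedge, "precision edges\n")
  cat("  modules:", paste(sprintf("%s (%d)", names(table(x$module_id)),
                                  table(x$module_id)), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a modular, optionally hemisphere-symmetric precision matrix
#'
#' Samples a sparse precision matrix whose support is denser within modules
#' than between them. Edge magnitudes are drawn uniformly from
#' `edge_magnitude_range` with random sign, the matrix is symmetrised, made
#' positive-definite by adding `|min eigenvalue| + 0.1` to the diagonal if
#' needed, and finally rescaled so the implied covariance has unit diagonal
#' (so the covariance is a correlation matrix).
#'
#' With `symmetry = TRUE` the first half of the nodes is labelled left, the
#' second half right, node `i` is homotopically paired with `i + n/2`, and
#' the precision matrix is constrained to be invariant under the hemisphere
#' swap: the right-right block mirrors the left-left block entrywise and the
#' between-hemisphere block is symmetric in paired coordinates. All later
#' rescaling is swap-equivariant, so left and right partial-correlation
#' blocks are equal entrywise by construction.
#'
#' @param n_nodes number of nodes (>= 4; even when `symmetry = TRUE`).
#' @param module_assignment per-node module labels; defaults to a single
#'   module. With `symmetry = TRUE` it must itself be mirror-consistent.
#' @param within_module_density,between_module_density expected fraction of
#'   present edges within / between modules, in `[0, 1]`.
#' @param edge_magnitude_range length-2 numeric, absolute off-diagonal
#'   magnitudes before rescaling.
#' @param symmetry logical; enforce hemispheric mirror symmetry.
#' @param seed integer seed; all randomness flows from it.
#' @return A [ground_truth_network()].
#' @export
make_modular_precision <- function(n_nodes, module_assignment = NULL,
                                   within_module_density = 0.3,
                                   between_module_density = 0.05,
                                   edge_magnitude_range = c(0.1, 0.4),
                                   symmetry = FALSE, seed = 1L) {
  stopifnot(n_nodes >= 4,
            within_module_density >= 0, within_module_density <= 1,
            between_module_density >= 0, between_module_density <= 1)
  if (symmetry && n_nodes %% 2 != 0)
    stop("symmetry requires an even number of nodes")
  if (is.null(module_assignment)) module_assignment <- rep("all", n_nodes)
  stopifnot(length(module_assignment) == n_nodes)

  with_seed(seed, {
    half <- n_nodes %/% 2
    if (symmetry) {
      hemisphere <- rep(c("left", "right"), each = half)
      pair <- c(seq_len(half) + half, seq_len(half))
      if (any(module_assignment[pair] != module_assignment))
        stop("module_assignment must be mirror-consistent when symmetry = TRUE")
    } else {
      hemisphere <- rep("midline", n_nodes)
      pair <- rep(NA_integer_, n_nodes)
    }

    draw_edge <- function(i, j) {
      dens <- if (module_assignment[i] == module_assignment[j])
        within_module_density else between_module_density
      if (runif(1) >= dens) return(0)
      sample(c(-1, 1), 1) * runif(1, edge_magnitude_range[1],
                                  edge_magnitude_range[2])
    }

    omega <- matrix(0, n_nodes, n_nodes)
    if (!symmetry) {
      for (i in seq_len(n_nodes - 1)) for (j in (i + 1):n_nodes) {
        v <- draw_edge(i, j)
        omega[i, j] <- omega[j, i] <- v
      }
    } else {
      # left-left upper triangle, mirrored to right-right
      for (i in seq_len(half - 1)) for (j in (i + 1):half) {
        v <- draw_edge(i, j)
        omega[i, j] <- omega[j, i] <- v
        omega[i + half, j + half] <- omega[j + half, i + half] <- v
      }
      # between-hemisphere block, symmetric in paired coordinates:
      # entry (i, j+half) must equal (j, i+half)
      for (i in seq_len(half)) for (j in i:half) {
        v <- draw_edge(i, j + half)
        omega[i, j + half] <- omega[j + half, i] <- v
        omega[j, i + half] <- omega[i + half, j] <- v
      }
    }
    diag(omega) <- 1

    ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-8)
      diag(omega) <- diag(omega) + abs(min(ev)) + 0.1
    ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("failed to obtain a positive-definite precision matrix")

    # rescale so the covariance has unit diagonal
    sigma <- chol2inv(chol(omega))
    d <- sqrt(diag(sigma))
    omega <- omega * (d %o% d)

    side <- ifelse(hemisphere == "right", "R", ifelse(hemisphere == "left", "L", "M"))
    idx_in_side <- stats::ave(seq_len(n_nodes), side, FUN = seq_along)
    labels <- sprintf("%s%02d_%s", side, idx_in_side, module_assignment)
    ground_truth_network(omega, node_labels = labels, hemisphere = hemisphere,
                         homotopic_pair = pair, module_id = module_assignment)
  })
}

#' Lesion trajectory specification
#'
#' Describes how a focal lesion alters the ground-truth network across
#' sessions: a persistent multiplicative attenuation of off-diagonal
#' precision entries within the lesioned subnetwork from the first
#' post-operative session onward, and a transient attenuation of a
#' designated set of global edges at the first post-operative session only
#' (remote diaschisis that resolves by the next session).
#'
#' @param session_ids ordered session labels; the first is the pre-operative
#'   baseline, the second the acute post-operative session.
#' @param persistent_scale multiplier in `(0, 2]` for off-diagonal precision
#'   entries within `lesion_module`, applied from session 2 onward.
#' @param transient_scale multiplier in `(0, 2]` for `transient_edges`,
#'   applied at session 2 only.
#' @param target_node index (or label) of the lesioned node.
#' @param lesion_module module label whose internal edges are persistently
#'   attenuated (default `"motor"`).
#' @param transient_edges two-column integer matrix of node index pairs
#'   scaled transiently; `NULL` for none.
#' @return An object of class `lesion_trajectory`.
#' @export
lesion_trajectory <- function(session_ids = c("op-1d", "op+1d", "op+7d", "op+3m"),
                              persistent_scale = 0.5, transient_scale = 0.5,
                              target_node = 1L, lesion_module = "motor",
                              transient_edges = NULL) {
  stopifnot(length(session_ids) >= 2,
            persistent_scale > 0, persistent_scale <= 2,
            transient_scale > 0, transient_scale <= 2)
  if (!is.null(transient_edges)) {
    transient_edges <- as.matrix(transient_edges)
    stopifnot(ncol(transient_edges) == 2)
  }
  structure(list(session_ids = session_ids,
                 persistent_scale = persistent_scale,
                 transient_scale = transient_scale,
                 target_node = target_node,
                 lesion_module = lesion_module,
                 transient_edges = transient_edges),
            class = "lesion_trajectory")
}

scale_precision_edges <- function(omega, rows, cols, scale) {
  for (k in seq_along(rows)) {
    i <- rows[k]; j <- cols[k]
    if (i == j) next
    omega[i, j] <- omega[i, j] * scale
    omega[j, i] <- omega[j, i] * scale
  }
  omega
}

#' Apply a lesion trajectory to a ground-truth network
#'
#' Returns one [ground_truth_network()] per session. The baseline session is
#' the unmodified input; every post-operative session carries the persistent
#' attenuation of the lesioned module's internal precision edges; the first
#' post-operative session additionally carries the transient attenuation,
#' which reverts exactly (bitwise) to baseline values afterwards.
#'
#' @param truth a [ground_truth_network()].
#' @param lesion a [lesion_trajectory()].
#' @return Named list of `ground_truth_network`, one per session.
#' @export
apply_lesion_trajectory <- function(truth, lesion) {
  stopifnot(inherits(truth, "ground_truth_network"),
            inherits(lesion, "lesion_trajectory"))
  omega0 <- truth$precision
  in_mod <- which(truth$module_id == lesion$lesion_module)

  persistent <- omega0
  if (length(in_mod) >= 2 && lesion$persistent_scale != 1) {
    pairs <- which(upper.tri(omega0), arr.ind = TRUE)
    keep <- pairs[, 1] %in% in_mod & pairs[, 2] %in% in_mod
    persistent <- scale_precision_edges(omega0, pairs[keep, 1], pairs[keep, 2],
                                        lesion$persistent_scale)
  }
  acute <- persistent
  if (!is.null(lesion$transient_edges) && lesion$transient_scale != 1)
    acute <- scale_precision_edges(acute, lesion$transient_edges[, 1],
                                   lesion$transient_edges[, 2],
                                   lesion$transient_scale)

  per_session <- vector("list", length(lesion$session_ids))
  names(per_session) <- lesion$session_ids
  for (s in seq_along(lesion$session_ids)) {
    omega_s <- if (s == 1) omega0 else if (s == 2) acute else persistent
    ev <- eigen(omega_s, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("lesion scaling breaks positive-definiteness at session ",
           lesion$session_ids[s])
    per_session[[s]] <- ground_truth_network(
      omega_s, node_labels = truth$node_labels, hemisphere = truth$hemisphere,
      homotopic_pair = truth$homotopic_pair, module_id = truth$module_id)
  }
  per_session
}

#' Cohort simulation configuration
#'
#' Study-design parameters for the synthetic cohort: 8 subjects scanned in
#' four sessions of 165 volumes at TR = 2 s (matching the emulated design),
#' an AR(1) temporal autocorrelation, low-frequency drift, motion-coupled
#' artifacts and white observation noise.
#'
#' @param n_subjects number of subjects.
#' @param n_timepoints volumes per session.
#' @param tr_seconds repetition time in seconds.
#' @param n_nodes atlas size.
#' @param ar_coefficient AR(1) coefficient `phi` in `[0, 1)`.
#' @param drift_amplitude amplitude of summed low-frequency sinusoids
#'   (frequencies below 0.009 Hz), in units of the unit-variance signal.
#' @param motion_artifact_amplitude scale of motion-regressor leakage into
#'   node series.
#' @param observation_noise_sd white measurement noise SD.
#' @param random_seed master seed for the whole cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 8L, n_timepoints = 165L,
                          tr_seconds = 2, n_nodes = 20L,
                          ar_coefficient = 0.4, drift_amplitude = 0.5,
                          motion_artifact_amplitude = 0.3,
                          observation_noise_sd = 0.2, random_seed = 1L) {
  stopifnot(ar_coefficient >= 0, ar_coefficient < 1,
            n_timepoints > 20, n_subjects >= 1, n_nodes >= 4)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds, n_nodes = as.integer(n_nodes),
                 ar_coefficient = ar_coefficient,
                 drift_amplitude = drift_amplitude,
                 motion_artifact_amplitude = motion_artifact_amplitude,
                 observation_noise_sd = observation_noise_sd,
                 random_seed = as.integer(random_seed)),
            class = "cohort_config")
}

#' Simulate nuisance regressors for one session
#'
#' Emulates realistic scanner nuisance: six smooth random-walk rigid-motion
#' parameters, their backward-difference derivatives (leading zero), and
#' three tissue-signal components. All columns are full rank after
#' demeaning; on the (vanishingly rare) rank-deficient draw the set is
#' regenerated with a new sub-seed, erroring after 5 attempts.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return A `nuisance_set`: list with `motion` (T x 6),
#'   `motion_derivatives` (T x 6), `tissue_components` (T x 3), `labels`.
#' @export
simulate_nuisance <- function(config, seed = config$random_seed) {
  T_ <- config$n_timepoints
  stopifnot(T_ >= 20)
  for (attempt in 0:4) {
    out <- with_seed(child_seed(seed, attempt), {
      motion <- sapply(1:6, function(i) {
        steps <- rnorm(T_, sd = 0.02)
        w <- cumsum(steps)
        stats::filter(w, rep(1 / 5, 5), sides = 1, method = "convolution") ->
          sm
        sm[is.na(sm)] <- w[is.na(sm)]
        as.numeric(sm)
      })
      deriv <- rbind(0, diff(motion))
      tissue <- sapply(1:3, function(i) as.numeric(
        stats::arima.sim(list(ar = 0.5), T_, sd = 1)))
      list(motion = motion, motion_derivatives = deriv,
           tissue_components = tissue)
    })
    X <- cbind(out$motion, out$motion_derivatives, out$tissue_components)
    Xc <- sweep(X, 2, colMeans(X))
    if (qr(Xc, tol = 1e-10)$rank == ncol(X)) {
      colnames(out$motion) <- sprintf("motion%d", 1:6)
      colnames(out$motion_derivatives) <- sprintf("motion%d_deriv", 1:6)
      colnames(out$tissue_components) <- sprintf("tissue%d", 1:3)
      out$labels <- c(colnames(out$motion), colnames(out$motion_derivatives),
                      colnames(out$tissue_components))
      return(structure(out, class = "nuisance_set"))
    }
  }
  stop("could not generate a full-rank nuisance set after 5 attempts")
}

#' Simulate one session of BOLD-like node time series
#'
#' Draws a stationary Gaussian AR(1) process
#' `x_t = phi * x_{t-1} + e_t`, `e_t ~ N(0, (1 - phi^2) * Sigma)`, so the
#' cross-sectional covariance equals the ground-truth covariance `Sigma`
#' regardless of `phi`; then adds low-frequency drift (sum of sinusoids
#' below 0.009 Hz with random phases), motion-artifact leakage (nuisance
#' regressors times random loadings), and white observation noise.
#'
#' @param truth a [ground_truth_network()].
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @param nuisance optional [simulate_nuisance()] output used for the
#'   artifact term (and typically saved alongside for later cleaning).
#' @return A [session_time_series()] in state `"raw"` (or `"clean"` when all
#'   contamination amplitudes are zero).
#' @export
simulate_session_bold <- function(truth, config, seed = config$random_seed,
                                  nuisance = NULL) {
  stopifnot(inherits(truth, "ground_truth_network"))
  T_ <- config$n_timepoints
  n <- length(truth$node_labels)
  phi <- config$ar_coefficient
  L <- chol(truth$covariance)  # upper triangular: t(L) %*% L = Sigma
  x <- with_seed(seed, {
    z <- matrix(rnorm(T_ * n), T_, n) %*% L
    x <- matrix(0, T_, n)
    x[1, ] <- z[1, ]
    scale_innov <- sqrt(1 - phi^2)
    for (t in 2:T_) x[t, ] <- phi * x[t - 1, ] + scale_innov * z[t, ]

    if (config$drift_amplitude > 0) {
      tt <- (seq_len(T_) - 1) * config$tr_seconds
      for (j in seq_len(n)) {
        freqs <- runif(3, 0.001, 0.009)
        phases <- runif(3, 0, 2 * pi)
        drift <- config$drift_amplitude *
          rowSums(sapply(1:3, function(k) sin(2 * pi * freqs[k] * tt + phases[k]))) / sqrt(3)
        x[, j] <- x[, j] + drift
      }
    }
    if (config$motion_artifact_amplitude > 0 && !is.null(nuisance)) {
      R <- cbind(nuisance$motion, nuisance$tissue_components)
      Rs <- scale(R)
      load <- matrix(rnorm(ncol(Rs) * n, sd = config$motion_artifact_amplitude /
                             sqrt(ncol(Rs))), ncol(Rs), n)
      x <- x + Rs %*% load
    }
    if (config$observation_noise_sd > 0)
      x <- x + matrix(rnorm(T_ * n, sd = config$observation_noise_sd), T_, n)
    x
  })
  if (any(!is.finite(x))) stop("non-finite values in simulated series")
  colnames(x) <- truth$node_labels
  contaminated <- config$drift_amplitude > 0 ||
    (config$motion_artifact_amplitude > 0 && !is.null(nuisance)) ||
    config$observation_noise_sd > 0
  session_time_series(x, tr_seconds = config$tr_seconds,
                      state = if (contaminated) "raw" else "clean")
}

#' Simulate ordinal tremor scores coupled to motor-network strength
#'
#' The latent severity is `2 + coupling_slope * z(strength) + noise`, where
#' `z()` standardises the per-session motor-network strengths; scores are the
#' latent value rounded and clipped into the ordinal range 0-4 (CRST-A
#' style). Expected score is monotone non-decreasing in motor strength.
#'
#' @param motor_strength_per_session numeric vector, one value per session.
#' @param coupling_slope non-negative slope on the standardised strength.
#' @param noise_sd Gaussian noise SD on the latent scale.
#' @param seed integer seed.
#' @return List with integer vectors `action` and `posture` (same coupling,
#'   independent noise).
#' @export
simulate_scores <- function(motor_strength_per_session, coupling_slope = 1.5,
                            noise_sd = 0.5, seed = 1L) {
  stopifnot(coupling_slope >= 0, noise_sd >= 0)
  s <- motor_strength_per_session
  z <- if (sd(s) > 0) (s - mean(s)) / sd(s) else rep(0, length(s))
  with_seed(seed, {
    one <- function() {
      latent <- 2 + coupling_slope * z + rnorm(length(z), sd = noise_sd)
      as.integer(pmin(4, pmax(0, round(latent))))
    }
    list(action = one(), posture = one())
  })
}

#' Generate a complete synthetic longitudinal cohort
#'
#' For each subject, the ground-truth precision matrix receives a
#' multiplicative log-normal jitter (sd 0.1) on its nonzero off-diagonal
#' entries (support never changes), the lesion trajectory is applied per
#' session, BOLD-like series plus nuisance sets are simulated, and ordinal
#' action/posture scores are coupled to the session-wise motor-network
#' strength. If `out_dir` is given the cohort is written as a directory tree
#' of TSV/JSON files (see [write_cohort()]).
#'
#' @param config a [cohort_config()].
#' @param truth a [ground_truth_network()]; default builds a two-module
#'   (motor/other) hemisphere-symmetric network on `config$n_nodes` nodes.
#' @param lesion a [lesion_trajectory()]; default attenuates the motor
#'   module persistently and a seeded random set of non-motor edges
#'   transiently.
#' @param seed master seed; defaults to `config$random_seed`.
#' @param out_dir optional output directory.
#' @return An object of class `synthetic_cohort`: list with `subjects` (each
#'   a `subject_record` with per-session series, nuisance, truths, scores),
#'   `truth`, `lesion`, `config`, and `atlas`.
#' @export
generate_cohort <- function(config = cohort_config(), truth = NULL,
                            lesion = NULL, seed = config$random_seed,
                            out_dir = NULL) {
  if (is.null(truth)) truth <- default_cohort_truth(config, seed)
  if (is.null(lesion)) lesion <- default_cohort_lesion(truth, seed)
  n <- length(truth$node_labels)
  stopifnot(n == config$n_nodes)

  subjects <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    sseed <- child_seed(seed, 1000 + s)
    jittered <- jitter_truth(truth, sseed)
    session_truths <- apply_lesion_trajectory(jittered, lesion)
    motor_strength <- vapply(session_truths, function(tr) {
      pc <- partial_corr_from_precision(tr$precision)
      idx <- which(tr$module_id == lesion$lesion_module)
      if (length(idx) < 2) return(0)
      mean(abs(upper_tri_values(pc[idx, idx, drop = FALSE])))
    }, numeric(1))
    scores <- simulate_scores(motor_strength, seed = child_seed(sseed, 7))

    sessions <- vector("list", length(session_truths))
    names(sessions) <- names(session_truths)
    for (k in seq_along(session_truths)) {
      nuis <- simulate_nuisance(config, seed = child_seed(sseed, 10 + k))
      ts <- simulate_session_bold(session_truths[[k]], config,
                                  seed = child_seed(sseed, 20 + k),
                                  nuisance = nuis)
      sessions[[k]] <- list(time_series = ts, nuisance = nuis,
                            truth = session_truths[[k]])
    }
    subjects[[s]] <- structure(
      list(subject_id = sprintf("sub%02d", s), sessions = sessions,
           action_score = scores$action, posture_score = scores$posture),
      class = "subject_record")
  }
  cohort <- structure(
    list(subjects = subjects, truth = truth, lesion = lesion, config = config,
         atlas = atlas_from_truth(truth)),
    class = "synthetic_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

# default truth: hemisphere-symmetric two-module network; the motor module
# occupies the first nodes of each hemisphere (half the atlas, mirroring a
# 10-node motor-tremor subnetwork on the default 20-node atlas), the
# lesioned "thalamus" is the first left motor node.
default_cohort_truth <- function(config, seed) {
  n <- config$n_nodes
  stopifnot(n %% 2 == 0, n >= 8)
  half <- n %/% 2
  n_motor_half <- max(2L, half %/% 2)
  mods_half <- c(rep("motor", n_motor_half), rep("other", half - n_motor_half))
  make_modular_precision(
    n, module_assignment = c(mods_half, mods_half),
    within_module_density = 0.4, between_module_density = 0.1,
    symmetry = TRUE, seed = child_seed(seed, 1))
}

default_cohort_lesion <- function(truth, seed) {
  omega <- truth$precision
  non_motor <- which(truth$module_id != "motor")
  pairs <- which(upper.tri(omega) & omega != 0, arr.ind = TRUE)
  cand <- pairs[pairs[, 1] %in% non_motor & pairs[, 2] %in% non_motor, ,
                drop = FALSE]
  trans <- with_seed(child_seed(seed, 2), {
    k <- min(10L, nrow(cand))
    cand[sample(nrow(cand), k), , drop = FALSE]
  })
  target <- which(truth$module_id == "motor" & truth$hemisphere == "left")[1]
  lesion_trajectory(target_node = target, transient_edges = trans)
}

jitter_truth <- function(truth, seed, sdlog = 0.1) {
  omega <- truth$precision
  with_seed(seed, {
    ut <- which(upper.tri(omega) & omega != 0, arr.ind = TRUE)
    for (attempt in 1:5) {
      om <- omega
      f <- rlnorm(nrow(ut), 0, sdlog)
      for (k in seq_len(nrow(ut))) {
        om[ut[k, 1], ut[k, 2]] <- om[ut[k, 1], ut[k, 2]] * f[k]
        om[ut[k, 2], ut[k, 1]] <- om[ut[k, 1], ut[k, 2]]
      }
      ev <- eigen(om, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) > 1e-8)
        return(ground_truth_network(om, truth$node_labels, truth$hemisphere,
                                    truth$homotopic_pair, truth$module_id))
    }
    stop("could not jitter precision matrix while preserving positive-definiteness")
  })
}

atlas_from_truth <- function(truth) {
  list(node_labels = truth$node_labels, hemisphere = truth$hemisphere,
       homotopic_pair = truth$homotopic_pair, module_id = truth$module_id)
}

partial_corr_from_precision <- function(omega) {
  d <- sqrt(diag(omega))
  pc <- -omega / (d %o% d)
  diag(pc) <- 0
  pc
}
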