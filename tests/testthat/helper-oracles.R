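# Independent oracles used by unit and acceptance tests. Deliberately naive
# implementations: correctness over speed, no shared code with the package.

# Exhaustive shortest-path distances on a small weighted graph: enumerate
# every simple path between each node pair (edge length = 1/weight) and take
# the minimum. Feasible for n <= 7.
brute_force_distances <- function(w) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- 0
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  walk <- function(path, total, target) {
    last <- path[length(path)]
    if (last == target) {
      if (total < best[path[1], target])
        best[path[1], target] <<- total
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (nxt %in% path) next
      if (!is.finite(len[last, nxt])) next
      walk(c(path, nxt), total + len[last, nxt], target)
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) walk(i, 0, j)
  best
}

brute_force_path_length <- function(w) {
  d <- brute_force_distances(w)
  diag(d) <- NA
  d[!is.finite(d)] <- NA
  pl <- rowMeans(d, na.rm = TRUE)
  pl[!is.finite(pl)] <- NA
  pl
}

brute_force_efficiency <- function(w) {
  n <- nrow(w)
  if (n < 2) return(0)
  d <- brute_force_distances(w)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# Random sparse non-negative symmetric weight matrix (possibly disconnected)
random_weight_matrix <- function(n, p_edge = 0.5, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < p_edge) w[i, j] <- w[j, i] <- runif(1, 0.1, 2)
  dimnames(w) <- list(sprintf("n%d", 1:n), sprintf("n%d", 1:n))
  w
}

# Tridiagonal (chain) precision matrix, unit diagonal couplings rho
chain_precision <- function(n, rho = 0.45) {
  om <- diag(n)
  for (i in seq_len(n - 1)) om[i, i + 1] <- om[i + 1, i] <- rho
  om
}

# F1 score of an estimated off-diagonal support against the truth
support_f1 <- function(est, truth) {
  e <- est[upper.tri(est)] != 0
  t_ <- truth[upper.tri(truth)] != 0
  tp <- sum(e & t_)
  if (tp == 0) return(0)
  prec <- tp / sum(e)
  rec <- tp / sum(t_)
  2 * prec * rec / (prec + rec)
}

# Draw T rows of a zero-mean Gaussian with covariance solve(omega)
rmvn_from_precision <- function(T_, omega, seed = 1) {
  set.seed(seed)
  sigma <- solve(omega)
  L <- chol(sigma)
  matrix(rnorm(T_ * nrow(omega)), T_, nrow(omega)) %*% L
}
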