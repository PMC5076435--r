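#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Coordinate descent for the column lasso sub-problem
//   min_b 0.5 b' W11 b - b' s12 + lambda * ||b||_1
// Updates beta in place; W11 must be positive-definite.
static void lasso_cd(const mat& W11, const vec& s12, vec& beta,
                     double lambda, int maxit, double tol) {
  const uword p = s12.n_elem;
  for (int it = 0; it < maxit; ++it) {
    double maxdiff = 0.0;
    for (uword k = 0; k < p; ++k) {
      // partial residual gradient with beta(k) removed
      double grad = s12(k) - dot(W11.col(k), beta) + W11(k, k) * beta(k);
      double bnew;
      if (grad > lambda)       bnew = (grad - lambda) / W11(k, k);
      else if (grad < -lambda) bnew = (grad + lambda) / W11(k, k);
      else                     bnew = 0.0;
      double d = std::abs(bnew - beta(k));
      if (d > maxdiff) maxdiff = d;
      beta(k) = bnew;
    }
    if (maxdiff < tol) break;
  }
}

// Assemble the precision matrix from the estimated covariance W and the
// per-column regression coefficients B, then symmetrise by averaging the
// two per-column estimates of each off-diagonal entry (exact zeros in B
// give exact zeros in the precision matrix: 0 + 0 stays 0).
static mat assemble_precision(const mat& W, const mat& B) {
  const uword p = W.n_rows;
  mat M(p, p, fill::zeros);
  const uvec all = regspace<uvec>(0, p - 1);
  for (uword j = 0; j < p; ++j) {
    uvec idx = find(all != j);
    vec beta = B.col(j);
    vec w12(p - 1);
    for (uword t = 0; t < p - 1; ++t) w12(t) = W(idx(t), j);
    double o22 = 1.0 / (W(j, j) - dot(w12, beta));
    M(j, j) = o22;
    for (uword t = 0; t < p - 1; ++t)
      M(idx(t), j) = -beta(t) * o22;
  }
  return 0.5 * (M + M.t());
}

// Graphical lasso by block coordinate descent (diagonal unpenalised):
// maximise log det(Omega) - tr(S Omega) - lambda * sum_{i!=j} |Omega_ij|.
// [[Rcpp::export]]
Rcpp::List glasso_cd(const arma::mat& S, double lambda,
                     int maxit = 500, double tol = 1e-5,
                     Rcpp::Nullable<Rcpp::NumericMatrix> warm_B = R_NilValue) {
  const uword p = S.n_rows;
  mat W = S;
  mat B(p - 1, p, fill::zeros);
  if (warm_B.isNotNull()) B = Rcpp::as<mat>(warm_B.get());
  const uvec all = regspace<uvec>(0, p - 1);
  double delta = datum::inf;
  int it = 0;
  for (; it < maxit; ++it) {
    double maxchg = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx = find(all != j);
      mat W11 = W(idx, idx);
      vec s12(p - 1);
      for (uword t = 0; t < p - 1; ++t) s12(t) = S(idx(t), j);
      vec beta = B.col(j);
      lasso_cd(W11, s12, beta, lambda, 1000, tol * 1e-2);
      vec w12 = W11 * beta;
      for (uword t = 0; t < p - 1; ++t) {
        double chg = std::abs(W(idx(t), j) - w12(t));
        if (chg > maxchg) maxchg = chg;
        W(idx(t), j) = w12(t);
        W(j, idx(t)) = w12(t);
      }
      B.col(j) = beta;
    }
    delta = maxchg;
    if (delta < tol) { ++it; break; }
  }
  mat Omega = assemble_precision(W, B);
  return Rcpp::List::create(
    Rcpp::Named("w") = W,
    Rcpp::Named("wi") = Omega,
    Rcpp::Named("B") = B,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("max_change") = delta,
    Rcpp::Named("converged") = (delta < tol));
}

// Covariance selection: Gaussian MLE of the precision matrix constrained to
// zeros off a fixed support. Same block sweep as the graphical lasso but the
// column sub-problem is an unpenalised linear solve restricted to the
// support neighbours, so off-support precision entries are exactly zero.
// Convergence is declared when the implied covariance matches S on
// support-union-diagonal within tol.
// [[Rcpp::export]]
Rcpp::List cov_select_refit(const arma::mat& S, const arma::umat& support,
                            int maxit = 1000, double tol = 1e-6) {
  const uword p = S.n_rows;
  mat W = S;
  mat B(p - 1, p, fill::zeros);
  const uvec all = regspace<uvec>(0, p - 1);
  double crit = datum::inf;
  int it = 0;
  for (; it < maxit; ++it) {
    for (uword j = 0; j < p; ++j) {
      uvec idx = find(all != j);
      vec beta(p - 1, fill::zeros);
      // neighbours of j inside the reduced index set
      std::vector<uword> nb;
      for (uword t = 0; t < p - 1; ++t)
        if (support(idx(t), j) != 0) nb.push_back(t);
      if (!nb.empty()) {
        uvec A = conv_to<uvec>::from(nb);
        mat W11 = W(idx, idx);
        vec sA(A.n_elem);
        for (uword t = 0; t < A.n_elem; ++t) sA(t) = S(idx(A(t)), j);
        mat WAA = W11(A, A);
        vec bA = solve(WAA, sA, solve_opts::likely_sympd);
        beta(A) = bA;
        vec w12 = W11 * beta;
        for (uword t = 0; t < p - 1; ++t) {
          W(idx(t), j) = w12(t);
          W(j, idx(t)) = w12(t);
        }
      } else {
        for (uword t = 0; t < p - 1; ++t) {
          W(idx(t), j) = 0.0;
          W(j, idx(t)) = 0.0;
        }
      }
      B.col(j) = beta;
    }
    // implied covariance must equal S on the support and the diagonal
    crit = 0.0;
    for (uword j = 0; j < p; ++j)
      for (uword i = 0; i < p; ++i)
        if (i == j || support(i, j) != 0) {
          double d = std::abs(W(i, j) - S(i, j));
          if (d > crit) crit = d;
        }
    if (crit < tol) { ++it; break; }
  }
  mat Omega = assemble_precision(W, B);
  return Rcpp::List::create(
    Rcpp::Named("w") = W,
    Rcpp::Named("wi") = Omega,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("max_deviation") = crit,
    Rcpp::Named("converged") = (crit < tol));
}
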