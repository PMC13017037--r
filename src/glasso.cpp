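// Graphical lasso by block coordinate descent (the classic sparse
// inverse-covariance algorithm): cycles over columns of the working
// covariance W, solving each column's lasso subproblem by coordinate
// descent. A path version with warm starts backs the EBIC model search and
// the bootstrap loops.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void glasso_core(const mat& S, double rho, mat& W, mat& B,
                        double tol, int maxit, int inner_max) {
  const int p = S.n_rows;
  uvec all = regspace<uvec>(0, p - 1);
  double offscale = mean(mean(abs(S - diagmat(S.diag())))) + 1e-12;
  for (int it = 0; it < maxit; ++it) {
    double delta = 0.0;
    for (int j = 0; j < p; ++j) {
      uvec idx = find(all != (unsigned) j);
      mat V = W.submat(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec b = B.col(j);
      // inner lasso: min 0.5 b'Vb - s12'b + rho ||b||_1
      for (int inner = 0; inner < inner_max; ++inner) {
        double ch = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          double x = s12(k) - dot(V.col(k), b) + V(k, k) * b(k);
          double bnew = 0.0;
          if (x > rho) bnew = (x - rho) / V(k, k);
          else if (x < -rho) bnew = (x + rho) / V(k, k);
          ch = std::max(ch, std::abs(bnew - b(k)));
          b(k) = bnew;
        }
        if (ch < tol) break;
      }
      vec w12 = V * b;
      for (int k = 0; k < p - 1; ++k) {
        double old = W(idx(k), j);
        delta = std::max(delta, std::abs(w12(k) - old));
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
      B.col(j) = b;
    }
    if (delta < tol * offscale) break;
  }
}

static mat theta_from(const mat& W, const mat& B) {
  const int p = W.n_rows;
  uvec all = regspace<uvec>(0, p - 1);
  mat Theta(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    uvec idx = find(all != (unsigned) j);
    vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double tjj = 1.0 / (W(j, j) - dot(w12, B.col(j)));
    Theta(j, j) = tjj;
    for (int k = 0; k < p - 1; ++k) Theta(idx(k), j) = -B(k, j) * tjj;
  }
  return 0.5 * (Theta + Theta.t());
}

// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, double rho,
                      double tol = 1e-10, int maxit = 1000) {
  const int p = S.n_rows;
  mat W = S + rho * eye(p, p);
  mat B(p - 1, p, fill::zeros);
  glasso_core(S, rho, W, B, tol, maxit, 1000);
  mat Theta = theta_from(W, B);
  return Rcpp::List::create(Rcpp::Named("w") = W,
                            Rcpp::Named("theta") = Theta);
}

// Penalty path, largest to smallest, warm-starting each fit from the
// previous solution. Returns one precision matrix per penalty plus the
// Gaussian log-likelihood term and edge count the EBIC needs.
// [[Rcpp::export]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           double tol = 1e-7, int maxit = 100) {
  const int p = S.n_rows;
  const int L = lambdas.n_elem;
  mat W = S + lambdas(0) * eye(p, p);
  mat B(p - 1, p, fill::zeros);
  Rcpp::List thetas(L);
  vec loglik(L);
  ivec n_edges(L);
  for (int l = 0; l < L; ++l) {
    // keep the warm-started diagonal consistent with the current penalty
    W.diag() = S.diag() + lambdas(l);
    glasso_core(S, lambdas(l), W, B, tol, maxit, 300);
    mat Theta = theta_from(W, B);
    thetas[l] = Theta;
    double sign;
    double ld;
    log_det(ld, sign, Theta);
    loglik(l) = ld - trace(S * Theta);
    int e = 0;
    for (int i = 0; i < p; ++i)
      for (int j = i + 1; j < p; ++j)
        if (std::abs(Theta(i, j)) > 1e-10) ++e;
    n_edges(l) = e;
  }
  return Rcpp::List::create(Rcpp::Named("theta") = thetas,
                            Rcpp::Named("loglik") = loglik,
                            Rcpp::Named("n_edges") = n_edges);
}
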