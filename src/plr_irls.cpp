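// Inner solver of the penalized logistic regression classifier: ridge-
// penalized IRLS (Newton with backtracking) and batch evaluation of
// candidate centroid columns during greedy cluster growth.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static double penalized_nll(const vec& eta, const vec& y, const vec& beta,
                            const vec& pen, double lambda) {
  double nll = 0.0;
  for (uword i = 0; i < eta.n_elem; ++i) {
    double e = eta[i];
    nll += std::max(e, 0.0) + std::log1p(std::exp(-std::abs(e))) - y[i] * e;
  }
  return nll + lambda * dot(pen, beta % beta);
}

static vec logistic(const vec& eta) {
  return 1.0 / (1.0 + exp(-clamp(eta, -700.0, 700.0)));
}

// Newton/IRLS minimization of nll + lambda * sum(pen * beta^2).
// Returns the criterion at the last iterate; beta is updated in place.
static double irls_fit(const mat& X, const vec& y, double lambda,
                       const vec& pen, vec& beta, double tol, int maxit,
                       double& grad_norm, bool& converged) {
  vec eta = X * beta;
  double cur = penalized_nll(eta, y, beta, pen, lambda);
  converged = false;
  for (int it = 0; it < maxit; ++it) {
    vec p = logistic(eta);
    vec g = X.t() * (p - y) + 2.0 * lambda * (pen % beta);
    if (abs(g).max() < tol) { converged = true; break; }
    vec w = clamp(p % (1.0 - p), 1e-10, datum::inf);
    mat Xw = X.each_col() % w;
    mat H = X.t() * Xw;
    H.diag() += 2.0 * lambda * pen;
    vec step;
    if (!solve(step, H, g, solve_opts::likely_sympd)) break;
    double t = 1.0, cnew = cur;
    vec bnew, enew;
    while (true) {
      bnew = beta - t * step;
      enew = X * bnew;
      cnew = penalized_nll(enew, y, bnew, pen, lambda);
      if (cnew <= cur + 1e-14 || t < 1e-8) break;
      t *= 0.5;
    }
    if (cnew > cur - 1e-14 && t < 1e-8) break;  // no progress possible
    beta = bnew; eta = enew; cur = cnew;
  }
  vec p = logistic(eta);
  vec g = X.t() * (p - y) + 2.0 * lambda * (pen % beta);
  grad_norm = abs(g).max();
  if (grad_norm < tol) converged = true;
  return cur;
}

// [[Rcpp::export(name = ".ridge_logistic_cpp")]]
Rcpp::List ridge_logistic_cpp(const arma::mat& X, const arma::vec& y,
                              double lambda, const arma::vec& pen,
                              arma::vec beta, double tol, int maxit) {
  double grad_norm; bool converged;
  double cur = irls_fit(X, y, lambda, pen, beta, tol, maxit, grad_norm,
                        converged);
  vec eta = X * beta;
  vec p = logistic(eta);
  return Rcpp::List::create(
      Rcpp::Named("beta") = beta,
      Rcpp::Named("criterion") = cur,
      Rcpp::Named("nll") = penalized_nll(eta, y, beta, zeros(beta.n_elem), 0.0),
      Rcpp::Named("fitted") = p,
      Rcpp::Named("grad_norm") = grad_norm,
      Rcpp::Named("converged") = converged);
}

// Evaluate appending each column of Z to the design X0: fit the penalized
// logistic model on [X0, z] from the warm start and return the criterion
// per candidate. pen is for the full (ncol(X0) + 1) coefficient vector.
// [[Rcpp::export(name = ".eval_candidates_cpp")]]
arma::vec eval_candidates_cpp(const arma::mat& X0, const arma::mat& Z,
                              const arma::vec& y, double lambda,
                              const arma::vec& pen, const arma::vec& warm,
                              double tol, int maxit) {
  uword k = X0.n_cols, J = Z.n_cols;
  mat X(X0.n_rows, k + 1);
  X.cols(0, k - 1) = X0;
  vec out(J);
  double grad_norm; bool converged;
  for (uword j = 0; j < J; ++j) {
    X.col(k) = Z.col(j);
    vec beta = warm;
    out[j] = irls_fit(X, y, lambda, pen, beta, tol, maxit, grad_norm,
                      converged);
  }
  return out;
}
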