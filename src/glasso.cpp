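// Graphical lasso: block coordinate descent on the covariance matrix
// (Friedman-Hastie-Tibshirani style). Only off-diagonal entries of the
// precision matrix are penalized, so the working covariance keeps the
// sample diagonal. Warm starts across a lambda path are essential for
// the bootstrap / permutation workloads.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Solve one lasso subproblem: min over beta of
//   0.5 beta' W11 beta - s12' beta + lambda ||beta||_1
// by cyclic coordinate descent. beta is modified in place.
static void lasso_cd(const mat& W11, const vec& s12, double lambda,
                     vec& beta, double tol, int maxit) {
  const uword q = s12.n_elem;
  for (int it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (uword k = 0; k < q; ++k) {
      double grad = s12(k) - dot(W11.col(k), beta) + W11(k, k) * beta(k);
      double bnew = soft(grad, lambda) / W11(k, k);
      double d = bnew - beta(k);
      if (std::abs(d) > dmax) dmax = std::abs(d);
      beta(k) = bnew;
    }
    if (dmax < tol) break;
  }
}

// One glasso fit. W and B carry warm starts (B column j = beta for
// block j, with a structural zero at row j). Returns number of sweeps,
// or -1 on non-convergence.
static int glasso_core(const mat& S, double lambda, mat& W, mat& B,
                       double tol, int maxit) {
  const uword p = S.n_rows;
  W.diag() = S.diag();  // diagonal unpenalized: w_jj = s_jj at optimum
  uvec all = regspace<uvec>(0, p - 1);
  for (int sweep = 0; sweep < maxit; ++sweep) {
    double dmax = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec rest = find(all != j);
      mat W11 = W.submat(rest, rest);
      vec s12 = S.col(j);
      s12 = s12.elem(rest);
      vec beta = B.col(j);
      beta = beta.elem(rest);
      lasso_cd(W11, s12, lambda, beta, tol * 0.1, maxit);
      vec w12 = W11 * beta;
      for (uword k = 0; k < rest.n_elem; ++k) {
        double d = std::abs(w12(k) - W(rest(k), j));
        if (d > dmax) dmax = d;
        W(rest(k), j) = w12(k);
        W(j, rest(k)) = w12(k);
        B(rest(k), j) = beta(k);
      }
      B(j, j) = 0.0;
    }
    if (dmax < tol) return sweep + 1;
  }
  return -1;
}

// Recover Theta from the final (W, B): theta_jj = 1/(w_jj - w12'beta),
// theta_12 = -beta * theta_jj. Exact zeros in beta give exact zeros.
static mat recover_theta(const mat& W, const mat& B) {
  const uword p = W.n_rows;
  mat Theta(p, p, fill::zeros);
  uvec all = regspace<uvec>(0, p - 1);
  for (uword j = 0; j < p; ++j) {
    uvec rest = find(all != j);
    vec beta = B.col(j);
    beta = beta.elem(rest);
    vec w12 = W.col(j);
    w12 = w12.elem(rest);
    double tjj = 1.0 / (W(j, j) - dot(w12, beta));
    Theta(j, j) = tjj;
    for (uword k = 0; k < rest.n_elem; ++k)
      Theta(rest(k), j) = -beta(k) * tjj;
  }
  // the two block solves give the same value up to solver tolerance
  return 0.5 * (Theta + Theta.t());
}

// [[Rcpp::export(name = ".glasso_fit_cpp")]]
Rcpp::List glasso_fit_cpp(const arma::mat& S, double lambda,
                          double tol = 1e-6, int maxit = 10000) {
  mat W = S;
  mat B(S.n_rows, S.n_cols, fill::zeros);
  int sweeps = glasso_core(S, lambda, W, B, tol, maxit);
  if (sweeps < 0) {
    mat Winv;
    bool ok = inv_sympd(Winv, W);
    double kkt = ok ? abs(Winv - S).max() : NA_REAL;
    Rcpp::stop("graphical lasso did not converge at lambda = %g "
               "(max KKT residual %g)", lambda, kkt);
  }
  mat Theta = recover_theta(W, B);
  return Rcpp::List::create(Rcpp::Named("Theta") = Theta,
                            Rcpp::Named("W_cov") = W,
                            Rcpp::Named("sweeps") = sweeps);
}

// Fit a decreasing lambda path with warm starts. Returns per-lambda
// precision matrices plus bookkeeping; EBIC scoring happens in R.
// [[Rcpp::export(name = ".glasso_path_cpp")]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           double tol = 1e-6, int maxit = 10000) {
  const uword p = S.n_rows, m = lambdas.n_elem;
  mat W = S;
  mat B(p, p, fill::zeros);
  Rcpp::List thetas(m);
  Rcpp::LogicalVector converged(m);
  for (uword i = 0; i < m; ++i) {
    int sweeps = glasso_core(S, lambdas(i), W, B, tol, maxit);
    converged(i) = sweeps >= 0;
    if (sweeps >= 0) {
      thetas[i] = Rcpp::wrap(recover_theta(W, B));
    } else {
      thetas[i] = R_NilValue;
      W = S;  // reset warm start after a failure
      B.zeros();
    }
  }
  return Rcpp::List::create(Rcpp::Named("Theta") = thetas,
                            Rcpp::Named("converged") = converged);
}
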