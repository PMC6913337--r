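// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Ridge-penalized logistic regression by iteratively reweighted least
// squares. X must carry the intercept as its first column; the penalty is
// applied to slopes only, so with ridge -> 0 this is the maximum-likelihood
// fit and the intercept-only model recovers logit(mean(y)) exactly.
// [[Rcpp::export]]
arma::vec cpp_logistic_irls(const arma::mat& X, const arma::vec& y,
                            double ridge = 1e-4, int maxit = 50,
                            double tol = 1e-8) {
  int p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  arma::vec pen(p, arma::fill::value(ridge));
  pen[0] = 0.0;
  for (int it = 0; it < maxit; ++it) {
    arma::vec eta = X * beta;
    eta = arma::clamp(eta, -30.0, 30.0);
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = mu % (1.0 - mu) + 1e-10;
    arma::vec z = eta + (y - mu) / w;
    arma::mat XtW = X.t();
    XtW.each_row() %= w.t();
    arma::mat A = XtW * X;
    A.diag() += pen;
    arma::vec rhs = XtW * z;
    arma::vec beta_new = arma::solve(A, rhs, arma::solve_opts::fast);
    double delta = arma::max(arma::abs(beta_new - beta));
    beta = beta_new;
    if (delta < tol) break;
  }
  return beta;
}
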