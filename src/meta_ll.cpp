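// Negative profiled (restricted) log-likelihood of the multilevel
// meta-analytic model, evaluated inside variance-component optimization
// loops.  The marginal covariance V = diag(v + omega2) + tau2 * block-ones
// (blocks = studies) is handled via the Sherman-Morrison identity, so the
// cost is O(n p^2) per evaluation.  M = [X y]; g is a 1-based study index.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// [[Rcpp::export(.meta_negll_cpp)]]
double meta_negll_cpp(double tau2, double omega2, const arma::mat& M,
                      const arma::vec& v, const arma::ivec& g, int B,
                      bool reml) {
  const arma::uword n = M.n_rows;
  const arma::uword p = M.n_cols - 1;
  arma::vec a = v + omega2;
  arma::vec w = 1.0 / a;
  arma::mat Mw = M.each_col() % w;
  arma::mat S(B, p + 1, arma::fill::zeros);
  arma::vec tb(B, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    const int b = g[i] - 1;
    S.row(b) += Mw.row(i);
    tb[b] += w[i];
  }
  arma::vec cb = tau2 / (1.0 + tau2 * tb);
  arma::mat A = M.t() * Mw - S.t() * (S.each_col() % cb);
  arma::mat XtVX = A.submat(0, 0, p - 1, p - 1);
  arma::vec XtVy = A.submat(0, p, p - 1, p);
  const double ytVy = A(p, p);
  arma::mat ch;
  if (!arma::chol(ch, XtVX)) return arma::datum::inf;
  arma::vec beta = arma::solve(arma::trimatu(ch),
                               arma::solve(arma::trimatl(ch.t()), XtVy));
  const double ytPy = ytVy - arma::dot(XtVy, beta);
  const double logdetV = arma::accu(arma::log(a)) +
    arma::accu(arma::log1p(tau2 * tb));
  double ll;
  if (reml) {
    ll = -0.5 * ((double)(n - p) * std::log(2.0 * M_PI) + logdetV +
                 2.0 * arma::accu(arma::log(ch.diag())) + ytPy);
  } else {
    ll = -0.5 * ((double)n * std::log(2.0 * M_PI) + logdetV + ytPy);
  }
  return -ll;
}
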