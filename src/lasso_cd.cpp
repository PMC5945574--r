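#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Coordinate descent for the L1-penalised residual sum of squares
//   min_g ||y - X g||^2 + lambda * sum_k |g_k|
// over a decreasing lambda path with warm starts. X and y are expected
// centred (intercept handled by the caller); columns need not be unit
// scale, the update divides by each column's sum of squares.
// [[Rcpp::export]]
arma::mat lasso_cd_path(const arma::mat& X, const arma::vec& y,
                        const arma::vec& lambda_path,
                        double tol = 1e-7, int max_iter = 1000) {
  const int m = X.n_cols;
  const int L = lambda_path.n_elem;
  arma::vec zz(m);
  for (int k = 0; k < m; ++k) zz(k) = arma::dot(X.col(k), X.col(k));
  arma::vec gamma(m, arma::fill::zeros);
  arma::vec r = y;                       // residual y - X gamma
  arma::mat out(m, L, arma::fill::zeros);
  for (int l = 0; l < L; ++l) {
    const double lam = lambda_path(l);
    const double thr = lam / 2.0;        // subgradient threshold of RSS form
    auto sweep = [&](const arma::uvec& idx) {
      double max_change = 0.0;
      for (arma::uword j = 0; j < idx.n_elem; ++j) {
        const int k = idx(j);
        if (zz(k) <= 0) continue;
        const double old = gamma(k);
        const double rho = arma::dot(X.col(k), r) + zz(k) * old;
        double g = 0.0;
        if (rho > thr) g = (rho - thr) / zz(k);
        else if (rho < -thr) g = (rho + thr) / zz(k);
        if (g != old) {
          r += X.col(k) * (old - g);
          gamma(k) = g;
          double ch = std::fabs(g - old) * std::sqrt(zz(k));
          if (ch > max_change) max_change = ch;
        }
      }
      return max_change;
    };
    const arma::uvec all = arma::regspace<arma::uvec>(0, m - 1);
    // active-set iteration: converge on the nonzero set, then one full
    // sweep to admit violators; done when the full sweep changes nothing
    for (int outer = 0; outer < max_iter; ++outer) {
      if (sweep(all) < tol) break;
      arma::uvec active = arma::find(gamma != 0.0);
      for (int it = 0; it < max_iter; ++it)
        if (active.n_elem == 0 || sweep(active) < tol) break;
    }
    out.col(l) = gamma;
  }
  return out;
}
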