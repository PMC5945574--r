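#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Pairwise (SMO-style) ascent on the epsilon-SVR dual in the compact
// beta = alpha - alpha* parameterisation:
//   max W(beta) = -1/2 beta' Q beta + y' beta - eps * sum_i |beta_i|
//   s.t. sum_i beta_i = 0, -C <= beta_i <= C,
// Q the (PSD) kernel matrix. Each step moves a pair (i, j) along
// e_i - e_j, maximising the exact piecewise-quadratic gain over the
// candidate break/stationary points, so every accepted step increases W.
// [[Rcpp::export]]
List svr_smo(const arma::mat& Q, const arma::vec& y, double C, double eps,
             double tol = 1e-3, int max_pass = 2000000) {
  const int n = Q.n_rows;
  arma::vec beta(n, arma::fill::zeros);
  arma::vec F = y;                       // F_i = y_i - (Q beta)_i

  auto gain_at = [&](int i, int j, double t, double G, double eta) {
    return G * t - 0.5 * eta * t * t -
           eps * (std::fabs(beta(i) + t) - std::fabs(beta(i)) +
                  std::fabs(beta(j) - t) - std::fabs(beta(j)));
  };

  int pass;
  for (pass = 0; pass < max_pass; ++pass) {
    // steepest feasible ascent pair: i to increase, j to decrease
    int bi = -1, bj = -1;
    double best_inc = -1e300, best_dec = -1e300;
    for (int k = 0; k < n; ++k) {
      if (beta(k) < C) {
        const double d_inc = F(k) + (beta(k) < 0 ? eps : -eps);
        if (d_inc > best_inc) { best_inc = d_inc; bi = k; }
      }
      if (beta(k) > -C) {
        const double d_dec = -F(k) + (beta(k) > 0 ? eps : -eps);
        if (d_dec > best_dec) { best_dec = d_dec; bj = k; }
      }
    }
    if (bi < 0 || bj < 0 || bi == bj || best_inc + best_dec < tol) break;

    const int i = bi, j = bj;
    const double G = F(i) - F(j);
    double eta = Q(i, i) + Q(j, j) - 2.0 * Q(i, j);
    if (eta < 1e-12) eta = 1e-12;
    const double t_lo = std::max(-C - beta(i), beta(j) - C);
    const double t_hi = std::min(C - beta(i), beta(j) + C);

    // candidate steps: stationary point of each sign region, kinks, box
    double cand[8];
    int nc = 0;
    for (int si = -1; si <= 1; si += 2)
      for (int sj = -1; sj <= 1; sj += 2)
        cand[nc++] = (G - eps * si + eps * sj) / eta;
    cand[nc++] = -beta(i);
    cand[nc++] = beta(j);
    cand[nc++] = t_lo;
    cand[nc++] = t_hi;
    double t_best = 0.0, w_best = 0.0;
    for (int c = 0; c < nc; ++c) {
      double t = std::min(t_hi, std::max(t_lo, cand[c]));
      double w = gain_at(i, j, t, G, eta);
      if (w > w_best) { w_best = w; t_best = t; }
    }
    if (w_best <= 1e-14 || t_best == 0.0) break;
    beta(i) += t_best;
    beta(j) -= t_best;
    F -= Q.col(i) * t_best;
    F += Q.col(j) * t_best;
  }

  // intercept from the KKT interval: b in [F_i - eps, F_i + eps] at
  // beta_i = 0, pinned to F_i -+ eps at interior points
  double lo = -1e300, hi = 1e300;
  for (int k = 0; k < n; ++k) {
    double l, h;
    if (beta(k) >= C) { l = -1e300; h = F(k) - eps; }
    else if (beta(k) <= -C) { l = F(k) + eps; h = 1e300; }
    else if (beta(k) > 0) { l = F(k) - eps; h = F(k) - eps; }
    else if (beta(k) < 0) { l = F(k) + eps; h = F(k) + eps; }
    else { l = F(k) - eps; h = F(k) + eps; }
    if (l > lo) lo = l;
    if (h < hi) hi = h;
  }
  double b;
  if (lo > -1e299 && hi < 1e299) b = 0.5 * (lo + hi);
  else if (lo > -1e299) b = lo;
  else if (hi < 1e299) b = hi;
  else b = 0.0;

  const double obj = -0.5 * arma::dot(beta, Q * beta) + arma::dot(y, beta) -
                     eps * arma::accu(arma::abs(beta));
  return List::create(_["beta"] = beta, _["b"] = b, _["objective"] = obj,
                      _["passes"] = pass);
}
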