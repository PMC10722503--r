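#include <Rcpp.h>
using namespace Rcpp;

// Log-likelihood of the geometric clade-size model over a (r, lambda) grid.
//
// Clades are aggregated by unique age: for age t_k let m_k be the number of
// clades and s_k the summed richness.  Then
//   ll(r, lam) = sum_k [ m_k * log(1 - beta_k) + (s_k - m_k) * log(beta_k) ]
// with beta_k = (1 - exp(-r t_k)) / (1 - eps * exp(-r t_k)), eps = 1 - r/lam.
// Grid points with lam < r (negative extinction rate) get -Inf.
//
// The arithmetic mirrors bd_beta()/bd_loglik() in R so the grid evaluation
// is interchangeable with the naive per-point loop.
// [[Rcpp::export]]
NumericMatrix bd_grid_loglik_cpp(NumericVector r, NumericVector lam,
                                 NumericVector tu, NumericVector m,
                                 NumericVector s) {
  const int nr = r.size(), nl = lam.size(), nt = tu.size();
  NumericMatrix ll(nr, nl);

  // exp(-r t) depends only on (r, t): precompute
  std::vector<double> ert(static_cast<size_t>(nr) * nt);
  for (int i = 0; i < nr; ++i)
    for (int k = 0; k < nt; ++k)
      ert[static_cast<size_t>(i) * nt + k] = std::exp(-r[i] * tu[k]);

  for (int j = 0; j < nl; ++j) {
    const double lamj = lam[j];
    for (int i = 0; i < nr; ++i) {
      if (lamj < r[i]) {
        ll(i, j) = R_NegInf;
        continue;
      }
      const double eps = 1.0 - r[i] / lamj;
      double acc = 0.0;
      const double *e = &ert[static_cast<size_t>(i) * nt];
      for (int k = 0; k < nt; ++k) {
        const double beta = (1.0 - e[k]) / (1.0 - eps * e[k]);
        const double extra = s[k] - m[k];  // sum of (n_i - 1) at this age
        acc += m[k] * std::log1p(-beta);
        if (extra > 0.0) acc += extra * std::log(beta);
      }
      ll(i, j) = acc;
    }
  }
  return ll;
}
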