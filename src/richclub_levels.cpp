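#include <Rcpp.h>
using namespace Rcpp;

// phi(r) at every richness level for a batch of weight assignments over a
// fixed edge skeleton (columns of W = weight-reshuffle nulls). Node
// strengths are accumulated per column; denom_cum holds the cumulative
// sums of the descending-sorted weight multiset (identical across nulls,
// which permute the same weights). Ranking ties are broken by ascending
// node index, matching the R-side convention.
// [[Rcpp::export]]
NumericMatrix phi_levels_batch(IntegerVector ei, IntegerVector ej,
                               NumericMatrix W, int n,
                               int step, int n_lev,
                               NumericVector denom_cum) {
  const int m = ei.size(), B = W.ncol();
  NumericMatrix phi(n_lev, B);
  std::vector<int> ord(n), rk(n), ce(n_lev);
  std::vector<double> cw(n_lev), s(n);
  for (int b = 0; b < B; ++b) {
    std::fill(s.begin(), s.end(), 0.0);
    for (int e = 0; e < m; ++e) {
      double w = W(e, b);
      s[ei[e] - 1] += w;
      s[ej[e] - 1] += w;
    }
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int c) { return s[a] > s[c]; });
    for (int i = 0; i < n; ++i) rk[ord[i]] = i + 1;
    std::fill(cw.begin(), cw.end(), 0.0);
    std::fill(ce.begin(), ce.end(), 0);
    for (int e = 0; e < m; ++e) {
      int r1 = rk[ei[e] - 1], r2 = rk[ej[e] - 1];
      int lev = ((r1 > r2 ? r1 : r2) + step - 1) / step;  // ceil(max rank / step)
      if (lev <= n_lev) {
        cw[lev - 1] += W(e, b);
        ce[lev - 1] += 1;
      }
    }
    double accw = 0.0;
    int acce = 0;
    for (int k = 0; k < n_lev; ++k) {
      accw += cw[k];
      acce += ce[k];
      phi(k, b) = acce > 0 ? accw / denom_cum[acce - 1] : NA_REAL;
    }
  }
  return phi;
}
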