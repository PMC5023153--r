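#include <Rcpp.h>
using namespace Rcpp;

// Gamma-index search kernel.
//
// meas:      measured dose at evaluated pixels (vector, length n)
// mrow,mcol: 0-based positions of those pixels on the fine reference grid
// ref:       fine (interpolated) reference grid, nr x nc, column-major
// off_r/off_c: candidate displacements on the fine grid, sorted by distance
// d2term:    (displacement distance / dta)^2 for each candidate, ascending
// inv_tol2:  1 / (dose tolerance in cGy)^2
//
// For each pixel the candidates are scanned in order of increasing distance
// and the scan stops as soon as the pure distance term can no longer beat
// the best combined gamma^2 found so far.
// [[Rcpp::export]]
NumericVector gamma_search_kernel(NumericVector meas,
                                  IntegerVector mrow, IntegerVector mcol,
                                  NumericMatrix ref,
                                  IntegerVector off_r, IntegerVector off_c,
                                  NumericVector d2term,
                                  double inv_tol2) {
  const int n = meas.size();
  const int m = off_r.size();
  const int nr = ref.nrow();
  const int nc = ref.ncol();
  const double *refp = ref.begin();
  NumericVector g2(n);
  for (int i = 0; i < n; ++i) {
    const double dm = meas[i];
    const int r0 = mrow[i];
    const int c0 = mcol[i];
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dist2 = d2term[j];
      if (dist2 >= best) break;  // candidates are distance-sorted
      const int r = r0 + off_r[j];
      const int c = c0 + off_c[j];
      if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
      const double dd = refp[(size_t)c * nr + r] - dm;
      const double g = dd * dd * inv_tol2 + dist2;
      if (g < best) best = g;
    }
    g2[i] = best;
  }
  return g2;
}
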