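#include <Rcpp.h>
using namespace Rcpp;

// brute-force 2D nearest neighbor: for each row of P, the 1-based index of
// the closest row of Q (ICP correspondence step; point sets are a few
// thousand at most, so O(N*M) in compiled code beats any index structure)
// [[Rcpp::export]]
IntegerVector nn2d_cpp(NumericMatrix P, NumericMatrix Q) {
  const int n = P.nrow(), m = Q.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const double px = P(i, 0), py = P(i, 1);
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < m; ++j) {
      const double dx = Q(j, 0) - px, dy = Q(j, 1) - py;
      const double d = dx * dx + dy * dy;
      if (d < best) { best = d; bj = j; }
    }
    out[i] = bj + 1;
  }
  return out;
}
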