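#include <Rcpp.h>
using namespace Rcpp;

// Classic DTW accumulated cost with absolute-difference local cost and
// symmetric steps (1,0), (0,1), (1,1); full alignment, no window.
// [[Rcpp::export(name = ".dtw_cost_cpp")]]
double dtw_cost_cpp(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1);
  prev[0] = 0.0;
  for (int i = 0; i < n; ++i) {
    cur[0] = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double c = std::abs(a[i] - b[j]);
      double best = std::min(prev[j], std::min(prev[j + 1], cur[j]));
      cur[j + 1] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
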