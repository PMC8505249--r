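#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Rolling trimmed mean over precomputed window index bounds.
// x: probe x column matrix; lo, hi: 1-based inclusive row-index bounds of
// each probe's window (windows are contiguous index runs because probes are
// sorted by position within a tile); trim: fraction removed from each tail
// (floor(trim * n) values, matching R's mean(x, trim=)).
// [[Rcpp::export(name = ".window_trimmed_mean_cpp")]]
NumericMatrix window_trimmed_mean_cpp(NumericMatrix x, IntegerVector lo,
                                      IntegerVector hi, double trim) {
  const int P = x.nrow(), C = x.ncol();
  if (lo.size() != P || hi.size() != P)
    stop("window bounds must have one entry per probe");
  NumericMatrix out(P, C);
  std::vector<double> buf;
  for (int j = 0; j < C; ++j) {
    const double* col = &x(0, j);
    for (int i = 0; i < P; ++i) {
      const int a = lo[i] - 1, b = hi[i] - 1;
      if (a < 0 || b >= P || b < a) stop("invalid window bounds at probe %d", i + 1);
      const int n = b - a + 1;
      const int k = (int)std::floor(trim * n);
      if (2 * k >= n) stop("trim removes the whole window");
      if (k == 0) {
        double s = 0.0;
        for (int t = a; t <= b; ++t) s += col[t];
        out(i, j) = s / n;
      } else {
        buf.assign(col + a, col + b + 1);
        std::sort(buf.begin(), buf.end());
        double s = 0.0;
        for (int t = k; t < n - k; ++t) s += buf[t];
        out(i, j) = s / (n - 2 * k);
      }
    }
  }
  return out;
}
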