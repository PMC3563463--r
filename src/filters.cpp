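#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Sliding-window median on a pre-padded matrix: the input carries k extra
// pixels on every side and the output drops them, so every window is full.
// [[Rcpp::export]]
NumericMatrix sliding_median_cpp(NumericMatrix padded, int k) {
  const int nr = padded.nrow() - 2 * k, nc = padded.ncol() - 2 * k;
  const int w = 2 * k + 1, n = w * w;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(n);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int m = 0;
      for (int cc = c; cc < c + w; ++cc)
        for (int rr = r; rr < r + w; ++rr)
          buf[m++] = padded(rr, cc);
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
      double med = buf[n / 2];
      if (n % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + n / 2 - 1, buf.end());
        med = (med + buf[n / 2 - 1]) / 2.0;
      }
      out(r, c) = med;
    }
  return out;
}
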