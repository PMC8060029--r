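#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Median of |x| over many (possibly overlapping) windows, via
// nth_element. Used by the Quiroga-threshold stability metric, where a
// thousand 10 s windows of a 40 kHz trace make R-level medians the
// bottleneck.
// [[Rcpp::export(.windowMedianAbs)]]
NumericVector windowMedianAbs(NumericVector x, IntegerVector starts,
                              int wlen) {
  int nw = starts.size();
  NumericVector out(nw);
  std::vector<double> buf(wlen);
  for (int w = 0; w < nw; ++w) {
    int s0 = starts[w] - 1;  // 1-based from R
    if (s0 < 0 || s0 + wlen > x.size())
      stop("window out of range");
    for (int i = 0; i < wlen; ++i) buf[i] = std::fabs(x[s0 + i]);
    int mid = wlen / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double m = buf[mid];
    if (wlen % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + mid - 1,
                       buf.begin() + mid);
      m = 0.5 * (m + buf[mid - 1]);
    }
    out[w] = m;
  }
  return out;
}
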