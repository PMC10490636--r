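// Hot path of feature extraction: alpha-trimmed means of every
// (window, channel) cell. Trim rule matches trimmed_mean() in R:
// k = floor(alpha * n / 100), reduced to floor((n - 1) / 2) if it would
// exhaust the window.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".window_trimmed_means")]]
NumericMatrix window_trimmed_means(NumericMatrix x, IntegerVector starts,
                                   int len, double alpha) {
  const int nw = starts.size(), nc = x.ncol();
  if (len < 1) stop("window length must be >= 1");
  int k = (int)std::floor(alpha * len / 100.0);
  if (2 * k >= len) k = (len - 1) / 2;
  NumericMatrix out(nw, nc);
  std::vector<double> buf(len);
  for (int w = 0; w < nw; ++w) {
    const int s = starts[w] - 1;  // 1-based from R
    if (s < 0 || s + len > x.nrow()) stop("window exceeds the sequence");
    for (int j = 0; j < nc; ++j) {
      for (int t = 0; t < len; ++t) buf[t] = x(s + t, j);
      std::sort(buf.begin(), buf.end());
      double acc = 0.0;
      for (int t = k; t < len - k; ++t) acc += buf[t];
      out(w, j) = acc / (len - 2 * k);
    }
  }
  return out;
}
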