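#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Centered running percentile with truncated windows at the edges.
// For frame t the window is [t - half, t + half] intersected with the trace;
// the percentile is the linearly interpolated type-7 quantile of that window.
// O(n * w log w) per trace; fast enough for 20 Hz sessions where pure R is not.
// [[Rcpp::export(name = ".running_percentile_cpp")]]
NumericVector running_percentile_cpp(NumericVector x, int half, double prob) {
  const int n = x.size();
  NumericVector out(n);
  std::vector<double> win;
  win.reserve(2 * half + 1);
  for (int t = 0; t < n; ++t) {
    int lo = std::max(0, t - half);
    int hi = std::min(n - 1, t + half);
    int m = hi - lo + 1;
    win.assign(x.begin() + lo, x.begin() + hi + 1);
    // type-7 quantile: h = (m - 1) * prob
    double h = (m - 1) * prob;
    int k = (int)std::floor(h);
    double g = h - k;
    std::nth_element(win.begin(), win.begin() + k, win.end());
    double qk = win[k];
    if (g > 0.0 && k + 1 < m) {
      double qk1 = *std::min_element(win.begin() + k + 1, win.end());
      qk += g * (qk1 - qk);
    }
    out[t] = qk;
  }
  return out;
}
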