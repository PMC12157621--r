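#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Gini mean difference via the sorted-order identity
//   GMD = 2/(n(n-1)) * sum_i (2i - n - 1) x_(i)
// [[Rcpp::export]]
double gini_cpp(NumericVector x) {
  const int n = x.size();
  std::vector<double> s(x.begin(), x.end());
  std::sort(s.begin(), s.end());
  double acc = 0.0;
  for (int i = 0; i < n; ++i) acc += (2.0 * (i + 1) - n - 1.0) * s[i];
  return 2.0 * acc / (static_cast<double>(n) * (n - 1));
}

static double median_inplace(std::vector<double>& v) {
  const size_t n = v.size();
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double hi = v[h];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(v.begin(), v.begin() + h);
  return 0.5 * (lo + hi);
}

// unscaled median absolute deviation: median(|x - median(x)|)
// [[Rcpp::export]]
double mad_cpp(NumericVector x) {
  std::vector<double> v(x.begin(), x.end());
  double med = median_inplace(v);
  for (size_t i = 0; i < v.size(); ++i) v[i] = std::fabs(x[i] - med);
  return median_inplace(v);
}
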