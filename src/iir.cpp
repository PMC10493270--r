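// Direct-form II transposed IIR filter with explicit initial state,
// enabling steady-state initialization for zero-phase filtering.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".iir_filter_cpp")]]
NumericVector iir_filter_cpp(const NumericVector& b, const NumericVector& a,
                             const NumericVector& x,
                             const NumericVector& zi) {
  const int n = x.size();
  const int m = std::max(b.size(), a.size()) - 1;
  std::vector<double> z(zi.begin(), zi.end());
  z.resize(m, 0.0);
  std::vector<double> bb(b.begin(), b.end());
  bb.resize(m + 1, 0.0);
  std::vector<double> aa(a.begin(), a.end());
  aa.resize(m + 1, 0.0);
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + (m > 0 ? z[0] : 0.0);
    for (int k = 0; k < m - 1; ++k) {
      z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    }
    if (m > 0) z[m - 1] = bb[m] * xi - aa[m] * yi;
    y[i] = yi;
  }
  return y;
}
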