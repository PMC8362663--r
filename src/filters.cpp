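#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with explicit initial state.
// b, a: transfer-function coefficients (a[0] must be 1 after scaling),
// zi: initial delay-line state of length max(len(a), len(b)) - 1.
// [[Rcpp::export(name = ".lfilter_cpp")]]
NumericVector lfilter_cpp(NumericVector b, NumericVector a, NumericVector x,
                          NumericVector zi) {
  int nb = b.size(), na = a.size();
  int n = std::max(nb, na);
  int m = n - 1;
  std::vector<double> bb(n, 0.0), aa(n, 0.0);
  double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  std::vector<double> z(m, 0.0);
  for (int i = 0; i < std::min((int)zi.size(), m); ++i) z[i] = zi[i];
  int N = x.size();
  NumericVector y(N);
  for (int t = 0; t < N; ++t) {
    double xt = x[t];
    double yt = bb[0] * xt + (m > 0 ? z[0] : 0.0);
    for (int i = 0; i < m - 1; ++i)
      z[i] = bb[i + 1] * xt + z[i + 1] - aa[i + 1] * yt;
    if (m > 0) z[m - 1] = bb[m] * xt - aa[m] * yt;
    y[t] = yt;
  }
  return y;
}
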