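#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// One-directional IIR filter, direct form II transposed, with initial
// state zi (length max(len(a), len(b)) - 1). a[0] must be non-zero.
// [[Rcpp::export]]
NumericVector lfilter_df2t(NumericVector b, NumericVector a, NumericVector x,
                           NumericVector zi) {
  const int n = x.size();
  const int nf = std::max(a.size(), b.size());
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  if (aa[0] == 0.0) stop("a[1] must be non-zero");
  for (int i = 0; i < nf; ++i) { bb[i] /= aa[0]; }
  for (int i = nf - 1; i >= 0; --i) { aa[i] /= aa[0]; }

  std::vector<double> z(nf - 1, 0.0);
  for (int i = 0; i < zi.size() && i < nf - 1; ++i) z[i] = zi[i];

  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + z[0];
    for (int j = 0; j < nf - 2; ++j) {
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    }
    z[nf - 2] = bb[nf - 1] * xi - aa[nf - 1] * yi;
    y[i] = yi;
  }
  return y;
}
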