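#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with carried state, so a signal can be
// processed in arbitrary chunks with output identical to one whole-trace pass.
// b, a: transfer-function coefficients (a[0] must be 1 after normalisation);
// zi: state vector of length max(length(a), length(b)) - 1 (zeros for a cold
// start). Returns the filtered chunk and the final state.
// [[Rcpp::export]]
List iir_filter_state(NumericVector b, NumericVector a, NumericVector x,
                      NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nfilt = std::max(nb, na);
  if ((int)zi.size() != nfilt - 1) stop("zi must have length %d", nfilt - 1);
  if (a[0] == 0) stop("a[1] must be non-zero");

  std::vector<double> bb(nfilt, 0.0), aa(nfilt, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];

  int n = x.size();
  NumericVector y(n);
  std::vector<double> z(zi.begin(), zi.end());

  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (nfilt > 1 ? z[0] : 0.0);
    for (int j = 0; j < nfilt - 2; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    if (nfilt > 1)
      z[nfilt - 2] = bb[nfilt - 1] * xi - aa[nfilt - 1] * yi;
    y[i] = yi;
  }
  return List::create(_["y"] = y, _["zf"] = NumericVector(z.begin(), z.end()));
}
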