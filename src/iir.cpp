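#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter: y = filter(b, a, x), a[0] == 1
// assumed after normalization. Sequential recursion, hence compiled.
// [[Rcpp::export]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nz = std::max(nb, na) - 1;
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0), z(nz, 0.0);
  double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int j = 0; j < nz - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    if (nz > 0)
      z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return y;
}
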