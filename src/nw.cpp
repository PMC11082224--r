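#include <Rcpp.h>
using namespace Rcpp;

// Nadaraya-Watson regression of r on x evaluated at the query points q.
// kernel: 1 = gaussian, 2 = epanechnikov. A query with zero kernel mass
// (possible for the compact Epanechnikov kernel) yields NaN; the R wrapper
// substitutes the global response mean there. With loo = true the queries
// must be the support points in order and the diagonal (self) kernel term
// is excluded from both sums.
// [[Rcpp::export]]
NumericVector nw_smooth_cpp(NumericVector x, NumericVector r,
                            NumericVector q, double b, int kernel,
                            bool loo = false) {
  const R_xlen_t n = x.size(), m = q.size();
  NumericVector out(m);
  for (R_xlen_t j = 0; j < m; ++j) {
    double num = 0.0, den = 0.0;
    const double z = q[j];
    if (kernel == 1) {
      for (R_xlen_t i = 0; i < n; ++i) {
        const double u = (x[i] - z) / b;
        const double k = std::exp(-0.5 * u * u);
        num += k * r[i];
        den += k;
      }
    } else {
      for (R_xlen_t i = 0; i < n; ++i) {
        const double u = (x[i] - z) / b;
        if (u > -1.0 && u < 1.0) {
          const double k = 0.75 * (1.0 - u * u);
          num += k * r[i];
          den += k;
        }
      }
    }
    if (loo) {
      const double k0 = (kernel == 1) ? 1.0 : 0.75;
      num -= k0 * r[j];
      den -= k0;
    }
    out[j] = (den > 0.0) ? num / den : NA_REAL;
  }
  return out;
}
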