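#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian-kernel CDF estimate per gene (row-wise), bandwidth s_i / 4.
// F(x_ij) = (1/n) * sum_k Phi((x_ij - x_ik) / h_i). Rows with zero sample
// standard deviation must be removed by the caller before this is reached.
// [[Rcpp::export(name = ".kcdf_gauss")]]
NumericMatrix kcdf_gauss(NumericMatrix x) {
  const int p = x.nrow(), n = x.ncol();
  NumericMatrix out(p, n);
  for (int i = 0; i < p; ++i) {
    double m = 0.0;
    for (int j = 0; j < n; ++j) m += x(i, j);
    m /= n;
    double v = 0.0;
    for (int j = 0; j < n; ++j) {
      const double d = x(i, j) - m;
      v += d * d;
    }
    v /= (n - 1);
    const double h = std::sqrt(v) / 4.0;
    if (h <= 0.0) stop("constant gene row reached the kernel (row %d)", i + 1);
    // accumulate pairwise Phi((x_j - x_k)/h) using Phi(-z) = 1 - Phi(z):
    // each unordered pair is evaluated once
    for (int j = 0; j < n; ++j) out(i, j) = 0.5;  // k == j term
    for (int j = 0; j < n; ++j) {
      const double xj = x(i, j);
      for (int k = j + 1; k < n; ++k) {
        // Phi(z) = erfc(-z / sqrt(2)) / 2
        const double phi = 0.5 * std::erfc(-(xj - x(i, k)) / h * M_SQRT1_2);
        out(i, j) += phi;
        out(i, k) += 1.0 - phi;
      }
    }
    for (int j = 0; j < n; ++j) out(i, j) /= n;
  }
  out.attr("dimnames") = x.attr("dimnames");
  return out;
}
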