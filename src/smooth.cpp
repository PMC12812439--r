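#include <Rcpp.h>
using namespace Rcpp;

// Gaussian-kernel smoothed methylation proportion at each cytosine:
//   p(x_j) = sum_i K((x_j - x_i)/h) * meth_i / sum_i K((x_j - x_i)/h) * total_i
// with K the standard normal kernel, truncated at truncate_sd standard
// deviations (weights beyond that are exactly zero).  Positions must be
// sorted strictly increasing; a two-pointer sweep keeps the cost linear in
// the number of (site, neighbour-in-window) pairs.  NA is returned where
// the weighted total is zero (no coverage anywhere in the window).
// [[Rcpp::export]]
NumericVector cpp_kernel_smooth(NumericVector positions, NumericVector meth,
                                NumericVector total, double bandwidth,
                                double truncate_sd = 3.0) {
  const int n = positions.size();
  if (meth.size() != n || total.size() != n)
    stop("positions, meth and total must have equal length");
  if (bandwidth <= 0) stop("bandwidth must be positive");
  NumericVector out(n);
  const double cutoff = truncate_sd * bandwidth;
  const double inv2h2 = 1.0 / (2.0 * bandwidth * bandwidth);
  int lo = 0;
  for (int j = 0; j < n; ++j) {
    const double x = positions[j];
    while (lo < n && positions[lo] < x - cutoff) ++lo;
    double num = 0.0, den = 0.0;
    for (int i = lo; i < n && positions[i] <= x + cutoff; ++i) {
      const double d = positions[i] - x;
      const double w = std::exp(-d * d * inv2h2);
      num += w * meth[i];
      den += w * total[i];
    }
    out[j] = (den > 0.0) ? num / den : NA_REAL;
  }
  return out;
}
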