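#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sum of Euclidean distances over all unordered pairs of rows of a 2-column
// coordinate matrix. O(s^2); called thousands of times per permutation test,
// hence compiled.
// [[Rcpp::export(name = ".sum_pairwise_dist")]]
double sum_pairwise_dist(NumericMatrix xy) {
  const int s = xy.nrow();
  double total = 0.0;
  for (int i = 0; i < s - 1; ++i) {
    const double xi = xy(i, 0), yi = xy(i, 1);
    for (int j = i + 1; j < s; ++j) {
      const double dx = xi - xy(j, 0), dy = yi - xy(j, 1);
      total += std::sqrt(dx * dx + dy * dy);
    }
  }
  return total;
}

// Batched version for permutation nulls: `idx` holds one draw per column
// (1-based row indices into `coords`); returns the pairwise-distance sum of
// each draw. Sampling stays in R so the RNG stream is seed-reproducible.
// [[Rcpp::export(name = ".sum_pairwise_dist_draws")]]
NumericVector sum_pairwise_dist_draws(NumericMatrix coords, IntegerMatrix idx) {
  const int s = idx.nrow(), n = idx.ncol();
  NumericVector out(n);
  std::vector<double> x(s), y(s);
  for (int k = 0; k < n; ++k) {
    for (int i = 0; i < s; ++i) {
      const int r = idx(i, k) - 1;
      x[i] = coords(r, 0);
      y[i] = coords(r, 1);
    }
    double total = 0.0;
    for (int i = 0; i < s - 1; ++i) {
      for (int j = i + 1; j < s; ++j) {
        const double dx = x[i] - x[j], dy = y[i] - y[j];
        total += std::sqrt(dx * dx + dy * dy);
      }
    }
    out[k] = total;
  }
  return out;
}
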