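#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Gaussian kernel sums over mapped insertion positions, truncated at
// `trunc` bp (callers use ~6*sigma, where the per-site error is < 2e-8).
// Positions and evaluation points must be sorted ascending.

// [[Rcpp::export]]
NumericVector cpp_kde_eval(NumericVector xs, NumericVector sites,
                           double sigma, double trunc) {
  const R_xlen_t m = xs.size(), n = sites.size();
  NumericVector out(m);
  if (n == 0 || m == 0) return out;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  R_xlen_t lo = 0;
  for (R_xlen_t i = 0; i < m; ++i) {
    const double x = xs[i];
    while (lo < n && sites[lo] < x - trunc) ++lo;
    double acc = 0.0;
    for (R_xlen_t j = lo; j < n && sites[j] <= x + trunc; ++j) {
      const double d = x - sites[j];
      acc += std::exp(-d * d * inv2s2);
    }
    out[i] = acc;
  }
  return out;
}

// Evaluation grid for one chromosome: multiples of `step` within `trunc`
// of any site (clipped to [lo, hi]) plus the exact site positions.
// Returns a sorted, de-duplicated vector.

// [[Rcpp::export]]
NumericVector cpp_kde_grid(NumericVector sites, double step, double trunc,
                           double lo, double hi) {
  const R_xlen_t n = sites.size();
  std::vector<double> xs;
  if (n == 0) return NumericVector(0);
  const long kmin_all = (long)std::ceil(lo / step);
  const long kmax_all = (long)std::floor(hi / step);
  long last_k = kmin_all - 1;
  for (R_xlen_t i = 0; i < n; ++i) {
    long k0 = (long)std::ceil((sites[i] - trunc) / step);
    long k1 = (long)std::floor((sites[i] + trunc) / step);
    if (k0 < kmin_all) k0 = kmin_all;
    if (k1 > kmax_all) k1 = kmax_all;
    if (k0 <= last_k) k0 = last_k + 1;  // sites sorted => ranges ordered
    for (long k = k0; k <= k1; ++k) xs.push_back((double)k * step);
    if (k1 > last_k) last_k = k1;
  }
  for (R_xlen_t i = 0; i < n; ++i) xs.push_back(sites[i]);
  std::sort(xs.begin(), xs.end());
  xs.erase(std::unique(xs.begin(), xs.end()), xs.end());
  return wrap(xs);
}

// Genome-wide maximum of the kernel profile for one chromosome, i.e.
// max over the snapped grid and the exact site positions.

// [[Rcpp::export]]
double cpp_kde_max(NumericVector sites, double sigma, double step,
                   double trunc, double lo, double hi) {
  const R_xlen_t n = sites.size();
  if (n == 0) return 0.0;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  NumericVector xs = cpp_kde_grid(sites, step, trunc, lo, hi);
  const R_xlen_t m = xs.size();
  double best = 0.0;
  R_xlen_t lo_i = 0;
  for (R_xlen_t i = 0; i < m; ++i) {
    const double x = xs[i];
    while (lo_i < n && sites[lo_i] < x - trunc) ++lo_i;
    double acc = 0.0;
    for (R_xlen_t j = lo_i; j < n && sites[j] <= x + trunc; ++j) {
      const double d = x - sites[j];
      acc += std::exp(-d * d * inv2s2);
    }
    if (acc > best) best = acc;
  }
  return best;
}
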