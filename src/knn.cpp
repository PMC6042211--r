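#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Linear time-scaled distance, squared:
//   d^2 = dx^2 + dy^2 + (s * vmax * dt)^2
// `svmax` is the product s * vmax (m/s scaled by the dimensionless s).
static inline double tsd2(double x1, double y1, double t1,
                          double x2, double y2, double t2, double svmax) {
  const double dx = x1 - x2, dy = y1 - y2, dz = svmax * (t1 - t2);
  return dx * dx + dy * dy + dz * dz;
}

// k nearest neighbours of every fix under the time-scaled distance.
// Parent is its own neighbour (distance 0). Ties broken by smaller index.
// Returns an n x k matrix of 1-based indices, ordered by (distance, index).
// [[Rcpp::export]]
IntegerMatrix cpp_knn_tsd(NumericVector x, NumericVector y, NumericVector t,
                          double svmax, int k) {
  const int n = x.size();
  if (k < 1 || k > n) stop("k out of range [1, n]");
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int> > d(n);
  for (int p = 0; p < n; ++p) {
    for (int i = 0; i < n; ++i)
      d[i] = std::make_pair(tsd2(x[i], y[i], t[i], x[p], y[p], t[p], svmax), i);
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int j = 0; j < k; ++j) out(p, j) = d[j].second + 1;
  }
  return out;
}

// Neighbours of a single parent (1-based index), same ordering contract.
// [[Rcpp::export]]
IntegerVector cpp_knn_tsd_one(NumericVector x, NumericVector y, NumericVector t,
                              double svmax, int k, int parent) {
  const int n = x.size();
  if (k < 1 || k > n) stop("k out of range [1, n]");
  if (parent < 1 || parent > n) stop("parent index out of range");
  const int p = parent - 1;
  std::vector<std::pair<double, int> > d(n);
  for (int i = 0; i < n; ++i)
    d[i] = std::make_pair(tsd2(x[i], y[i], t[i], x[p], y[p], t[p], svmax), i);
  std::partial_sort(d.begin(), d.begin() + k, d.end());
  IntegerVector out(k);
  for (int j = 0; j < k; ++j) out[j] = d[j].second + 1;
  return out;
}
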