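#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <utility>
#include <vector>
using namespace Rcpp;

// k nearest neighbours by Euclidean distance, restricted to the +/- window
// Chebyshev box around each point; distance ties broken by id_rank.
// Returns an n x k matrix of 1-based indices; an all-NA row marks a point
// with fewer than k in-window neighbours (the discard rule).
// [[Rcpp::export]]
IntegerMatrix knn_window_cpp(NumericVector x, NumericVector y,
                             IntegerVector id_rank, int k, double window) {
  const int n = x.size();
  if (k < 1) stop("k must be >= 1");
  if (window <= 0) stop("window must be > 0");
  IntegerMatrix out(n, k);
  std::fill(out.begin(), out.end(), NA_INTEGER);
  std::vector<std::pair<double, int> > cand;
  cand.reserve(n);
  for (int i = 0; i < n; ++i) {
    cand.clear();
    const double xi = x[i], yi = y[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = x[j] - xi, dy = y[j] - yi;
      if (std::fabs(dx) <= window && std::fabs(dy) <= window)
        cand.push_back(std::make_pair(dx * dx + dy * dy, j));
    }
    if ((int)cand.size() < k) continue;
    const IntegerVector& rk = id_rank;
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end(),
                      [&rk](const std::pair<double, int>& a,
                            const std::pair<double, int>& b) {
                        if (a.first != b.first) return a.first < b.first;
                        return rk[a.second] < rk[b.second];
                      });
    for (int m = 0; m < k; ++m) out(i, m) = cand[m].second + 1;
  }
  return out;
}
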