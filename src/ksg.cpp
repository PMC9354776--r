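#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger (algorithm 1) mutual information
// estimator for two continuous variables, in nats:
//
//   I(X;Y) ~= psi(k) + psi(n) - < psi(nx_i + 1) + psi(ny_i + 1) >
//
// where eps_i is the Chebyshev distance from point i to its k-th nearest
// neighbour in the joint space and nx_i / ny_i count marginal neighbours
// strictly inside eps_i.  O(n^2), exact (no space partitioning), hence
// invariant under adding a constant to x or y.  In the counting loops the
// self term (distance 0 < eps) contributes the "+1" of psi(nx+1).
// [[Rcpp::export]]
double ksg_mi_cpp(NumericVector xs, NumericVector ys, int k) {
  const int n = xs.size();
  if (ys.size() != n) stop("x and y must have equal length");
  if (k < 1 || k > n - 1) stop("k must be in [1, n-1]");
  const double *x = REAL(xs), *y = REAL(ys);
  std::vector<double> d(n - 1);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i];
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = std::fabs(xi - x[j]);
      const double dy = std::fabs(yi - y[j]);
      d[m++] = dx > dy ? dx : dy;
    }
    std::nth_element(d.begin(), d.begin() + (k - 1), d.end());
    const double eps = d[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      nx += std::fabs(xi - x[j]) < eps;
      ny += std::fabs(yi - y[j]) < eps;
    }
    acc += R::digamma((double)nx) + R::digamma((double)ny);
  }
  return R::digamma((double)k) + R::digamma((double)n) - acc / n;
}
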