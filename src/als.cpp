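// Banded solver for the asymmetric penalized least-squares baseline:
// (diag(w) + lambda * t(D2) %*% D2) z = w * y, with D2 the second
// difference operator. The system is symmetric positive definite and
// pentadiagonal, so an LDL^T factorization with bandwidth 2 solves it
// in O(n).
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".als_solve_banded")]]
NumericVector als_solve_banded(NumericVector w, NumericVector y,
                               double lambda) {
  const int n = w.size();
  if (y.size() != n) stop("w and y must have equal length");
  if (n < 3) stop("need at least 3 points");

  // Assemble the three bands of diag(w) + lambda * D2'D2.
  std::vector<double> d0(n), d1(n - 1), d2(n - 2);
  for (int i = 0; i < n; ++i) {
    double m = 0.0;                       // sum over rows k of D2 covering i
    if (i <= n - 3) m += 1.0;             // k = i      (coef 1)
    if (i >= 1 && i - 1 <= n - 3) m += 4.0; // k = i - 1 (coef -2)
    if (i >= 2 && i - 2 <= n - 3) m += 1.0; // k = i - 2 (coef 1)
    d0[i] = w[i] + lambda * m;
  }
  for (int i = 0; i < n - 1; ++i) {
    double m = 0.0;
    if (i <= n - 3) m += -2.0;            // k = i: (1)(-2)
    if (i >= 1 && i - 1 <= n - 3) m += -2.0; // k = i - 1: (-2)(1)
    d1[i] = lambda * m;
  }
  for (int i = 0; i < n - 2; ++i) d2[i] = lambda * 1.0;

  // LDL^T factorization, bandwidth 2 (L unit lower triangular).
  std::vector<double> D(n), L1(n - 1), L2(n - 2);
  for (int i = 0; i < n; ++i) {
    double di = d0[i];
    if (i >= 1) di -= L1[i - 1] * L1[i - 1] * D[i - 1];
    if (i >= 2) di -= L2[i - 2] * L2[i - 2] * D[i - 2];
    D[i] = di;
    if (i + 1 < n) {
      double l1 = d1[i];
      if (i >= 1) l1 -= L1[i - 1] * L2[i - 1] * D[i - 1];
      L1[i] = l1 / D[i];
    }
    if (i + 2 < n) L2[i] = d2[i] / D[i];
  }

  // Solve L v = w*y, then D u = v, then L^T z = u.
  NumericVector z(n);
  for (int i = 0; i < n; ++i) {
    double v = w[i] * y[i];
    if (i >= 1) v -= L1[i - 1] * z[i - 1];
    if (i >= 2) v -= L2[i - 2] * z[i - 2];
    z[i] = v;
  }
  for (int i = 0; i < n; ++i) z[i] /= D[i];
  for (int i = n - 1; i >= 0; --i) {
    double v = z[i];
    if (i + 1 < n) v -= L1[i] * z[i + 1];
    if (i + 2 < n) v -= L2[i] * z[i + 2];
    z[i] = v;
  }
  return z;
}
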