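// Dual coordinate descent for the L1-loss (hinge) linear SVM WITHOUT an
// intercept, i.e. the ranking primal
//   min_w  1/2 ||w||^2 + C * sum_i max(0, 1 - y_i w.x_i)
// (liblinear's algorithm for L1-loss dual, no bias term). Differences of
// feature vectors make an intercept unidentifiable, so none is fitted.
// Deterministic: coordinate order is a seeded permutation per epoch.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {
struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  int unif_int(int n) { return (int)(next() % (uint64_t)n); }
};
} // namespace

// [[Rcpp::export(name = ".svm_dcd")]]
List svm_dcd(NumericMatrix X, NumericVector y, double C, int max_epochs,
             double tol, int seed) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> w(p, 0.0), alpha(n, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    double q = 0.0;
    for (int d = 0; d < p; ++d) q += X(i, d) * X(i, d);
    qii[i] = q;
  }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  SplitMix64 rng((uint64_t)seed * 0x9e3779b9ULL + 7ULL);

  // liblinear-style shrinking: bound variables whose gradient is safely
  // past the previous epoch's violation range leave the active set until
  // a full-pass convergence check re-admits them
  const double INF = std::numeric_limits<double>::infinity();
  int active = n;
  double PGmax_old = INF, PGmin_old = -INF;
  bool converged = false;
  int ep = 0;
  for (; ep < max_epochs; ++ep) {
    for (int i = active - 1; i > 0; --i)
      std::swap(order[i], order[rng.unif_int(i + 1)]);
    double PGmax = -INF, PGmin = INF;
    for (int t = 0; t < active; ++t) {
      int i = order[t];
      if (qii[i] <= 0.0) continue; // all-zero row cannot move
      double dot = 0.0;
      for (int d = 0; d < p; ++d) dot += w[d] * X(i, d);
      double G = y[i] * dot - 1.0;
      double PG = 0.0;
      if (alpha[i] <= 0.0) {
        if (G > PGmax_old) { // shrink
          --active;
          std::swap(order[t], order[active]);
          --t;
          continue;
        }
        if (G < 0.0) PG = G;
      } else if (alpha[i] >= C) {
        if (G < PGmin_old) {
          --active;
          std::swap(order[t], order[active]);
          --t;
          continue;
        }
        if (G > 0.0) PG = G;
      } else {
        PG = G;
      }
      if (PG > PGmax) PGmax = PG;
      if (PG < PGmin) PGmin = PG;
      if (std::fabs(PG) > 1e-12) {
        double a_old = alpha[i];
        double a_new = a_old - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        alpha[i] = a_new;
        double delta = (a_new - a_old) * y[i];
        if (delta != 0.0)
          for (int d = 0; d < p; ++d) w[d] += delta * X(i, d);
      }
    }
    if (PGmax - PGmin < tol || active == 0) {
      if (active == n) {
        converged = true;
        break;
      }
      // optimal on the active set: re-admit everything and verify
      active = n;
      PGmax_old = INF;
      PGmin_old = -INF;
      continue;
    }
    PGmax_old = PGmax <= 0.0 ? INF : PGmax;
    PGmin_old = PGmin >= 0.0 ? -INF : PGmin;
  }

  return List::create(_["weights"] = NumericVector(w.begin(), w.end()),
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["epochs"] = ep + 1, _["converged"] = converged);
}
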