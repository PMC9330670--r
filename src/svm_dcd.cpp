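#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Dual coordinate descent for the soft-margin linear SVM with hinge loss
// (Hsieh et al. 2008, Algorithm 1). The bias term is handled by augmenting
// every observation with a constant feature of value `bias`, which is the
// usual trick for linear solvers. y must be coded -1/+1.
//
// A small local LCG drives the per-epoch permutation so that results are
// bit-reproducible for a given integer seed, independent of the standard
// library's shuffle implementation.

static inline double lcg_next(unsigned long long &state) {
  state = state * 6364136223846793005ULL + 1442695040888963407ULL;
  return (double)(state >> 11) / 9007199254740992.0; // 2^53
}

// [[Rcpp::export]]
List svm_dcd(NumericMatrix X, NumericVector y, double C, double bias,
             double tol, int max_epochs, int seed) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> w(p + 1, 0.0), alpha(n, 0.0), Qii(n);
  for (int i = 0; i < n; ++i) {
    double q = bias * bias;
    for (int j = 0; j < p; ++j) q += X(i, j) * X(i, j);
    Qii[i] = q;
  }
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  unsigned long long rng = (unsigned long long)(seed) * 2654435761ULL + 1ULL;

  // shrinking heuristic as in liblinear: bounded variables whose projected
  // gradient lies strictly outside the last epoch's range are frozen until
  // the reduced problem converges, then one clean full pass confirms.
  const double INF = std::numeric_limits<double>::infinity();
  int active = n;
  double pgmax_old = INF, pgmin_old = -INF;
  int epoch = 0;
  bool converged = false;
  for (epoch = 0; epoch < max_epochs; ++epoch) {
    // Fisher-Yates permutation of the active block
    for (int t = active - 1; t > 0; --t) {
      int k = (int)(lcg_next(rng) * (t + 1));
      if (k > t) k = t;
      std::swap(idx[t], idx[k]);
    }
    double pgmax_new = -INF, pgmin_new = INF;
    for (int t = 0; t < active; ++t) {
      const int i = idx[t];
      if (Qii[i] <= 0) continue; // all-zero row: alpha stays put
      double g = bias * w[p];
      for (int j = 0; j < p; ++j) g += X(i, j) * w[j];
      g = y[i] * g - 1.0;
      double pg = 0.0;
      if (alpha[i] <= 0.0) {
        if (g > pgmax_old) { // shrink
          --active;
          std::swap(idx[t], idx[active]);
          --t;
          continue;
        }
        if (g < 0.0) pg = g;
      } else if (alpha[i] >= C) {
        if (g < pgmin_old) {
          --active;
          std::swap(idx[t], idx[active]);
          --t;
          continue;
        }
        if (g > 0.0) pg = g;
      } else pg = g;
      if (pg > pgmax_new) pgmax_new = pg;
      if (pg < pgmin_new) pgmin_new = pg;
      if (std::fabs(pg) > 1e-12) {
        const double a_old = alpha[i];
        double a_new = a_old - g / Qii[i];
        if (a_new < 0.0) a_new = 0.0;
        else if (a_new > C) a_new = C;
        alpha[i] = a_new;
        const double delta = (a_new - a_old) * y[i];
        for (int j = 0; j < p; ++j) w[j] += delta * X(i, j);
        w[p] += delta * bias;
      }
    }
    if (pgmax_new - pgmin_new <= tol) {
      if (active == n) { converged = true; ++epoch; break; }
      active = n; // unshrink and confirm with a full pass
      pgmax_old = INF; pgmin_old = -INF;
      continue;
    }
    pgmax_old = pgmax_new > 0 ? pgmax_new : INF;
    pgmin_old = pgmin_new < 0 ? pgmin_new : -INF;
  }
  NumericVector wv(p);
  for (int j = 0; j < p; ++j) wv[j] = w[j];
  return List::create(_["w"] = wv, _["b"] = w[p] * bias,
                      _["converged"] = converged, _["epochs"] = epoch,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()));
}
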