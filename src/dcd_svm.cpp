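#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Dual coordinate descent for the L1-loss (hinge) linear SVM
// (Hsieh et al. 2008, the LIBLINEAR solver, with shrinking).  Solves
//   min_a  1/2 a' Q a - e' a   s.t. 0 <= a_i <= C,  Q_ij = y_i y_j x_i' x_j,
// maintaining w = sum_i a_i y_i x_i.  Stopping rule: PGmax - PGmin < tol
// over an outer pass, as in LIBLINEAR.  The bias is handled by the caller
// via an augmented constant feature.  A fixed xorshift permutation stream
// makes the fit deterministic.
static inline uint32_t xorshift32(uint32_t &s) {
  s ^= s << 13; s ^= s >> 17; s ^= s << 5; return s;
}

// [[Rcpp::export]]
List dcd_linear_svm(const NumericMatrix &X, const NumericVector &y,
                    double C, int max_epochs, double tol,
                    uint32_t perm_seed) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> w(d, 0.0), alpha(n, 0.0), qii(n);
  const double *xp = X.begin();
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += xp[i + (size_t)j * n] * xp[i + (size_t)j * n];
    qii[i] = s;
  }
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  int n_active = n;
  uint32_t rng = perm_seed ? perm_seed : 1u;
  double pgmax_old = R_PosInf, pgmin_old = R_NegInf;
  int epoch = 0;
  bool converged = false;
  for (epoch = 0; epoch < max_epochs; ++epoch) {
    // shuffle the active set
    for (int i = n_active - 1; i > 0; --i) {
      int j = (int)(xorshift32(rng) % (uint32_t)(i + 1));
      std::swap(active[i], active[j]);
    }
    double pgmax = R_NegInf, pgmin = R_PosInf;
    for (int t = 0; t < n_active; ++t) {
      const int i = active[t];
      if (qii[i] <= 0.0) continue;
      double G = 0.0;
      for (int j = 0; j < d; ++j) G += w[j] * xp[i + (size_t)j * n];
      G = y[i] * G - 1.0;
      double pg = 0.0;
      if (alpha[i] <= 0.0) {
        if (G > pgmax_old) {  // shrink: stuck at lower bound
          active[t--] = active[--n_active];
          continue;
        }
        if (G < 0.0) pg = G;
      } else if (alpha[i] >= C) {
        if (G < pgmin_old) {  // shrink: stuck at upper bound
          active[t--] = active[--n_active];
          continue;
        }
        if (G > 0.0) pg = G;
      } else {
        pg = G;
      }
      if (pg > pgmax) pgmax = pg;
      if (pg < pgmin) pgmin = pg;
      if (std::fabs(pg) > 1e-12) {
        double a_old = alpha[i];
        double a_new = std::min(std::max(a_old - G / qii[i], 0.0), C);
        alpha[i] = a_new;
        double delta = (a_new - a_old) * y[i];
        if (delta != 0.0)
          for (int j = 0; j < d; ++j) w[j] += delta * xp[i + (size_t)j * n];
      }
    }
    if (pgmax - pgmin < tol) {
      if (n_active == n) { converged = true; ++epoch; break; }
      // re-activate everything and take one clean pass before stopping
      n_active = n;
      for (int i = 0; i < n; ++i) active[i] = i;
      pgmax_old = R_PosInf; pgmin_old = R_NegInf;
      continue;
    }
    pgmax_old = pgmax <= 0.0 ? R_PosInf : pgmax;
    pgmin_old = pgmin >= 0.0 ? R_NegInf : pgmin;
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["epochs"] = epoch,
                      _["converged"] = converged);
}
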