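// Sequential minimal optimization for the C-cost soft-margin SVC dual on a
// precomputed kernel.  Minimizes 0.5 a'Qa - e'a with Q_ij = y_i y_j K_ij
// subject to y'a = 0, 0 <= a_i <= C, using first-order maximal-violating-
// pair working-set selection.  Problem sizes here are small (tens of
// samples), so the full kernel is held densely and no caching or shrinking
// is needed.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".Call_smo_solve")]]
List smo_solve(NumericMatrix K, NumericVector y, double C,
               double eps = 1e-6, int maxIter = 1000000,
               Nullable<NumericVector> warmAlpha = R_NilValue) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("kernel must be square");
  if (y.size() != n) stop("labels must match kernel size");
  const double TAU = 1e-12;

  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  if (warmAlpha.isNotNull()) {
    NumericVector a0(warmAlpha);
    if (a0.size() != n) stop("warm start must match kernel size");
    for (int t = 0; t < n; ++t)
      alpha[t] = std::min(std::max(a0[t], 0.0), C);
    for (int t = 0; t < n; ++t) {
      double acc = 0.0;
      for (int s = 0; s < n; ++s)
        if (alpha[s] > 0) acc += alpha[s] * y[s] * K(t, s);
      G[t] = y[t] * acc - 1.0;
    }
  }

  int iter = 0;
  for (; iter < maxIter; ++iter) {
    // second-order working-set selection: i maximizes the violation,
    // j maximizes the guaranteed objective decrease against i
    int i = -1, j = -1;
    double gmax = -std::numeric_limits<double>::infinity();
    double gmin = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      double v = -y[t] * G[t];
      if (up && v > gmax) { gmax = v; i = t; }
    }
    if (i >= 0) {
      double best = -std::numeric_limits<double>::infinity();
      for (int t = 0; t < n; ++t) {
        bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
        if (!low) continue;
        double v = -y[t] * G[t];
        if (v < gmin) gmin = v;
        double bdiff = gmax - v;
        if (bdiff > 0) {
          double quad = K(i, i) + K(t, t) - 2.0 * y[i] * y[t] * K(i, t);
          if (quad <= 0) quad = TAU;
          double dec = bdiff * bdiff / quad;
          if (dec > best) { best = dec; j = t; }
        }
      }
    }
    if (i < 0 || j < 0 || gmax - gmin < eps) break;

    const double yi = y[i], yj = y[j];
    const double Kii = K(i, i), Kjj = K(j, j), Kij = K(i, j);
    const double oldAi = alpha[i], oldAj = alpha[j];

    if (yi != yj) {
      double quad = Kii + Kjj + 2.0 * Kij * yi * yj;  // = Qii+Qjj+2Qij
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = Kii + Kjj - 2.0 * Kij * yi * yj;
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    const double dAi = alpha[i] - oldAi, dAj = alpha[j] - oldAj;
    if (dAi == 0.0 && dAj == 0.0) break;  // numerically stuck
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (yi * K(t, i) * dAi + yj * K(t, j) * dAj);
  }

  // bias: average of y_t - f0_t over free SVs, else midpoint of bounds
  double ub = std::numeric_limits<double>::infinity();
  double lb = -std::numeric_limits<double>::infinity();
  double sumFree = 0.0;
  int nFree = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];  // = f0_t - y_t
    if (alpha[t] >= C - 1e-12) {
      if (y[t] < 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 1e-12) {
      if (y[t] > 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      ++nFree; sumFree += yG;
    }
  }
  double rho = (nFree > 0) ? sumFree / nFree : (ub + lb) / 2.0;

  NumericVector alphaSigned(n), alphaRaw(n);
  for (int t = 0; t < n; ++t) {
    alphaSigned[t] = alpha[t] * y[t];
    alphaRaw[t] = alpha[t];
  }
  return List::create(_["alphaSigned"] = alphaSigned, _["bias"] = -rho,
                      _["alpha"] = alphaRaw, _["iterations"] = iter);
}
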