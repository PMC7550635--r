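#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// SMO solver for the kernel SVM dual
//   min 1/2 a'Qa - e'a   s.t. y'a = 0, 0 <= a <= C,  Q_ij = y_i y_j K_ij
// using maximal-violating-pair working-set selection.  Operates on an
// index subset of a precomputed n_total x n_total kernel so that
// leave-one-out loops need no kernel copies.
static void smo_core(const double *K, int n_total,
                     const std::vector<int> &idx,
                     const double *y, double C, double tol, int max_iter,
                     std::vector<double> &alpha, double &b, int &iters) {
  const int n = (int)idx.size();
  alpha.assign(n, 0.0);
  std::vector<double> G(n, -1.0);  // gradient of the dual objective
  iters = 0;
  while (iters < max_iter) {
    // select i: argmax of -y_t G_t over I_up; j: argmin over I_low
    int i = -1, j = -1;
    double gmax = -1e300, gmin = 1e300;
    for (int t = 0; t < n; ++t) {
      const double yt = y[idx[t]];
      const bool up = (yt > 0 && alpha[t] < C) || (yt < 0 && alpha[t] > 0);
      const bool low = (yt > 0 && alpha[t] > 0) || (yt < 0 && alpha[t] < C);
      const double v = -yt * G[t];
      if (up && v > gmax) { gmax = v; i = t; }
      if (low && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) break;
    ++iters;
    const int gi = idx[i], gj = idx[j];
    const double yi = y[gi], yj = y[gj];
    const double kii = K[(size_t)gi * n_total + gi];
    const double kjj = K[(size_t)gj * n_total + gj];
    const double kij = K[(size_t)gi * n_total + gj];
    double quad = kii + kjj - 2.0 * kij;
    if (quad <= 1e-12) quad = 1e-12;
    double d = (gmax - gmin) / quad;  // step along (y_i e_i, -y_j e_j)
    // box clipping
    if (yi > 0) d = std::min(d, C - alpha[i]); else d = std::min(d, alpha[i]);
    if (yj > 0) d = std::min(d, alpha[j]); else d = std::min(d, C - alpha[j]);
    if (d <= 0) break;
    alpha[i] += yi > 0 ? d : -d;
    alpha[j] -= yj > 0 ? d : -d;
    const double dai = (yi > 0 ? d : -d);   // change in alpha_i
    const double daj = -(yj > 0 ? d : -d);  // change in alpha_j
    for (int t = 0; t < n; ++t) {
      const int gt = idx[t];
      const double yt = y[gt];
      G[t] += yt * yi * K[(size_t)gt * n_total + gi] * dai +
              yt * yj * K[(size_t)gt * n_total + gj] * daj;
    }
  }
  // bias from free support vectors (0 < alpha < C); else midpoint of bounds
  double bsum = 0.0; int bcnt = 0;
  double gmax = -1e300, gmin = 1e300;
  for (int t = 0; t < n; ++t) {
    const double yt = y[idx[t]];
    const double v = -yt * G[t];
    const bool up = (yt > 0 && alpha[t] < C) || (yt < 0 && alpha[t] > 0);
    const bool low = (yt > 0 && alpha[t] > 0) || (yt < 0 && alpha[t] < C);
    if (alpha[t] > 1e-9 * C && alpha[t] < C * (1 - 1e-9)) { bsum += v; ++bcnt; }
    if (up && v > gmax) gmax = v;
    if (low && v < gmin) gmin = v;
  }
  b = bcnt > 0 ? bsum / bcnt : (gmax + gmin) / 2.0;
}

// [[Rcpp::export]]
List svm_smo(NumericMatrix K, NumericVector y, double C,
             double tol = 1e-6, int max_iter = 100000) {
  const int n = K.nrow();
  std::vector<int> idx(n);
  for (int t = 0; t < n; ++t) idx[t] = t;
  std::vector<double> alpha;
  double b; int iters;
  smo_core(K.begin(), n, idx, y.begin(), C, tol, max_iter, alpha, b, iters);
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iters);
}

// Inner leave-one-out grid search: for every (beta row, C) candidate,
// combine the modality kernels, run LOOCV over the n subjects, and
// return the accuracy matrix (n_beta x n_C).
// [[Rcpp::export]]
NumericMatrix mkl_inner_cv(List kernels, NumericVector y, NumericMatrix betas,
                           NumericVector c_grid, double tol = 1e-6,
                           int max_iter = 100000) {
  const int n = y.size();
  const int n_mod = kernels.size();
  const int n_beta = betas.nrow(), n_c = c_grid.size();
  std::vector<const double *> Kp(n_mod);
  for (int m = 0; m < n_mod; ++m) {
    NumericMatrix Km = kernels[m];
    if (Km.nrow() != n || Km.ncol() != n) stop("kernel dimension mismatch");
    Kp[m] = REAL(Km);
  }
  std::vector<double> Kc((size_t)n * n);
  NumericMatrix acc(n_beta, n_c);
  std::vector<int> idx(n - 1);
  std::vector<double> alpha;
  for (int bi = 0; bi < n_beta; ++bi) {
    for (size_t e = 0; e < (size_t)n * n; ++e) {
      double s = 0.0;
      for (int m = 0; m < n_mod; ++m) s += betas(bi, m) * Kp[m][e];
      Kc[e] = s;
    }
    for (int ci = 0; ci < n_c; ++ci) {
      const double C = c_grid[ci];
      int correct = 0;
      for (int hold = 0; hold < n; ++hold) {
        int pos = 0, neg = 0;
        for (int t = 0; t < n; ++t) if (t != hold) (y[t] > 0 ? pos : neg)++;
        if (pos == 0 || neg == 0) continue;  // degenerate inner fold
        int k = 0;
        for (int t = 0; t < n; ++t) if (t != hold) idx[k++] = t;
        double b; int iters;
        smo_core(Kc.data(), n, idx, y.begin(), C, tol, max_iter, alpha, b, iters);
        double f = b;
        for (int t = 0; t < n - 1; ++t)
          f += alpha[t] * y[idx[t]] * Kc[(size_t)idx[t] * n + hold];
        const double pred = f > 0 ? 1.0 : -1.0;
        if (pred == y[hold]) ++correct;
      }
      acc(bi, ci) = (double)correct / n;
    }
  }
  return acc;
}
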