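#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Online self-organizing map on a non-periodic sheet lattice.
// One training cycle presents every row of X once, in a random order drawn
// from R's RNG (so set.seed() governs the whole run).  Learning rate and
// neighborhood radius decay linearly per cycle; the Gaussian lattice
// kernel is tabulated once per cycle and neurons with negligible kernel
// weight are skipped.  Neurons are indexed column-major over the lattice:
// k = ix + nx*iy (0-based here, 1-based in the BMU vector of som_bmu_cpp).
// [[Rcpp::export]]
List train_som_cpp(NumericMatrix X, int nx, int ny, int cycles,
                   NumericMatrix codebook0,
                   double alpha0, double alpha1,
                   double radius0, double radius1) {
  int n = X.nrow(), d = X.ncol(), m = nx * ny;
  if (codebook0.nrow() != m || codebook0.ncol() != d)
    stop("codebook dimensions do not match grid/features");
  // row-major copies for cache-friendly inner loops
  std::vector<double> x(n * d), w(m * d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) x[i * d + j] = X(i, j);
  for (int k = 0; k < m; ++k)
    for (int j = 0; j < d; ++j) w[k * d + j] = codebook0(k, j);
  std::vector<double> lat2(m * m);
  for (int a = 0; a < m; ++a)
    for (int b = 0; b < m; ++b) {
      double dx = a % nx - b % nx, dy = a / nx - b / nx;
      lat2[a * m + b] = dx * dx + dy * dy;
    }
  NumericVector qerr(cycles);
  std::vector<int> ord(n), nb_idx(m * m), nb_cnt(m);
  std::vector<double> h(m * m);
  for (int cyc = 0; cyc < cycles; ++cyc) {
    double frac = (cycles > 1) ? (double)cyc / (cycles - 1) : 0.0;
    double alpha = alpha0 + (alpha1 - alpha0) * frac;
    double radius = radius0 + (radius1 - radius0) * frac;
    if (radius < 1e-8) radius = 1e-8;
    double denom = 2.0 * radius * radius;
    for (int a = 0; a < m; ++a) {
      int cnt = 0;
      for (int b = 0; b < m; ++b) {
        double hv = std::exp(-lat2[a * m + b] / denom);
        if (hv >= 1e-4) {
          h[a * m + cnt] = alpha * hv;
          nb_idx[a * m + cnt] = b;
          ++cnt;
        }
      }
      nb_cnt[a] = cnt;
    }
    // Fisher-Yates shuffle via R RNG
    for (int i = 0; i < n; ++i) ord[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      int tmp = ord[i]; ord[i] = ord[j]; ord[j] = tmp;
    }
    double qsum = 0.0;
    for (int ii = 0; ii < n; ++ii) {
      const double *xi = &x[(size_t)ord[ii] * d];
      int best = 0;
      double bestd = R_PosInf;
      for (int k = 0; k < m; ++k) {
        const double *wk = &w[(size_t)k * d];
        double acc = 0.0;
        for (int j = 0; j < d; ++j) {
          double diff = xi[j] - wk[j];
          acc += diff * diff;
        }
        if (acc < bestd) { bestd = acc; best = k; }
      }
      qsum += std::sqrt(bestd);
      for (int t = 0; t < nb_cnt[best]; ++t) {
        double *wk = &w[(size_t)nb_idx[best * m + t] * d];
        double ah = h[best * m + t];
        for (int j = 0; j < d; ++j)
          wk[j] += ah * (xi[j] - wk[j]);
      }
    }
    qerr[cyc] = qsum / n;
  }
  NumericMatrix W(m, d);
  for (int k = 0; k < m; ++k)
    for (int j = 0; j < d; ++j) W(k, j) = w[k * d + j];
  return List::create(_["codebook"] = W, _["qerr"] = qerr);
}

// Best-matching unit (1-based) for every row of X.
// [[Rcpp::export]]
IntegerVector som_bmu_cpp(NumericMatrix X, NumericMatrix W) {
  int n = X.nrow(), d = X.ncol(), m = W.nrow();
  if (W.ncol() != d) stop("dimension mismatch");
  IntegerVector bmu(n);
  for (int i = 0; i < n; ++i) {
    int best = 0;
    double bestd = R_PosInf;
    for (int k = 0; k < m; ++k) {
      double acc = 0.0;
      for (int j = 0; j < d; ++j) {
        double diff = X(i, j) - W(k, j);
        acc += diff * diff;
      }
      if (acc < bestd) { bestd = acc; best = k; }
    }
    bmu[i] = best + 1;
  }
  return bmu;
}
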