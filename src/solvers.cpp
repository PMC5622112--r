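#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Deterministic 32-bit xorshift; keeps the solver independent of R's RNG
// state so fits are reproducible from the seed argument alone.
static inline uint32_t xorshift32(uint32_t &s) {
  s ^= s << 13; s ^= s >> 17; s ^= s << 5;
  return s;
}

//' @keywords internal
// Dual coordinate descent for the L2-regularized L1-loss (hinge) linear SVM
// (Hsieh et al. 2008). Xt is d x n (one sample per column, contiguous in
// memory); y in {-1, +1}. The bias is realized as an implicit constant
// feature of value 1, so it carries the same L2 penalty as the weights.
// [[Rcpp::export]]
List svm_dcd(NumericMatrix Xt, NumericVector y, double C, double tol,
             int max_epochs, int seed) {
  const int d = Xt.nrow(), n = Xt.ncol();
  std::vector<double> w(d + 1, 0.0), alpha(n, 0.0), Qii(n);
  const double *X = REAL(Xt);
  for (int i = 0; i < n; ++i) {
    const double *xi = X + (size_t)i * d;
    double s = 1.0;  // bias feature
    for (int j = 0; j < d; ++j) s += xi[j] * xi[j];
    Qii[i] = s;
  }
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  int active_size = n;
  uint32_t st = (uint32_t)seed * 2654435761u + 88172645u;
  // shrinking thresholds (Hsieh et al. 2008 / LIBLINEAR)
  double Mbar = R_PosInf, mbar = R_NegInf;
  int epoch = 0;
  double gap = R_PosInf;
  for (epoch = 0; epoch < max_epochs; ++epoch) {
    double PGmax = R_NegInf, PGmin = R_PosInf;
    for (int i = active_size - 1; i > 0; --i) {
      int j = (int)(xorshift32(st) % (uint32_t)(i + 1));
      std::swap(active[i], active[j]);
    }
    int s = 0;
    while (s < active_size) {
      const int i = active[s];
      const double yi = y[i];
      const double *xi = X + (size_t)i * d;
      double wx = w[d];
      for (int j = 0; j < d; ++j) wx += w[j] * xi[j];
      const double G = yi * wx - 1.0;
      double PG = 0.0;
      if (alpha[i] <= 0.0) {
        if (G > Mbar) {  // shrink: optimal at lower bound
          --active_size;
          std::swap(active[s], active[active_size]);
          continue;
        }
        if (G < 0.0) PG = G;
      } else if (alpha[i] >= C) {
        if (G < mbar) {  // shrink: optimal at upper bound
          --active_size;
          std::swap(active[s], active[active_size]);
          continue;
        }
        if (G > 0.0) PG = G;
      } else {
        PG = G;
      }
      if (PG > PGmax) PGmax = PG;
      if (PG < PGmin) PGmin = PG;
      if (std::fabs(PG) > 1e-12) {
        const double a_old = alpha[i];
        const double a_new = std::min(std::max(a_old - G / Qii[i], 0.0), C);
        const double delta = (a_new - a_old) * yi;
        if (delta != 0.0) {
          for (int j = 0; j < d; ++j) w[j] += delta * xi[j];
          w[d] += delta;
          alpha[i] = a_new;
        }
      }
      ++s;
    }
    gap = PGmax - PGmin;
    if (!R_finite(gap)) gap = 0.0;  // empty active set
    if (gap <= tol) {
      if (active_size == n) { ++epoch; break; }
      // converged on the shrunk problem: restore and verify on full set
      active_size = n;
      Mbar = R_PosInf; mbar = R_NegInf;
      continue;
    }
    Mbar = PGmax > 0.0 ? PGmax : R_PosInf;
    mbar = PGmin < 0.0 ? PGmin : R_NegInf;
  }
  NumericVector wout(d);
  for (int j = 0; j < d; ++j) wout[j] = w[j];
  return List::create(_["w"] = wout, _["b"] = w[d],
                      _["epochs"] = epoch, _["violation"] = gap,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()));
}

// Unbiased squared-MMD for one pair of 1-D samples with Gaussian kernel.
static double mmd2_1d(const double *x, int m, const double *y, int n,
                      double sigma, bool printed) {
  const double g = 1.0 / (2.0 * sigma * sigma);
  double sxx = 0.0, syy = 0.0, sxy = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = i + 1; j < m; ++j) {
      const double d = x[i] - x[j];
      sxx += std::exp(-d * d * g);
    }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double d = y[i] - y[j];
      syy += std::exp(-d * d * g);
    }
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) {
      if (printed && j == i) continue;
      const double d = x[i] - y[j];
      sxy += std::exp(-d * d * g);
    }
  return 2.0 * sxx / ((double)m * (m - 1)) +
         2.0 * syy / ((double)n * (n - 1)) -
         2.0 * sxy / ((double)m * n);
}

//' @keywords internal
// Per-column 1-D unbiased squared MMD between X (m x p) and Y (n x p).
// Each column is standardized by the pooled mean/sd, the bandwidth is the
// per-column median heuristic over pooled pairwise distances (fallback:
// smallest nonzero distance). Constant columns yield mmd2 = 0, sigma = NA.
// Returns a p x 2 matrix (mmd2, sigma).
// [[Rcpp::export]]
NumericMatrix mmd1d_columns(NumericMatrix Xm, NumericMatrix Ym, bool printed) {
  const int m = Xm.nrow(), n = Ym.nrow(), p = Xm.ncol();
  NumericMatrix out(p, 2);
  const int N = m + n;
  std::vector<double> z(N), dists;
  dists.reserve((size_t)N * (N - 1) / 2);
  for (int c = 0; c < p; ++c) {
    for (int i = 0; i < m; ++i) z[i] = Xm(i, c);
    for (int i = 0; i < n; ++i) z[m + i] = Ym(i, c);
    double mu = 0.0;
    for (int i = 0; i < N; ++i) mu += z[i];
    mu /= N;
    double v = 0.0;
    for (int i = 0; i < N; ++i) v += (z[i] - mu) * (z[i] - mu);
    v /= (N - 1);
    if (v <= 0.0) { out(c, 0) = 0.0; out(c, 1) = NA_REAL; continue; }
    const double sd = std::sqrt(v);
    for (int i = 0; i < N; ++i) z[i] = (z[i] - mu) / sd;
    dists.clear();
    double minpos = R_PosInf;
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        const double d = std::fabs(z[i] - z[j]);
        if (d > 0.0) {
          dists.push_back(d);
          if (d < minpos) minpos = d;
        }
      }
    if (dists.empty()) { out(c, 0) = 0.0; out(c, 1) = NA_REAL; continue; }
    const size_t k = dists.size() / 2;
    std::nth_element(dists.begin(), dists.begin() + k, dists.end());
    double med = dists[k];
    if (dists.size() % 2 == 0) {
      double lo = *std::max_element(dists.begin(), dists.begin() + k);
      med = 0.5 * (lo + med);
    }
    double sigma = med > 0.0 ? med : minpos;
    out(c, 0) = mmd2_1d(&z[0], m, &z[m], n, sigma, printed);
    out(c, 1) = sigma;
  }
  return out;
}
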