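#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1D squared Euclidean distance transform (lower envelope of parabolas,
// Felzenszwalb & Huttenlocher) with sample spacing h.
static void dt1d(const double *f, double *d, int n, double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  // background is encoded as a large finite value so the parabola
  // intersection below never evaluates INF - INF

  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  const double h2 = h * h;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2.0 * h2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = h * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact anisotropic Euclidean distance transform of a binary mask.
// Returns distances in mm to the nearest foreground voxel centre.
// [[Rcpp::export]]
NumericVector edt3d_cpp(NumericVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  const double BIG = 1e20;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] > 0.5 ? 0.0 : BIG;

  int maxdim = std::max(d0, std::max(d1, d2));
  std::vector<double> f(maxdim), d(maxdim);

  // axis 0
  for (int k = 0; k < d2; ++k)
    for (int j = 0; j < d1; ++j) {
      double *col = &g[(R_xlen_t)d0 * (j + (R_xlen_t)d1 * k)];
      dt1d(col, d.data(), d0, spacing[0]);
      std::copy(d.begin(), d.begin() + d0, col);
    }
  // axis 1
  for (int k = 0; k < d2; ++k)
    for (int i = 0; i < d0; ++i) {
      for (int j = 0; j < d1; ++j) f[j] = g[i + (R_xlen_t)d0 * (j + (R_xlen_t)d1 * k)];
      dt1d(f.data(), d.data(), d1, spacing[1]);
      for (int j = 0; j < d1; ++j) g[i + (R_xlen_t)d0 * (j + (R_xlen_t)d1 * k)] = d[j];
    }
  // axis 2
  for (int j = 0; j < d1; ++j)
    for (int i = 0; i < d0; ++i) {
      for (int k = 0; k < d2; ++k) f[k] = g[i + (R_xlen_t)d0 * (j + (R_xlen_t)d1 * k)];
      dt1d(f.data(), d.data(), d2, spacing[2]);
      for (int k = 0; k < d2; ++k) g[i + (R_xlen_t)d0 * (j + (R_xlen_t)d1 * k)] = d[k];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}
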