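#include <Rcpp.h>
using namespace Rcpp;

// 3D array access, R column-major layout: arr[i + d0*(j + d1*k)]
static inline double at3(const double *a, int d0, int d1, int d2,
                         int i, int j, int k, double fill) {
  if (i < 0 || j < 0 || k < 0 || i >= d0 || j >= d1 || k >= d2) return fill;
  return a[i + (R_xlen_t)d0 * (j + (R_xlen_t)d1 * k)];
}

// Trilinear sampling at fractional 0-based voxel coordinates.
// Corners outside the array contribute `fill`.
// [[Rcpp::export]]
NumericVector sample_trilinear_cpp(NumericVector arr, IntegerVector dim,
                                   NumericMatrix coords, double fill = 0.0) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const double *a = arr.begin();
  const R_xlen_t n = coords.nrow();
  NumericVector out(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    double x = coords(r, 0), y = coords(r, 1), z = coords(r, 2);
    if (!R_finite(x) || !R_finite(y) || !R_finite(z)) { out[r] = NA_REAL; continue; }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double v = 0.0;
    for (int di = 0; di < 2; ++di)
      for (int dj = 0; dj < 2; ++dj)
        for (int dk = 0; dk < 2; ++dk) {
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          if (w != 0.0)
            v += w * at3(a, d0, d1, d2, i0 + di, j0 + dj, k0 + dk, fill);
        }
    out[r] = v;
  }
  return out;
}

// Trilinear sampling with analytic gradient w.r.t. voxel coordinates.
// Returns an n x 4 matrix: value, d/di, d/dj, d/dk.
// [[Rcpp::export]]
NumericMatrix sample_trilinear_grad_cpp(NumericVector arr, IntegerVector dim,
                                        NumericMatrix coords, double fill = 0.0) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const double *a = arr.begin();
  const R_xlen_t n = coords.nrow();
  NumericMatrix out(n, 4);
  for (R_xlen_t r = 0; r < n; ++r) {
    double x = coords(r, 0), y = coords(r, 1), z = coords(r, 2);
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double c[2][2][2];
    for (int di = 0; di < 2; ++di)
      for (int dj = 0; dj < 2; ++dj)
        for (int dk = 0; dk < 2; ++dk)
          c[di][dj][dk] = at3(a, d0, d1, d2, i0 + di, j0 + dj, k0 + dk, fill);
    double wx[2] = {1 - fx, fx}, wy[2] = {1 - fy, fy}, wz[2] = {1 - fz, fz};
    double v = 0, gx = 0, gy = 0, gz = 0;
    for (int di = 0; di < 2; ++di)
      for (int dj = 0; dj < 2; ++dj)
        for (int dk = 0; dk < 2; ++dk) {
          double cc = c[di][dj][dk];
          v  += wx[di] * wy[dj] * wz[dk] * cc;
          gx += (di ? 1.0 : -1.0) * wy[dj] * wz[dk] * cc;
          gy += (dj ? 1.0 : -1.0) * wx[di] * wz[dk] * cc;
          gz += (dk ? 1.0 : -1.0) * wx[di] * wy[dj] * cc;
        }
    out(r, 0) = v; out(r, 1) = gx; out(r, 2) = gy; out(r, 3) = gz;
  }
  return out;
}

// Nearest-neighbour sampling (for label masks).
// [[Rcpp::export]]
NumericVector sample_nearest_cpp(NumericVector arr, IntegerVector dim,
                                 NumericMatrix coords, double fill = 0.0) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const double *a = arr.begin();
  const R_xlen_t n = coords.nrow();
  NumericVector out(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    int i = (int)std::lround(coords(r, 0));
    int j = (int)std::lround(coords(r, 1));
    int k = (int)std::lround(coords(r, 2));
    out[r] = at3(a, d0, d1, d2, i, j, k, fill);
  }
  return out;
}
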