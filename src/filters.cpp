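#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian smoothing; sigma per axis in voxel units.  The kernel
// is truncated at 3 sigma and renormalised at the array boundary so that a
// constant image stays constant.
// [[Rcpp::export]]
NumericVector gaussian_smooth_cpp(NumericVector arr, IntegerVector dim,
                                  NumericVector sigma) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  std::vector<double> src(arr.begin(), arr.end()), dst(n);

  const R_xlen_t stride[3] = {1, (R_xlen_t)d[0], (R_xlen_t)d[0] * d[1]};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int rad = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * rad + 1);
    for (int t = -rad; t <= rad; ++t)
      ker[t + rad] = std::exp(-0.5 * (t * t) / (s * s));
    const int len = d[ax];
    const R_xlen_t st = stride[ax];
    // iterate over all lines along axis ax
    const int dA = d[(ax + 1) % 3], dB = d[(ax + 2) % 3];
    const R_xlen_t stA = stride[(ax + 1) % 3], stB = stride[(ax + 2) % 3];
    for (int b = 0; b < dB; ++b)
      for (int a = 0; a < dA; ++a) {
        R_xlen_t base = a * stA + b * stB;
        for (int p = 0; p < len; ++p) {
          double acc = 0.0, wsum = 0.0;
          int lo = std::max(-rad, -p), hi = std::min(rad, len - 1 - p);
          for (int t = lo; t <= hi; ++t) {
            double w = ker[t + rad];
            acc += w * src[base + (R_xlen_t)(p + t) * st];
            wsum += w;
          }
          dst[base + (R_xlen_t)p * st] = acc / wsum;
        }
      }
    std::swap(src, dst);
  }
  return NumericVector(src.begin(), src.end());
}

// Discrete Laplacian with anisotropic spacing (mm).  Along each axis the
// second difference at the boundary uses linear extrapolation of the field
// (free boundary), so the operator annihilates affine fields exactly.
// [[Rcpp::export]]
NumericVector laplacian_cpp(NumericVector arr, IntegerVector dim,
                            NumericVector spacing) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  NumericVector out(n);
  const double *a = arr.begin();
  const double w0 = 1.0 / (spacing[0] * spacing[0]);
  const double w1 = 1.0 / (spacing[1] * spacing[1]);
  const double w2 = 1.0 / (spacing[2] * spacing[2]);
  for (int k = 0; k < d2; ++k)
    for (int j = 0; j < d1; ++j) {
      R_xlen_t base = (R_xlen_t)d0 * (j + (R_xlen_t)d1 * k);
      for (int i = 0; i < d0; ++i) {
        R_xlen_t idx = base + i;
        double v = 0.0;
        if (i > 0 && i < d0 - 1)
          v += w0 * (a[idx - 1] - 2.0 * a[idx] + a[idx + 1]);
        if (j > 0 && j < d1 - 1)
          v += w1 * (a[idx - d0] - 2.0 * a[idx] + a[idx + d0]);
        if (k > 0 && k < d2 - 1) {
          R_xlen_t s = (R_xlen_t)d0 * d1;
          v += w2 * (a[idx - s] - 2.0 * a[idx] + a[idx + s]);
        }
        out[idx] = v;
      }
    }
  return out;
}

// 26-connected component labelling of a binary mask (flood fill).
// [[Rcpp::export]]
IntegerVector label_components_cpp(NumericVector mask, IntegerVector dim) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] <= 0.5 || lab[s] != 0) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int i = (int)(cur % d0), j = (int)((cur / d0) % d1), k = (int)(cur / ((R_xlen_t)d0 * d1));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= d0 || jj >= d1 || kk >= d2) continue;
            R_xlen_t q = ii + (R_xlen_t)d0 * (jj + (R_xlen_t)d1 * kk);
            if (mask[q] > 0.5 && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Adjoint of laplacian_cpp (the operator above is not symmetric at the
// boundary rows, which produce no output; its transpose zeroes those rows
// of the input before applying the interior stencil).
// [[Rcpp::export]]
NumericVector laplacian_adjoint_cpp(NumericVector arr, IntegerVector dim,
                                    NumericVector spacing) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  NumericVector out(n);
  const double w[3] = {1.0 / (spacing[0] * spacing[0]),
                       1.0 / (spacing[1] * spacing[1]),
                       1.0 / (spacing[2] * spacing[2])};
  for (int k = 0; k < d2; ++k)
    for (int j = 0; j < d1; ++j)
      for (int i = 0; i < d0; ++i) {
        R_xlen_t idx = i + (R_xlen_t)d0 * (j + (R_xlen_t)d1 * k);
        double v = arr[idx];
        if (v == 0.0) continue;
        // axis 0: row i contributes only if interior along axis 0
        if (i > 0 && i < d0 - 1) {
          out[idx - 1] += w[0] * v;
          out[idx] -= 2.0 * w[0] * v;
          out[idx + 1] += w[0] * v;
        }
        if (j > 0 && j < d1 - 1) {
          out[idx - d0] += w[1] * v;
          out[idx] -= 2.0 * w[1] * v;
          out[idx + d0] += w[1] * v;
        }
        if (k > 0 && k < d2 - 1) {
          R_xlen_t s = (R_xlen_t)d0 * d1;
          out[idx - s] += w[2] * v;
          out[idx] -= 2.0 * w[2] * v;
          out[idx + s] += w[2] * v;
        }
      }
  return out;
}
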