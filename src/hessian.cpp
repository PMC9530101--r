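#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// One pass of the interior second-difference Laplacian (free boundary).
static void lap_apply(const double *a, double *out, int d0, int d1, int d2,
                      const double *w) {
  const R_xlen_t s2 = (R_xlen_t)d0 * d1;
  for (int k = 0; k < d2; ++k)
    for (int j = 0; j < d1; ++j) {
      R_xlen_t base = (R_xlen_t)d0 * (j + (R_xlen_t)d1 * k);
      for (int i = 0; i < d0; ++i) {
        R_xlen_t idx = base + i;
        double v = 0.0;
        if (i > 0 && i < d0 - 1)
          v += w[0] * (a[idx - 1] - 2.0 * a[idx] + a[idx + 1]);
        if (j > 0 && j < d1 - 1)
          v += w[1] * (a[idx - d0] - 2.0 * a[idx] + a[idx + d0]);
        if (k > 0 && k < d2 - 1)
          v += w[2] * (a[idx - s2] - 2.0 * a[idx] + a[idx + s2]);
        out[idx] = v;
      }
    }
}

static void lap_adjoint_apply(const double *a, double *out, int d0, int d1,
                              int d2, const double *w) {
  const R_xlen_t s2 = (R_xlen_t)d0 * d1;
  const R_xlen_t n = s2 * d2;
  for (R_xlen_t idx = 0; idx < n; ++idx) out[idx] = 0.0;
  for (int k = 0; k < d2; ++k)
    for (int j = 0; j < d1; ++j) {
      R_xlen_t base = (R_xlen_t)d0 * (j + (R_xlen_t)d1 * k);
      for (int i = 0; i < d0; ++i) {
        R_xlen_t idx = base + i;
        double v = a[idx];
        if (v == 0.0) continue;
        if (i > 0 && i < d0 - 1) {
          out[idx - 1] += w[0] * v; out[idx] -= 2.0 * w[0] * v;
          out[idx + 1] += w[0] * v;
        }
        if (j > 0 && j < d1 - 1) {
          out[idx - d0] += w[1] * v; out[idx] -= 2.0 * w[1] * v;
          out[idx + d0] += w[1] * v;
        }
        if (k > 0 && k < d2 - 1) {
          out[idx - s2] += w[2] * v; out[idx] -= 2.0 * w[2] * v;
          out[idx + s2] += w[2] * v;
        }
      }
    }
}

// Gauss-Newton Hessian-vector product for the deformable objective:
//   H p = vv * G (G . p) + alpha * vv * L^T L p (per component)
//         + beta * vv * Jd (Jd . p) on rows didx + ridge * p
// p, G: n x 3; Jd: m x 3 with 1-based row indices didx.
// [[Rcpp::export]]
NumericMatrix gn_hessian_apply_cpp(NumericMatrix p, NumericMatrix G,
                                   IntegerVector dim, NumericVector spacing,
                                   double alpha, double vv, double ridge,
                                   IntegerVector didx, NumericMatrix Jd,
                                   double beta) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const R_xlen_t n = p.nrow();
  NumericMatrix out(n, 3);
  double w[3] = {1.0 / (spacing[0] * spacing[0]),
                 1.0 / (spacing[1] * spacing[1]),
                 1.0 / (spacing[2] * spacing[2])};
  // SSD block-diagonal part + ridge
  for (R_xlen_t r = 0; r < n; ++r) {
    double dp = G(r, 0) * p(r, 0) + G(r, 1) * p(r, 1) + G(r, 2) * p(r, 2);
    out(r, 0) = vv * G(r, 0) * dp + ridge * p(r, 0);
    out(r, 1) = vv * G(r, 1) * dp + ridge * p(r, 1);
    out(r, 2) = vv * G(r, 2) * dp + ridge * p(r, 2);
  }
  // curvature part, per component
  std::vector<double> tmp(n), tmp2(n), col(n);
  for (int cmp = 0; cmp < 3; ++cmp) {
    for (R_xlen_t r = 0; r < n; ++r) col[r] = p(r, cmp);
    lap_apply(col.data(), tmp.data(), d0, d1, d2, w);
    lap_adjoint_apply(tmp.data(), tmp2.data(), d0, d1, d2, w);
    double av = alpha * vv;
    for (R_xlen_t r = 0; r < n; ++r) out(r, cmp) += av * tmp2[r];
  }
  // distance surrogate part
  const R_xlen_t m = didx.size();
  for (R_xlen_t q = 0; q < m; ++q) {
    R_xlen_t r = didx[q] - 1;
    double dp = Jd(q, 0) * p(r, 0) + Jd(q, 1) * p(r, 1) + Jd(q, 2) * p(r, 2);
    double bv = beta * vv * dp;
    out(r, 0) += bv * Jd(q, 0);
    out(r, 1) += bv * Jd(q, 1);
    out(r, 2) += bv * Jd(q, 2);
  }
  return out;
}
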