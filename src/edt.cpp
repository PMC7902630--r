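// Exact squared Euclidean distance transform in 3D with anisotropic voxel spacing,
// via the separable lower-envelope-of-parabolas algorithm (one pass per axis).
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D transform on samples at physical positions i*s: d(p) = min_q (s(p-q))^2 + f(q).
// Infinite parabolas (no source on this line yet) are skipped.
static void dt1d(std::vector<double> &f, double s, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z) {
  const int n = (int)f.size();
  const double s2 = s * s;
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  int k = 0;
  v[0] = q0; z[0] = -INF; z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double inter;
    while (true) {
      inter = ((f[q] + s2 * (double)q * q) - (f[v[k]] + s2 * (double)v[k] * v[k])) /
              (2.0 * s2 * (q - v[k]));
      if (inter > z[k]) break;
      --k;
    }
    ++k; v[k] = q; z[k] = inter; z[k + 1] = INF;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    d[q] = s2 * (double)(q - v[j]) * (q - v[j]) + f[v[j]];
  }
}

// [[Rcpp::export]]
NumericVector edt_sq_3d(IntegerVector mask, IntegerVector dims, NumericVector spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? 0.0 : INF;
  const int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // axis 1 (stride 1)
  for (int k3 = 0; k3 < n3; ++k3)
    for (int k2 = 0; k2 < n2; ++k2) {
      double *line = REAL(d) + (R_xlen_t)k3 * n1 * n2 + (R_xlen_t)k2 * n1;
      f.assign(line, line + n1); out.resize(n1);
      dt1d(f, spacing[0], out, v, z);
      for (int i = 0; i < n1; ++i) line[i] = out[i];
    }
  // axis 2 (stride n1)
  for (int k3 = 0; k3 < n3; ++k3)
    for (int k1 = 0; k1 < n1; ++k1) {
      double *base = REAL(d) + (R_xlen_t)k3 * n1 * n2 + k1;
      f.resize(n2); out.resize(n2);
      for (int i = 0; i < n2; ++i) f[i] = base[(R_xlen_t)i * n1];
      dt1d(f, spacing[1], out, v, z);
      for (int i = 0; i < n2; ++i) base[(R_xlen_t)i * n1] = out[i];
    }
  // axis 3 (stride n1*n2)
  for (int k2 = 0; k2 < n2; ++k2)
    for (int k1 = 0; k1 < n1; ++k1) {
      double *base = REAL(d) + (R_xlen_t)k2 * n1 + k1;
      f.resize(n3); out.resize(n3);
      for (int i = 0; i < n3; ++i) f[i] = base[(R_xlen_t)i * n1 * n2];
      dt1d(f, spacing[2], out, v, z);
      for (int i = 0; i < n3; ++i) base[(R_xlen_t)i * n1 * n2] = out[i];
    }
  d.attr("dim") = dims;
  return d;
}
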