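// Exact Euclidean distance transform (squared), separable lower-envelope
// algorithm, with anisotropic voxel spacing.  Used for surface distances
// and for shape-based (signed-distance) slice interpolation.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e30;

// 1D squared-distance lower envelope along samples at positions i*h;
// sites with f >= INF are skipped (no seed in that line position).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double h) {
  const double h2 = h * h;
  int k = -1;
  for (int q = 0; q < n; q++) {
    if (f[q] >= INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] - f[p]) / h2 + (double)q * q - (double)p * p) / (2.0 * (q - p));
      if (s <= z[k] && k > 0) { k--; continue; }
      if (s <= z[k] && k == 0) { v[0] = q; z[0] = -INF; z[1] = INF; s = NA_REAL; }
      break;
    }
    if (!ISNA(s)) {
      k++; v[k] = q; z[k] = s; z[k + 1] = INF;
    }
  }
  if (k < 0) {
    for (int q = 0; q < n; q++) d[q] = INF;
    return;
  }
  int kk = 0;
  for (int q = 0; q < n; q++) {
    while (z[kk + 1] < q) kk++;
    double dq = (double)(q - v[kk]) * h;
    d[q] = dq * dq + f[v[kk]];
  }
}

// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector seed, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t V = (R_xlen_t)nx * ny * nz;
  NumericVector out(V);
  double* o = REAL(out);
  const int* sd = LOGICAL(seed);
  for (R_xlen_t i = 0; i < V; i++) o[i] = sd[i] ? 0.0 : INF;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 2);
  std::vector<int> v(nmax);
  for (int zz = 0; zz < nz; zz++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * zz);
      for (int x = 0; x < nx; x++) f[x] = o[base + x];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int x = 0; x < nx; x++) o[base + x] = d[x];
    }
  for (int zz = 0; zz < nz; zz++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * zz;
      for (int y = 0; y < ny; y++) f[y] = o[base + (R_xlen_t)nx * y];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int y = 0; y < ny; y++) o[base + (R_xlen_t)nx * y] = d[y];
    }
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = x + (R_xlen_t)nx * y;
      for (int zz = 0; zz < nz; zz++) f[zz] = o[base + (R_xlen_t)nx * ny * zz];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int zz = 0; zz < nz; zz++) o[base + (R_xlen_t)nx * ny * zz] = d[zz];
    }
  return out;
}
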