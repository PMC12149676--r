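// Mutual-information objective for rigid registration.  The fixed image is
// pre-binned at a set of sample points; the moving image contributes to the
// joint histogram by partial-volume (trilinear) weighting, which makes the
// objective continuous in the transform parameters.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
double mi_transform_cpp(IntegerVector fixed_bins, NumericMatrix pts,
                        NumericVector mov, IntegerVector mdim,
                        NumericVector mspacing, NumericVector morigin,
                        NumericMatrix rot, NumericVector trans,
                        NumericVector center, int nbins, double mmin,
                        double mbw) {
  const int n = fixed_bins.size();
  const int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  const double* m = REAL(mov);
  std::vector<double> joint((size_t)nbins * nbins, 0.0);
  const double r11 = rot(0, 0), r12 = rot(0, 1), r13 = rot(0, 2);
  const double r21 = rot(1, 0), r22 = rot(1, 1), r23 = rot(1, 2);
  const double r31 = rot(2, 0), r32 = rot(2, 1), r33 = rot(2, 2);
  double total = 0;
  for (int i = 0; i < n; i++) {
    double wx = pts(0, i) - center[0], wy = pts(1, i) - center[1],
           wz = pts(2, i) - center[2];
    double px = r11 * wx + r12 * wy + r13 * wz + center[0] + trans[0];
    double py = r21 * wx + r22 * wy + r23 * wz + center[1] + trans[1];
    double pz = r31 * wx + r32 * wy + r33 * wz + center[2] + trans[2];
    double ux = (px - morigin[0]) / mspacing[0];
    double uy = (py - morigin[1]) / mspacing[1];
    double uz = (pz - morigin[2]) / mspacing[2];
    long ix = (long)std::floor(ux), iy = (long)std::floor(uy),
         iz = (long)std::floor(uz);
    if (ix < 0 || iy < 0 || iz < 0 || ix >= nx - 1 || iy >= ny - 1 || iz >= nz - 1)
      continue;
    double fx = ux - ix, fy = uy - iy, fz = uz - iz;
    int fb = fixed_bins[i];
    // trilinear intensity interpolation, then a linear (tent) spread over
    // the two adjacent moving bins keeps the objective continuous
    double val = 0;
    for (int dz = 0; dz < 2; dz++)
      for (int dy = 0; dy < 2; dy++)
        for (int dx = 0; dx < 2; dx++) {
          double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
          val += w * m[(ix + dx) + (R_xlen_t)nx * ((iy + dy) + (R_xlen_t)ny * (iz + dz))];
        }
    double b = (val - mmin) / mbw - 0.5;
    int b0 = (int)std::floor(b);
    double w1 = b - b0;
    int lo = b0 < 0 ? 0 : (b0 >= nbins ? nbins - 1 : b0);
    int hi = b0 + 1 < 0 ? 0 : (b0 + 1 >= nbins ? nbins - 1 : b0 + 1);
    joint[(size_t)fb * nbins + lo] += 1 - w1;
    joint[(size_t)fb * nbins + hi] += w1;
    total += 1;
  }
  if (total <= 0) return 0.0;
  std::vector<double> pf(nbins, 0.0), pm(nbins, 0.0);
  for (int a = 0; a < nbins; a++)
    for (int b = 0; b < nbins; b++) {
      double p = joint[(size_t)a * nbins + b] / total;
      pf[a] += p;
      pm[b] += p;
    }
  double mi = 0;
  for (int a = 0; a < nbins; a++)
    for (int b = 0; b < nbins; b++) {
      double p = joint[(size_t)a * nbins + b] / total;
      if (p > 0 && pf[a] > 0 && pm[b] > 0) mi += p * std::log(p / (pf[a] * pm[b]));
    }
  return mi;
}
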