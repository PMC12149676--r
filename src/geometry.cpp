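// Affine resampling between voxel grids with physical (world) geometry.
// World convention: voxel centres, x_world = origin + spacing * index,
// axes aligned with the canonical right-handed frame.
// The map applied is y = R (x - c) + c + t (fixed/world -> source/world),
// i.e. the transform pulls values from the source at y for each target x.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// mode: 0 = nearest neighbour, 1 = trilinear
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector src, IntegerVector sdim,
                                  NumericVector sspacing, NumericVector sorigin,
                                  IntegerVector tdim, NumericVector tspacing,
                                  NumericVector torigin, NumericMatrix rot,
                                  NumericVector trans, NumericVector center,
                                  int mode, double background) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  NumericVector out((R_xlen_t)tx * ty * tz);
  const double* s = REAL(src);
  double* o = REAL(out);
  const double r11 = rot(0, 0), r12 = rot(0, 1), r13 = rot(0, 2);
  const double r21 = rot(1, 0), r22 = rot(1, 1), r23 = rot(1, 2);
  const double r31 = rot(2, 0), r32 = rot(2, 1), r33 = rot(2, 2);
  R_xlen_t v = 0;
  for (int k = 0; k < tz; k++) {
    double wz = torigin[2] + tspacing[2] * k - center[2];
    for (int j = 0; j < ty; j++) {
      double wy = torigin[1] + tspacing[1] * j - center[1];
      for (int i = 0; i < tx; i++, v++) {
        double wx = torigin[0] + tspacing[0] * i - center[0];
        double px = r11 * wx + r12 * wy + r13 * wz + center[0] + trans[0];
        double py = r21 * wx + r22 * wy + r23 * wz + center[1] + trans[1];
        double pz = r31 * wx + r32 * wy + r33 * wz + center[2] + trans[2];
        double ux = (px - sorigin[0]) / sspacing[0];
        double uy = (py - sorigin[1]) / sspacing[1];
        double uz = (pz - sorigin[2]) / sspacing[2];
        if (mode == 0) {
          long ix = (long)std::lround(ux), iy = (long)std::lround(uy),
               iz = (long)std::lround(uz);
          if (ix < 0 || iy < 0 || iz < 0 || ix >= sx || iy >= sy || iz >= sz) {
            o[v] = background;
          } else {
            o[v] = s[ix + (R_xlen_t)sx * (iy + (R_xlen_t)sy * iz)];
          }
        } else {
          long ix = (long)std::floor(ux), iy = (long)std::floor(uy),
               iz = (long)std::floor(uz);
          if (ix < -1 || iy < -1 || iz < -1 || ix >= sx || iy >= sy || iz >= sz) {
            o[v] = background;
            continue;
          }
          double fx = ux - ix, fy = uy - iy, fz = uz - iz;
          double acc = 0;
          for (int dz = 0; dz < 2; dz++)
            for (int dy = 0; dy < 2; dy++)
              for (int dx = 0; dx < 2; dx++) {
                long xx = ix + dx, yy = iy + dy, zz = iz + dz;
                double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
                double val = (xx < 0 || yy < 0 || zz < 0 || xx >= sx || yy >= sy || zz >= sz)
                                 ? background
                                 : s[xx + (R_xlen_t)sx * (yy + (R_xlen_t)sy * zz)];
                acc += w * val;
              }
          o[v] = acc;
        }
      }
    }
  }
  return out;
}

// Backward warp by a dense displacement field defined on the target grid:
// out(x) = src(x + disp(x)) in world mm, grids identical.
// [[Rcpp::export]]
NumericVector warp_displacement_cpp(NumericVector src, IntegerVector dim,
                                    NumericVector spacing, NumericVector origin,
                                    NumericMatrix disp, int mode,
                                    double background) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double* s = REAL(src);
  double* o = REAL(out);
  R_xlen_t v = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, v++) {
        double ux = i + disp(v, 0) / spacing[0];
        double uy = j + disp(v, 1) / spacing[1];
        double uz = k + disp(v, 2) / spacing[2];
        if (mode == 0) {
          long ix = (long)std::lround(ux), iy = (long)std::lround(uy),
               iz = (long)std::lround(uz);
          o[v] = (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz)
                     ? background
                     : s[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
        } else {
          long ix = (long)std::floor(ux), iy = (long)std::floor(uy),
               iz = (long)std::floor(uz);
          double fx = ux - ix, fy = uy - iy, fz = uz - iz, acc = 0;
          for (int dz = 0; dz < 2; dz++)
            for (int dy = 0; dy < 2; dy++)
              for (int dx = 0; dx < 2; dx++) {
                long xx = ix + dx, yy = iy + dy, zz = iz + dz;
                double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
                double val = (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
                                 ? background
                                 : s[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
                acc += w * val;
              }
          o[v] = acc;
        }
      }
  return out;
}
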