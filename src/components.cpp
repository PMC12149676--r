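// Connected-component labelling for 3D binary masks (6/18/26 connectivity).
// Labels are assigned in raster-scan discovery order, so label 1 is always
// the component containing the lowest-index foreground voxel.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity = 26) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t V = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(V);
  const int* m = LOGICAL(mask);
  int* L = INTEGER(lab);
  for (R_xlen_t i = 0; i < V; i++) L[i] = 0;
  std::vector<int> offx, offy, offz;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        int nn = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nn == 0) continue;
        if (connectivity == 6 && nn > 1) continue;
        if (connectivity == 18 && nn > 2) continue;
        offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
      }
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < V; i++) {
    if (!m[i] || L[i]) continue;
    next++;
    L[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < offx.size(); k++) {
        int xx = x + offx[k], yy = y + offy[k], zz = z + offz[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        R_xlen_t u = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (m[u] && !L[u]) { L[u] = next; stack.push_back(u); }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// Surface voxels: foreground with a face-adjacent background neighbour;
// out-of-volume counts as background.
// [[Rcpp::export]]
LogicalVector surface_voxels_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t V = (R_xlen_t)nx * ny * nz;
  LogicalVector out(V);
  const int* m = LOGICAL(mask);
  int* o = LOGICAL(out);
  R_xlen_t v = 0;
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++, v++) {
        o[v] = FALSE;
        if (!m[v]) continue;
        bool surf = x == 0 || x == nx - 1 || y == 0 || y == ny - 1 || z == 0 || z == nz - 1;
        if (!surf) {
          surf = !m[v - 1] || !m[v + 1] || !m[v - nx] || !m[v + nx] ||
                 !m[v - (R_xlen_t)nx * ny] || !m[v + (R_xlen_t)nx * ny];
        }
        o[v] = surf;
      }
  return out;
}
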