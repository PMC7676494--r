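#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a 3D logical array stored with dim
// (ny, nx, nz). connectivity is 6 (faces) or 26 (faces+edges+corners).
// Labels are assigned in raster-scan order of first contact, from 1.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  int ny = dims[0], nx = dims[1], nz = dims[2];
  long n = (long)ny * nx * nz;
  IntegerVector labels(n, 0);

  // neighbor offsets in (dy, dx, dz)
  std::vector<int> offy, offx, offz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (dy == 0 && dx == 0 && dz == 0) continue;
        int manh = std::abs(dy) + std::abs(dx) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offy.push_back(dy); offx.push_back(dx); offz.push_back(dz);
      }
  int noff = (int)offy.size();

  std::vector<long> stack;
  int next_label = 0;
  for (long i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next_label;
    labels[i] = next_label;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      long cur = stack.back(); stack.pop_back();
      int z = (int)(cur / ((long)ny * nx));
      long rem = cur % ((long)ny * nx);
      int x = (int)(rem / ny);
      int y = (int)(rem % ny);
      for (int k = 0; k < noff; ++k) {
        int yy = y + offy[k], xx = x + offx[k], zz = z + offz[k];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        long j = (long)zz * ny * nx + (long)xx * ny + yy;
        if (mask[j] && labels[j] == 0) {
          labels[j] = next_label;
          stack.push_back(j);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

static inline double trilinear(const double* v, int ny, int nx, int nz,
                               double y, double x, double z, double fill,
                               bool* inside) {
  if (y < 0 || x < 0 || z < 0 || y > ny - 1 || x > nx - 1 || z > nz - 1) {
    *inside = false;
    return fill;
  }
  *inside = true;
  int y0 = (int)std::floor(y), x0 = (int)std::floor(x), z0 = (int)std::floor(z);
  int y1 = std::min(y0 + 1, ny - 1), x1 = std::min(x0 + 1, nx - 1),
      z1 = std::min(z0 + 1, nz - 1);
  double fy = y - y0, fx = x - x0, fz = z - z0;
  long pyx = (long)ny * nx;
#define V(yy, xx, zz) v[(long)(zz) * pyx + (long)(xx) * ny + (yy)]
  double c00 = (1 - fy) * V(y0, x0, z0) + fy * V(y1, x0, z0);
  double c01 = (1 - fy) * V(y0, x0, z1) + fy * V(y1, x0, z1);
  double c10 = (1 - fy) * V(y0, x1, z0) + fy * V(y1, x1, z0);
  double c11 = (1 - fy) * V(y0, x1, z1) + fy * V(y1, x1, z1);
#undef V
  double c0 = (1 - fx) * c00 + fx * c10;
  double c1 = (1 - fx) * c01 + fx * c11;
  return (1 - fz) * c0 + fz * c1;
}

// Resample a source volume onto an output grid under an affine map.
// A is 3x4 acting on 0-based output voxel coordinates (z, y, x, 1),
// yielding 0-based source voxel coordinates (z, y, x). Returns the
// resampled volume and a logical mask of voxels that fell inside the
// source grid.
// [[Rcpp::export]]
List cpp_affine_resample(NumericVector src, IntegerVector sdim,
                         IntegerVector odim, NumericMatrix A, double fill) {
  int sny = sdim[0], snx = sdim[1], snz = sdim[2];
  int ony = odim[0], onx = odim[1], onz = odim[2];
  long n = (long)ony * onx * onz;
  NumericVector out(n);
  LogicalVector inside(n);
  const double* v = REAL(src);
  long i = 0;
  for (int z = 0; z < onz; ++z)
    for (int x = 0; x < onx; ++x)
      for (int y = 0; y < ony; ++y, ++i) {
        double sz = A(0, 0) * z + A(0, 1) * y + A(0, 2) * x + A(0, 3);
        double sy = A(1, 0) * z + A(1, 1) * y + A(1, 2) * x + A(1, 3);
        double sx = A(2, 0) * z + A(2, 1) * y + A(2, 2) * x + A(2, 3);
        bool in;
        out[i] = trilinear(v, sny, snx, snz, sy, sx, sz, fill, &in);
        inside[i] = in;
      }
  out.attr("dim") = odim;
  inside.attr("dim") = odim;
  return List::create(_["values"] = out, _["inside"] = inside);
}
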