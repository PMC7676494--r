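#include <Rcpp.h>
using namespace Rcpp;

// Piecewise-linear transfer function: tf is a k x 2 matrix of
// (intensity, alpha) breakpoints sorted by intensity; values outside the
// range clamp to the end alphas.
static inline double tf_eval(const NumericMatrix& tf, double v) {
  int k = tf.nrow();
  if (v <= tf(0, 0)) return tf(0, 1);
  if (v >= tf(k - 1, 0)) return tf(k - 1, 1);
  for (int i = 1; i < k; ++i) {
    if (v <= tf(i, 0)) {
      double span = tf(i, 0) - tf(i - 1, 0);
      if (span <= 0) return tf(i, 1);
      double f = (v - tf(i - 1, 0)) / span;
      return (1 - f) * tf(i - 1, 1) + f * tf(i, 1);
    }
  }
  return tf(k - 1, 1);
}

static inline double trilin(const double* v, int ny, int nx, int nz,
                            double y, double x, double z) {
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

// Orthographic ray caster with front-to-back alpha compositing.
// channels: list of numeric 3D arrays with dim (ny, nx, nz), shared.
// spacing: (dz, dy, dx) in um; colors: nchan x 3 RGB in [0,1];
// tfs: list of k x 2 (intensity, alpha) matrices; dir/u/v: orthonormal
// camera basis in physical (x, y, z) coordinates; pixel_um: image pixel
// size; step_vox: sample step along the ray in voxel units; bg: RGB
// background; alpha_cutoff: early ray termination threshold.
// Samples are placed at midpoints of step intervals from the ray's entry
// into the voxel-extent bounding box, so an axis-aligned view with
// step_vox = 1 samples exactly at voxel centers.
// [[Rcpp::export]]
NumericVector cpp_render(List channels, IntegerVector vdim,
                         NumericVector spacing, NumericMatrix colors,
                         List tfs, NumericVector dir, NumericVector u,
                         NumericVector v, double pixel_um, int out_h,
                         int out_w, double step_vox, NumericVector bg,
                         double alpha_cutoff) {
  int ny = vdim[0], nx = vdim[1], nz = vdim[2];
  double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  int nchan = channels.size();
  std::vector<const double*> chan(nchan);
  std::vector<NumericMatrix> tfv;
  for (int c = 0; c < nchan; ++c) {
    chan[c] = REAL((SEXP)channels[c]);
    tfv.push_back(as<NumericMatrix>(tfs[c]));
  }

  // physical center and voxel-extent bounding box (x, y, z)
  double cx = (nx - 1) * 0.5 * dx, cy = (ny - 1) * 0.5 * dy,
         cz = (nz - 1) * 0.5 * dz;
  double lo[3] = {-0.5 * dx, -0.5 * dy, -0.5 * dz};
  double hi[3] = {(nx - 0.5) * dx, (ny - 0.5) * dy, (nz - 0.5) * dz};

  // step length in um: step_vox voxels along the ray in index space
  double didx[3] = {dir[0] / dx, dir[1] / dy, dir[2] / dz};
  double inorm = std::sqrt(didx[0] * didx[0] + didx[1] * didx[1] +
                           didx[2] * didx[2]);
  double step_um = step_vox / inorm;

  NumericVector img((long)out_h * out_w * 3);
  for (int col = 0; col < out_w; ++col) {
    for (int row = 0; row < out_h; ++row) {
      double ou = (col - (out_w - 1) * 0.5) * pixel_um;
      double ov = (row - (out_h - 1) * 0.5) * pixel_um;
      double org[3] = {cx + ou * u[0] + ov * v[0],
                       cy + ou * u[1] + ov * v[1],
                       cz + ou * u[2] + ov * v[2]};
      // slab intersection
      double t0 = -1e300, t1 = 1e300;
      bool miss = false;
      for (int a = 0; a < 3; ++a) {
        if (std::fabs(dir[a]) < 1e-12) {
          if (org[a] < lo[a] || org[a] > hi[a]) { miss = true; break; }
        } else {
          double ta = (lo[a] - org[a]) / dir[a];
          double tb = (hi[a] - org[a]) / dir[a];
          if (ta > tb) std::swap(ta, tb);
          t0 = std::max(t0, ta);
          t1 = std::min(t1, tb);
        }
      }
      double R = bg[0], G = bg[1], B = bg[2];
      if (!miss && t1 > t0) {
        double accR = 0, accG = 0, accB = 0, T = 1.0;
        int nsteps = (int)std::ceil((t1 - t0) / step_um - 1e-9);
        for (int k = 0; k < nsteps; ++k) {
          double t = t0 + (k + 0.5) * step_um;
          double px = org[0] + t * dir[0];
          double py = org[1] + t * dir[1];
          double pz = org[2] + t * dir[2];
          double iy = py / dy, ix = px / dx, iz = pz / dz;
          if (iy < 0 || ix < 0 || iz < 0 || iy > ny - 1 || ix > nx - 1 ||
              iz > nz - 1)
            continue;  // inside bounding box but outside voxel-center grid
          double asum = 0, pr = 0, pg = 0, pb = 0;
          for (int c = 0; c < nchan; ++c) {
            double val = trilin(chan[c], ny, nx, nz, iy, ix, iz);
            double a = tf_eval(tfv[c], val);
            if (a <= 0) continue;
            asum += a;
            pr += a * colors(c, 0);
            pg += a * colors(c, 1);
            pb += a * colors(c, 2);
          }
          if (asum <= 0) continue;
          double a_samp = std::min(asum, 1.0);
          double a_eff = 1.0 - std::pow(1.0 - a_samp, step_vox);
          double w = T * a_eff / asum;
          accR += w * pr; accG += w * pg; accB += w * pb;
          T *= (1.0 - a_eff);
          if (1.0 - T >= alpha_cutoff) break;
        }
        R = accR + T * bg[0];
        G = accG + T * bg[1];
        B = accB + T * bg[2];
      }
      long base = (long)row + (long)col * out_h;
      long pix = (long)out_h * out_w;
      img[base] = R; img[base + pix] = G; img[base + 2 * pix] = B;
    }
  }
  img.attr("dim") = IntegerVector::create(out_h, out_w, 3);
  return img;
}
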