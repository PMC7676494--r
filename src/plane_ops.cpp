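#include <Rcpp.h>
using namespace Rcpp;

// Symmetric reflection of an out-of-range 0-based index into [0, n).
// Pattern: c b a | a b c | c b a  (scipy-style "reflect").
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i = ((i % period) + period) % period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// Windowed sum of the squared response of a small high-pass kernel.
// Accumulation order (kernel rows outer, cols inner; window rows outer,
// cols inner) is fixed so that a naive per-pixel oracle written with the
// same loop nesting reproduces the result bit-exactly.
// [[Rcpp::export]]
NumericMatrix cpp_local_energy(NumericMatrix plane, int radius,
                               NumericMatrix kernel) {
  int ny = plane.nrow(), nx = plane.ncol();
  int kh = kernel.nrow(), kw = kernel.ncol();
  int cy = kh / 2, cx = kw / 2;

  NumericMatrix resp(ny, nx);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      double acc = 0.0;
      for (int ki = 0; ki < kh; ++ki) {
        int yy = reflect_idx(y + ki - cy, ny);
        for (int kj = 0; kj < kw; ++kj) {
          int xx = reflect_idx(x + kj - cx, nx);
          acc += kernel(ki, kj) * plane(yy, xx);
        }
      }
      resp(y, x) = acc;
    }
  }

  NumericMatrix energy(ny, nx);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      double acc = 0.0;
      for (int wy = -radius; wy <= radius; ++wy) {
        int yy = reflect_idx(y + wy, ny);
        for (int wx = -radius; wx <= radius; ++wx) {
          int xx = reflect_idx(x + wx, nx);
          double r = resp(yy, xx);
          acc += r * r;
        }
      }
      energy(y, x) = acc;
    }
  }
  return energy;
}

// Zero-normalized cross-correlation of mov against ref over all integer
// shifts in [-max_shift, max_shift]^2, each computed on the full overlap
// region with per-shift mean/variance normalization. Entry [dy + m + 1,
// dx + m + 1] (1-based) holds NCC at shift (dy, dx): correlation of
// ref(y, x) with mov(y + dy, x + dx). Undefined (zero-variance) shifts
// get -2 so they can never win the argmax.
// [[Rcpp::export]]
NumericMatrix cpp_zncc_grid(NumericMatrix ref, NumericMatrix mov,
                            int max_shift) {
  int ny = ref.nrow(), nx = ref.ncol();
  int m = max_shift, side = 2 * m + 1;
  NumericMatrix out(side, side);
  for (int dx = -m; dx <= m; ++dx) {
    int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
    for (int dy = -m; dy <= m; ++dy) {
      int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
      long n = (long)(y1 - y0) * (x1 - x0);
      if (n < 2) { out(dy + m, dx + m) = -2.0; continue; }
      double sa = 0, sb = 0;
      for (int x = x0; x < x1; ++x)
        for (int y = y0; y < y1; ++y) {
          sa += ref(y, x);
          sb += mov(y + dy, x + dx);
        }
      double ma = sa / n, mb = sb / n;
      double saa = 0, sbb = 0, sab = 0;
      for (int x = x0; x < x1; ++x)
        for (int y = y0; y < y1; ++y) {
          double a = ref(y, x) - ma;
          double b = mov(y + dy, x + dx) - mb;
          saa += a * a; sbb += b * b; sab += a * b;
        }
      double denom = std::sqrt(saa * sbb);
      out(dy + m, dx + m) = (denom > 0) ? sab / denom : -2.0;
    }
  }
  return out;
}

// Resample img at (y + dy, x + dx) by bilinear interpolation (0-based
// sample positions); out-of-field samples take `fill`. Integer shifts
// reduce to exact index shifts.
// [[Rcpp::export]]
NumericMatrix cpp_bilinear_shift(NumericMatrix img, double dy, double dx,
                                 double fill) {
  int ny = img.nrow(), nx = img.ncol();
  NumericMatrix out(ny, nx);
  for (int x = 0; x < nx; ++x) {
    double sx = x + dx;
    int x0 = (int)std::floor(sx);
    double fx = sx - x0;
    for (int y = 0; y < ny; ++y) {
      double sy = y + dy;
      int y0 = (int)std::floor(sy);
      double fy = sy - y0;
      if (sy < 0 || sx < 0 || sy > ny - 1 || sx > nx - 1) {
        out(y, x) = fill;
        continue;
      }
      int y1 = std::min(y0 + 1, ny - 1), x1 = std::min(x0 + 1, nx - 1);
      double v00 = img(y0, x0), v01 = img(y0, x1);
      double v10 = img(y1, x0), v11 = img(y1, x1);
      out(y, x) = (1 - fy) * ((1 - fx) * v00 + fx * v01) +
                  fy * ((1 - fx) * v10 + fx * v11);
    }
  }
  return out;
}
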