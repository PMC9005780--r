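#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sphere-capped cone tip profile z(d): vertical drop of the tip surface at
// lateral distance d from the apex. Apex at origin, z increasing away from
// the sample. alpha = cone half-angle (radians, from the vertical axis).
// Spherical cap for d <= R*cos(alpha), tangent-continuous cone beyond.
static inline double tip_z(double d, double R, double alpha) {
  double dt = R * std::cos(alpha);
  if (d <= dt) {
    double s = R * R - d * d;
    return R - std::sqrt(s > 0.0 ? s : 0.0);
  }
  double zt = R * (1.0 - std::sin(alpha));
  return zt + (d - dt) / std::tan(alpha);
}

// Lateral footprint radius at which the tip profile reaches height h.
static inline double tip_dmax(double h, double R, double alpha) {
  if (h <= 0.0) return 0.0;
  double zt = R * (1.0 - std::sin(alpha));
  if (h <= zt) return std::sqrt(h * (2.0 * R - h));
  return R * std::cos(alpha) + (h - zt) * std::tan(alpha);
}

// [[Rcpp::export]]
NumericVector cpp_tip_z(NumericVector d, double R, double alpha) {
  int n = d.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = tip_z(d[i], R, alpha);
  return out;
}

// Simulated topograph: grey-scale dilation of a surface point cloud by the
// reflected tip. Pixel (ix, iy) centre at (x0 + ix*px, y0 + iy*px); the
// image value is max over surface points p of p.z - tip_z(|p - pixel|_xy),
// clamped at the substrate (0). Matrix is (ny rows = y, nx cols = x).
// [[Rcpp::export]]
NumericMatrix cpp_simulate_topograph(NumericVector sx, NumericVector sy,
                                     NumericVector sz, double x0, double y0,
                                     int nx, int ny, double px,
                                     double R, double alpha) {
  NumericMatrix img(ny, nx);
  int np = sx.size();
  for (int p = 0; p < np; ++p) {
    double h = sz[p];
    if (h <= 0.0) continue;
    double dmax = tip_dmax(h, R, alpha);
    int ix0 = (int)std::ceil((sx[p] - dmax - x0) / px);
    int ix1 = (int)std::floor((sx[p] + dmax - x0) / px);
    int iy0 = (int)std::ceil((sy[p] - dmax - y0) / px);
    int iy1 = (int)std::floor((sy[p] + dmax - y0) / px);
    if (ix0 < 0) ix0 = 0;
    if (iy0 < 0) iy0 = 0;
    if (ix1 > nx - 1) ix1 = nx - 1;
    if (iy1 > ny - 1) iy1 = ny - 1;
    for (int ix = ix0; ix <= ix1; ++ix) {
      double dx = x0 + ix * px - sx[p];
      for (int iy = iy0; iy <= iy1; ++iy) {
        double dy = y0 + iy * px - sy[p];
        double d = std::sqrt(dx * dx + dy * dy);
        double v = h - tip_z(d, R, alpha);
        if (v > img(iy, ix)) img(iy, ix) = v;
      }
    }
  }
  return img;
}

// Tip deconvolution: grey-scale erosion of a height image by the reflected
// tip. E(x) = min over pixels q of I(q) + tip_z(|q - x|); recovers the
// deepest surface consistent with the observed image. Row (y) and column
// (x) sample spacings may differ (e.g. a laterally upsampled image).
// [[Rcpp::export]]
NumericMatrix cpp_erode_topograph(NumericMatrix img, double px_x, double px_y,
                                  double R, double alpha) {
  int ny = img.nrow(), nx = img.ncol();
  double hmax = 0.0;
  for (int i = 0; i < ny * nx; ++i)
    if (img[i] > hmax) hmax = img[i];
  double dmax = tip_dmax(hmax, R, alpha);
  int wx = (int)std::ceil(dmax / px_x) + 1;
  int wy = (int)std::ceil(dmax / px_y) + 1;
  NumericMatrix out(ny, nx);
  for (int ix = 0; ix < nx; ++ix) {
    for (int iy = 0; iy < ny; ++iy) {
      double best = img(iy, ix);
      int jx0 = ix - wx < 0 ? 0 : ix - wx;
      int jx1 = ix + wx > nx - 1 ? nx - 1 : ix + wx;
      int jy0 = iy - wy < 0 ? 0 : iy - wy;
      int jy1 = iy + wy > ny - 1 ? ny - 1 : iy + wy;
      for (int jx = jx0; jx <= jx1; ++jx) {
        double dx = (jx - ix) * px_x;
        for (int jy = jy0; jy <= jy1; ++jy) {
          double dy = (jy - iy) * px_y;
          double v = img(jy, jx) + tip_z(std::sqrt(dx * dx + dy * dy), R, alpha);
          if (v < best) best = v;
        }
      }
      out(iy, ix) = best;
    }
  }
  return out;
}

static inline double cubic_w(double t) {
  // Catmull-Rom kernel (a = -0.5)
  double at = std::fabs(t);
  if (at <= 1.0) return 1.5 * at * at * at - 2.5 * at * at + 1.0;
  if (at < 2.0) return -0.5 * at * at * at + 2.5 * at * at - 4.0 * at + 2.0;
  return 0.0;
}

// Bicubic (cubic-convolution) sampling of img at fractional 0-based
// (row, col) coordinates; edge pixels are clamped.
// [[Rcpp::export]]
NumericVector cpp_interp_bicubic(NumericMatrix img, NumericVector row,
                                 NumericVector col) {
  int ny = img.nrow(), nx = img.ncol(), n = row.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    double r = row[k], c = col[k];
    int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    double acc = 0.0, wsum = 0.0;
    for (int i = -1; i <= 2; ++i) {
      int ri = r0 + i;
      if (ri < 0) ri = 0;
      if (ri > ny - 1) ri = ny - 1;
      double wr = cubic_w(r - (r0 + i));
      for (int j = -1; j <= 2; ++j) {
        int cj = c0 + j;
        if (cj < 0) cj = 0;
        if (cj > nx - 1) cj = nx - 1;
        double w = wr * cubic_w(c - (c0 + j));
        acc += w * img(ri, cj);
        wsum += w;
      }
    }
    out[k] = wsum != 0.0 ? acc / wsum : 0.0;
  }
  return out;
}
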