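#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear sample of img at fractional (row, col), 0-based; outside -> 0.
// Weights of exactly 0 are skipped so on-grid samples are exact.
static inline double sample_bilinear(const double *img, int H, int W,
                                     double r, double c) {
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  double fr = r - r0, fc = c - c0;
  double v = 0.0;
  for (int dr = 0; dr <= 1; ++dr) {
    double wr = dr ? fr : 1.0 - fr;
    if (wr <= 0.0) continue;
    int rr = r0 + dr;
    if (rr < 0 || rr >= H) continue;
    for (int dc = 0; dc <= 1; ++dc) {
      double w = wr * (dc ? fc : 1.0 - fc);
      if (w <= 0.0) continue;
      int cc = c0 + dc;
      if (cc < 0 || cc >= W) continue;
      v += w * img[(size_t)cc * H + rr];
    }
  }
  return v;
}

// Keys cubic kernel, a = -0.5 (Catmull-Rom).
static inline double cubic_w(double t) {
  t = std::fabs(t);
  if (t < 1.0) return 1.0 + t * t * (1.5 * t - 2.5);
  if (t < 2.0) return 2.0 - t * (4.0 - t * (2.5 - 0.5 * t));
  return 0.0;
}

static inline double sample_bicubic(const double *img, int H, int W,
                                    double r, double c) {
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  double v = 0.0, wsum = 0.0;
  for (int dr = -1; dr <= 2; ++dr) {
    int rr = r0 + dr;
    double wr = cubic_w(r - (r0 + dr));
    if (wr == 0.0) continue;
    for (int dc = -1; dc <= 2; ++dc) {
      int cc = c0 + dc;
      double w = wr * cubic_w(c - (c0 + dc));
      if (w == 0.0) continue;
      wsum += w;
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;  // zero fill
      v += w * img[(size_t)cc * H + rr];
    }
  }
  return (wsum != 0.0) ? v / wsum : 0.0;
}

// Resample img through the inverse map: out(x, y) = img(a11 x + a12 y + a13,
// a21 x + a22 y + a23) in centred coordinates (x along columns, y along rows,
// origin at the image centre). ainv is the 3x3 inverse-map matrix.
// [[Rcpp::export]]
NumericMatrix warp_affine_cpp(NumericMatrix img, NumericMatrix ainv,
                              int interp) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  double cr = (H - 1) / 2.0, cc = (W - 1) / 2.0;
  double a11 = ainv(0, 0), a12 = ainv(0, 1), a13 = ainv(0, 2);
  double a21 = ainv(1, 0), a22 = ainv(1, 1), a23 = ainv(1, 2);
  const double *src = REAL(img);
  for (int c = 0; c < W; ++c) {
    double x = c - cc;
    for (int r = 0; r < H; ++r) {
      double y = r - cr;
      double xi = a11 * x + a12 * y + a13;
      double yi = a21 * x + a22 * y + a23;
      out(r, c) = (interp == 1)
                      ? sample_bicubic(src, H, W, yi + cr, xi + cc)
                      : sample_bilinear(src, H, W, yi + cr, xi + cc);
    }
  }
  return out;
}

// Parallel-beam projection of a volume vol[a, i, j] (axial slice index a,
// in-plane x index i, in-plane y index j; dims all refer to voxels).
// Projection at tilt angle alpha for detector column position s (centred
// pixel units): integral over t of vol at in-plane point
//   (x, y) = (s cos a - t sin a, s sin a + t cos a),
// one unit step per sample, bilinear in-plane interpolation, zero outside.
// Returns array (n_axial x width x n_angles): detector row = axial index.
// [[Rcpp::export]]
NumericVector project_volume_cpp(NumericVector vol, NumericVector angles_rad,
                                 int width) {
  IntegerVector dims = vol.attr("dim");
  int na = dims[0], nx = dims[1], ny = dims[2];
  int nA = angles_rad.size();
  NumericVector out(Dimension(na, width, nA));
  const double *V = REAL(vol);
  double *O = REAL(out);
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cd = (width - 1) / 2.0;
  int nt = std::max(nx, ny);
  double ct = (nt - 1) / 2.0;
  for (int ia = 0; ia < nA; ++ia) {
    double ca = std::cos(angles_rad[ia]), sa = std::sin(angles_rad[ia]);
    for (int d = 0; d < width; ++d) {
      double s = d - cd;
      double *ocol = O + ((size_t)ia * width + d) * na;
      for (int k = 0; k < nt; ++k) {
        double t = k - ct;
        double px = s * ca - t * sa + cx;
        double py = s * sa + t * ca + cy;
        int ix = (int)std::floor(px), iy = (int)std::floor(py);
        double fx = px - ix, fy = py - iy;
        for (int dy = 0; dy <= 1; ++dy) {
          double wy = dy ? fy : 1.0 - fy;
          if (wy <= 0.0) continue;
          int jy = iy + dy;
          if (jy < 0 || jy >= ny) continue;
          for (int dx = 0; dx <= 1; ++dx) {
            double w = wy * (dx ? fx : 1.0 - fx);
            if (w <= 0.0) continue;
            int jx = ix + dx;
            if (jx < 0 || jx >= nx) continue;
            const double *vcol = V + ((size_t)jy * nx + jx) * na;
            for (int a = 0; a < na; ++a) ocol[a] += w * vcol[a];
          }
        }
      }
    }
  }
  return out;
}

// Back-projection of a filtered sinogram (n_angles x width) onto an
// nout x nout grid; out[i, j] accumulates the filtered projections at
// detector position s = x cos a + y sin a with x = i, y = j centred.
// Linear interpolation along the detector; caller applies pi/(2 nA) scaling.
// [[Rcpp::export]]
NumericMatrix backproject_cpp(NumericMatrix fsino, NumericVector angles_rad,
                              int nout) {
  int nA = fsino.nrow(), W = fsino.ncol();
  NumericMatrix out(nout, nout);
  double c0 = (nout - 1) / 2.0, cd = (W - 1) / 2.0;
  for (int ia = 0; ia < nA; ++ia) {
    double ca = std::cos(angles_rad[ia]), sa = std::sin(angles_rad[ia]);
    for (int j = 0; j < nout; ++j) {
      double y = j - c0;
      double base = y * sa + cd;
      for (int i = 0; i < nout; ++i) {
        double s = (i - c0) * ca + base;
        int s0 = (int)std::floor(s);
        double fs = s - s0;
        double v = 0.0;
        if (s0 >= 0 && s0 < W) v += (1.0 - fs) * fsino(ia, s0);
        if (s0 + 1 >= 0 && s0 + 1 < W && fs > 0.0) v += fs * fsino(ia, s0 + 1);
        out(i, j) += v;
      }
    }
  }
  return out;
}
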