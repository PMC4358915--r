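#ifndef CORRALSIM_GRID_INTERP_H
#define CORRALSIM_GRID_INTERP_H

#include <Rcpp.h>
#include <cmath>

// Regular 3D scalar grid with quadratic (3rd-order) B-spline interpolation.
// Column-major storage, x fastest: index = ix + nx*(iy + ny*iz).
struct Grid3 {
  double ox, oy, oz;     // origin (node 0 coordinates), Angstrom
  double hx, hy, hz;     // spacing per axis
  int nx, ny, nz;
  const double *v;
  // world-coordinate bounding box outside of which the field is exactly
  // zero (with interpolation margin already included); skips far particles
  bool has_bbox;
  double bxlo, bxhi, bylo, byhi, bzlo, bzhi;
  bool clamp;            // true: clamp to interior (U^CORE policy)
                         // false: outside interior is an error (phi policy)
};

inline Grid3 grid_from_list(const Rcpp::List &g) {
  Grid3 gr;
  Rcpp::NumericVector o = g["origin"], h = g["spacing"];
  Rcpp::IntegerVector n = g["counts"];
  gr.ox = o[0]; gr.oy = o[1]; gr.oz = o[2];
  gr.hx = h[0]; gr.hy = h[1]; gr.hz = h[2];
  gr.nx = n[0]; gr.ny = n[1]; gr.nz = n[2];
  Rcpp::NumericVector vv = g["values"];
  gr.v = REAL(vv);
  gr.clamp = Rcpp::as<bool>(g["clamp"]);
  gr.has_bbox = false;
  if (g.containsElementNamed("bbox") && !Rf_isNull(g["bbox"])) {
    Rcpp::NumericVector b = g["bbox"];
    gr.has_bbox = true;
    gr.bxlo = b[0]; gr.bxhi = b[1];
    gr.bylo = b[2]; gr.byhi = b[3];
    gr.bzlo = b[4]; gr.bzhi = b[5];
  }
  return gr;
}

// quadratic B-spline weights and derivatives on the 3-node stencil
// centred at the nearest node; t in [-0.5, 0.5]
inline void qspline(double t, double *w, double *dw) {
  w[0] = 0.5 * (0.5 - t) * (0.5 - t);
  w[1] = 0.75 - t * t;
  w[2] = 0.5 * (0.5 + t) * (0.5 + t);
  dw[0] = t - 0.5;
  dw[1] = -2.0 * t;
  dw[2] = t + 0.5;
}

// Evaluate value and gradient at point p. Returns 0 on success, 1 if the
// point lies outside the interpolable interior and clamping is disabled.
// Clamped axes get zero gradient.
inline int grid_eval(const Grid3 &g, double x, double y, double z,
                     double *val, double *grad) {
  val[0] = 0.0; grad[0] = grad[1] = grad[2] = 0.0;
  if (g.has_bbox &&
      (x < g.bxlo || x > g.bxhi || y < g.bylo || y > g.byhi ||
       z < g.bzlo || z > g.bzhi))
    return 0;
  double u[3] = { (x - g.ox) / g.hx, (y - g.oy) / g.hy, (z - g.oz) / g.hz };
  int nn[3] = { g.nx, g.ny, g.nz };
  double hh[3] = { g.hx, g.hy, g.hz };
  int i0[3];
  bool clamped[3] = { false, false, false };
  for (int a = 0; a < 3; ++a) {
    double lo = 0.5, hi = nn[a] - 1.5;
    if (u[a] < lo || u[a] > hi) {
      if (!g.clamp) return 1;
      u[a] = (u[a] < lo) ? lo : hi;
      clamped[a] = true;
    }
    i0[a] = (int) std::floor(u[a] + 0.5);
    if (i0[a] < 1) i0[a] = 1;
    if (i0[a] > nn[a] - 2) i0[a] = nn[a] - 2;
  }
  double wx[3], dwx[3], wy[3], dwy[3], wz[3], dwz[3];
  qspline(u[0] - i0[0], wx, dwx);
  qspline(u[1] - i0[1], wy, dwy);
  qspline(u[2] - i0[2], wz, dwz);
  double s = 0.0, gx = 0.0, gy = 0.0, gz = 0.0;
  for (int kz = -1; kz <= 1; ++kz) {
    int iz = i0[2] + kz;
    for (int ky = -1; ky <= 1; ++ky) {
      int iy = i0[1] + ky;
      const double *col = g.v + (size_t) g.nx * (iy + (size_t) g.ny * iz);
      for (int kx = -1; kx <= 1; ++kx) {
        double vv = col[i0[0] + kx];
        s  += wx[kx+1] * wy[ky+1] * wz[kz+1] * vv;
        gx += dwx[kx+1] * wy[ky+1] * wz[kz+1] * vv;
        gy += wx[kx+1] * dwy[ky+1] * wz[kz+1] * vv;
        gz += wx[kx+1] * wy[ky+1] * dwz[kz+1] * vv;
      }
    }
  }
  val[0] = s;
  grad[0] = clamped[0] ? 0.0 : gx / hh[0];
  grad[1] = clamped[1] ? 0.0 : gy / hh[1];
  grad[2] = clamped[2] ? 0.0 : gz / hh[2];
  return 0;
}

#endif
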