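#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Finite-difference linearized Poisson-Boltzmann solver on a uniform grid,
// Gaussian-style units: div(eps grad phi) - kap2bar(r) phi = -4 pi ke rho,
// phi in kcal/(mol e), lengths in Angstrom, ke = 332.0636 kcal A/(mol e^2).
//
// Regions (per-node test): inside any atom sphere -> solute dielectric, no
// salt; else inside the membrane slab (zmem_lo < z < zmem_hi) -> membrane
// dielectric, no salt; else solvent dielectric with kap2bar = eps_s * kappa^2.
// Face dielectrics are the arithmetic mean of the two adjacent node values.
//
// Dirichlet boundaries: either the Debye-Hueckel sum over bc_atoms
// (spherical-ion form, q e^{-kappa (d - r)} / (eps_s d (1 + kappa r)),
// Coulombic when kappa = 0) or caller-supplied values in `init` when
// bc_mode = 1 (focusing: boundary layer of `init` is held fixed).

static inline size_t idx3(int i, int j, int k, int nx, int ny) {
  return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
}

// [[Rcpp::export]]
List pb_solve_cpp(NumericVector origin, double h, IntegerVector counts,
                  NumericMatrix atoms,   // columns x, y, z, radius, charge
                  double eps_solute, double eps_mem, double eps_solv,
                  double zmem_lo, double zmem_hi, double kap2bar,
                  double ke, int bc_mode, NumericMatrix bc_atoms,
                  Nullable<NumericVector> init,
                  double omega, double tol, int maxit, double stern) {
  const int nx = counts[0], ny = counts[1], nz = counts[2];
  const size_t n = (size_t)nx * ny * nz;
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const int na = atoms.nrow();

  // region codes: 0 solvent, 1 membrane, 2 solute
  std::vector<unsigned char> reg(n, 0);
  for (int k = 0; k < nz; ++k) {
    double z = oz + k * h;
    if (z > zmem_lo && z < zmem_hi)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) reg[idx3(i,j,k,nx,ny)] = 1;
  }
  for (int a = 0; a < na; ++a) {
    double ax = atoms(a,0), ay = atoms(a,1), az = atoms(a,2), ar = atoms(a,3);
    if (ar <= 0) continue;
    int ilo = std::max(0, (int)std::ceil((ax - ar - ox)/h));
    int ihi = std::min(nx-1, (int)std::floor((ax + ar - ox)/h));
    int jlo = std::max(0, (int)std::ceil((ay - ar - oy)/h));
    int jhi = std::min(ny-1, (int)std::floor((ay + ar - oy)/h));
    int klo = std::max(0, (int)std::ceil((az - ar - oz)/h));
    int khi = std::min(nz-1, (int)std::floor((az + ar - oz)/h));
    double r2 = ar * ar;
    for (int k = klo; k <= khi; ++k) {
      double dz = oz + k*h - az;
      for (int j = jlo; j <= jhi; ++j) {
        double dy = oy + j*h - ay;
        double dyz = dy*dy + dz*dz;
        if (dyz > r2) continue;
        for (int i = ilo; i <= ihi; ++i) {
          double dx = ox + i*h - ax;
          if (dx*dx + dyz <= r2) reg[idx3(i,j,k,nx,ny)] = 2;
        }
      }
    }
  }
  std::vector<double> epsn(n), kap(n);
  for (size_t m = 0; m < n; ++m) {
    epsn[m] = reg[m] == 2 ? eps_solute : (reg[m] == 1 ? eps_mem : eps_solv);
    kap[m] = reg[m] == 0 ? kap2bar : 0.0;
  }
  // Stern layer: mobile ions additionally excluded within `stern` of the
  // membrane surface and of every atom surface
  if (stern > 0.0 && kap2bar > 0.0) {
    for (int k = 0; k < nz; ++k) {
      double z = oz + k * h;
      if (z > zmem_lo - stern && z < zmem_hi + stern)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) kap[idx3(i,j,k,nx,ny)] = 0.0;
    }
    for (int a = 0; a < na; ++a) {
      double ar = atoms(a,3) + stern;
      if (atoms(a,3) <= 0) continue;
      double ax = atoms(a,0), ay = atoms(a,1), az = atoms(a,2);
      int ilo = std::max(0, (int)std::ceil((ax - ar - ox)/h));
      int ihi = std::min(nx-1, (int)std::floor((ax + ar - ox)/h));
      int jlo = std::max(0, (int)std::ceil((ay - ar - oy)/h));
      int jhi = std::min(ny-1, (int)std::floor((ay + ar - oy)/h));
      int klo = std::max(0, (int)std::ceil((az - ar - oz)/h));
      int khi = std::min(nz-1, (int)std::floor((az + ar - oz)/h));
      double r2 = ar * ar;
      for (int k = klo; k <= khi; ++k) {
        double dz = oz + k*h - az;
        for (int j = jlo; j <= jhi; ++j) {
          double dy = oy + j*h - ay;
          double dyz = dy*dy + dz*dz;
          if (dyz > r2) continue;
          for (int i = ilo; i <= ihi; ++i) {
            double dx = ox + i*h - ax;
            if (dx*dx + dyz <= r2) kap[idx3(i,j,k,nx,ny)] = 0.0;
          }
        }
      }
    }
  }

  // charge spreading: trilinear onto the 8 surrounding nodes
  std::vector<double> src(n, 0.0);           // 4 pi ke q_node / h
  const double cq = 4.0 * M_PI * ke / h;
  for (int a = 0; a < na; ++a) {
    double qa = atoms(a,4);
    if (qa == 0.0) continue;
    double u = (atoms(a,0) - ox)/h, v = (atoms(a,1) - oy)/h,
           w = (atoms(a,2) - oz)/h;
    int i0 = (int)std::floor(u), j0 = (int)std::floor(v),
        k0 = (int)std::floor(w);
    if (i0 < 0 || i0 >= nx-1 || j0 < 0 || j0 >= ny-1 || k0 < 0 || k0 >= nz-1)
      stop("charge %d lies outside the PB grid", a + 1);
    double fu = u - i0, fv = v - j0, fw = w - k0;
    for (int dk = 0; dk <= 1; ++dk)
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          double wt = (di ? fu : 1-fu) * (dj ? fv : 1-fv) * (dk ? fw : 1-fw);
          src[idx3(i0+di, j0+dj, k0+dk, nx, ny)] += cq * qa * wt;
        }
  }

  std::vector<double> phi(n, 0.0);
  if (init.isNotNull()) {
    NumericVector ini(init.get());
    if ((size_t)ini.size() != n) stop("init has wrong length");
    std::copy(ini.begin(), ini.end(), phi.begin());
  }
  // Debye-Hueckel boundary values from bc_atoms
  double kappa = std::sqrt(std::max(kap2bar, 0.0) / eps_solv);
  if (bc_mode == 0) {
    int nb = bc_atoms.nrow();
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          if (i > 0 && i < nx-1 && j > 0 && j < ny-1 && k > 0 && k < nz-1)
            continue;
          double x = ox + i*h, y = oy + j*h, z = oz + k*h, s = 0.0;
          for (int a = 0; a < nb; ++a) {
            double qa = bc_atoms(a,4);
            if (qa == 0.0) continue;
            double dx = x - bc_atoms(a,0), dy = y - bc_atoms(a,1),
                   dz = z - bc_atoms(a,2);
            double d = std::sqrt(dx*dx + dy*dy + dz*dz);
            if (d < 1e-6) d = 1e-6;
            double ra = bc_atoms(a,3);
            s += ke * qa * std::exp(-kappa * std::max(d - ra, 0.0)) /
                 (eps_solv * d * (1.0 + kappa * ra));
          }
          phi[idx3(i,j,k,nx,ny)] = s;
        }
  }

  // red-black SOR on the 7-point variable-coefficient stencil
  double maxphi = 1.0, resid = R_PosInf;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    double du_max = 0.0;
    maxphi = 1e-30;
    for (int colour = 0; colour < 2; ++colour) {
      for (int k = 1; k < nz-1; ++k)
        for (int j = 1; j < ny-1; ++j) {
          int i0 = 1 + ((j + k + colour) & 1);
          for (int i = i0; i < nx-1; i += 2) {
            size_t m = idx3(i,j,k,nx,ny);
            double e0 = epsn[m];
            double exm = 0.5*(e0 + epsn[m-1]);
            double exp_ = 0.5*(e0 + epsn[m+1]);
            double eym = 0.5*(e0 + epsn[m-(size_t)nx]);
            double eyp = 0.5*(e0 + epsn[m+(size_t)nx]);
            double ezm = 0.5*(e0 + epsn[m-(size_t)nx*ny]);
            double ezp = 0.5*(e0 + epsn[m+(size_t)nx*ny]);
            double num = exm*phi[m-1] + exp_*phi[m+1]
                       + eym*phi[m-(size_t)nx] + eyp*phi[m+(size_t)nx]
                       + ezm*phi[m-(size_t)nx*ny] + ezp*phi[m+(size_t)nx*ny]
                       + src[m];
            double den = exm + exp_ + eym + eyp + ezm + ezp + h*h*kap[m];
            double pnew = (1.0 - omega)*phi[m] + omega*num/den;
            double du = std::fabs(pnew - phi[m]);
            if (du > du_max) du_max = du;
            double ap = std::fabs(pnew);
            if (ap > maxphi) maxphi = ap;
            phi[m] = pnew;
          }
        }
    }
    resid = du_max / maxphi;
    if (resid < tol) break;
    if (it % 50 == 0) checkUserInterrupt();
  }
  if (resid >= tol)
    stop("PB solver did not converge in %d iterations (relative update %g)",
         maxit, resid);
  return List::create(_["phi"] = NumericVector(phi.begin(), phi.end()),
                      _["iterations"] = it, _["residual"] = resid);
}

// Trilinear interpolation used to transfer a coarse solution onto a focused
// fine grid (boundary values + initial guess).
// [[Rcpp::export]]
NumericVector trilinear_cpp(NumericVector origin, NumericVector spacing,
                            IntegerVector counts, NumericVector values,
                            NumericMatrix points) {
  int nx = counts[0], ny = counts[1], nz = counts[2];
  int np = points.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double u = (points(p,0) - origin[0]) / spacing[0];
    double v = (points(p,1) - origin[1]) / spacing[1];
    double w = (points(p,2) - origin[2]) / spacing[2];
    int i0 = (int)std::floor(u), j0 = (int)std::floor(v),
        k0 = (int)std::floor(w);
    if (i0 < 0) { i0 = 0; u = 0; } if (i0 > nx-2) { i0 = nx-2; u = nx-1; }
    if (j0 < 0) { j0 = 0; v = 0; } if (j0 > ny-2) { j0 = ny-2; v = ny-1; }
    if (k0 < 0) { k0 = 0; w = 0; } if (k0 > nz-2) { k0 = nz-2; w = nz-1; }
    double fu = u - i0, fv = v - j0, fw = w - k0;
    double s = 0.0;
    for (int dk = 0; dk <= 1; ++dk)
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          double wt = (di ? fu : 1-fu) * (dj ? fv : 1-fv) * (dk ? fw : 1-fw);
          s += wt * values[idx3(i0+di, j0+dj, k0+dk, nx, ny)];
        }
    out[p] = s;
  }
  return out;
}
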