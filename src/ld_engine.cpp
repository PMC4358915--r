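#include <Rcpp.h>
#include "grid_interp.h"
using namespace Rcpp;

// AKMA-style unit system: Angstrom, kcal/mol, amu, elementary charge, ps.
static const double KCAL_TO_AKMA = 418.4;     // kcal/mol -> amu A^2/ps^2
static const double KB = 0.0019872041;        // kcal/mol/K

// [[Rcpp::export]]
List grid_eval_cpp(List grid, NumericMatrix points) {
  Grid3 g = grid_from_list(grid);
  int np = points.nrow();
  NumericVector val(np);
  NumericMatrix grad(np, 3);
  for (int i = 0; i < np; ++i) {
    double v, gr[3];
    int bad = grid_eval(g, points(i,0), points(i,1), points(i,2), &v, gr);
    if (bad)
      stop("point %d is outside the spline-interpolable region of the grid",
           i + 1);
    val[i] = v;
    grad(i,0) = gr[0]; grad(i,1) = gr[1]; grad(i,2) = gr[2];
  }
  return List::create(_["value"] = val, _["gradient"] = grad);
}

struct SysParams {
  double xlo, xhi, ylo, yhi;     // hard-wall box
  double kwall, kplane, zplane;
  double corral_x;               // equilibration-only one-sided wall
  bool corral_on;
  bool pairs_on;
  double cutoff;                 // 0 = none; else shifted truncation
  double ke_over_eps;            // 332.0636 / 80
};

// Accumulate forces and an energy breakdown for the current positions.
// f must be zeroed by the caller. Returns energies via breakdown[6]:
// 0 pair_lj, 1 pair_coulomb, 2 core, 3 phix, 4 planar, 5 wall.
static void forces(const double *x, const double *y, const double *z, int n,
                   const double *q, const double *eps, const double *rmh,
                   const SysParams &sp,
                   const Grid3 *core, const Grid3 *phix,
                   double *fx, double *fy, double *fz, double *brk) {
  for (int k = 0; k < 6; ++k) brk[k] = 0.0;
  // pairwise LJ + Coulomb/eps_w over all unordered pairs
  if (sp.pairs_on) {
    double rc2 = sp.cutoff > 0 ? sp.cutoff * sp.cutoff : R_PosInf;
    bool uniform = true;
    for (int i = 1; i < n && uniform; ++i)
      uniform = (eps[i] == eps[0]) && (rmh[i] == rmh[0]);
    double e0 = eps[0], rm20 = 4.0 * rmh[0] * rmh[0];
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = x[i]-x[j], dy = y[i]-y[j], dz = z[i]-z[j];
        double r2 = dx*dx + dy*dy + dz*dz;
        if (r2 <= 0.0)
          stop("overlapping particles (%d, %d) at zero separation", i+1, j+1);
        if (r2 > rc2) continue;
        double e, rm2;
        if (uniform) { e = e0; rm2 = rm20; }
        else {
          double rmin = rmh[i] + rmh[j];
          e = std::sqrt(eps[i] * eps[j]);
          rm2 = rmin * rmin;
        }
        double inv_r2 = 1.0 / r2;
        double s2 = rm2 * inv_r2;
        double s6 = s2 * s2 * s2;
        double s12 = s6 * s6;
        double ulj = e * (s12 - 2.0 * s6);
        double uc  = sp.ke_over_eps * q[i] * q[j] * std::sqrt(inv_r2);
        // radial force / r: F_r/r = (12 e (s12 - s6) + U_coul) / r^2
        double fr = (12.0 * e * (s12 - s6) + uc) * inv_r2;
        if (sp.cutoff > 0) {  // energy-shifted truncation
          double sc2 = rm2 / rc2;
          double sc6 = sc2 * sc2 * sc2;
          ulj -= e * (sc6 * sc6 - 2.0 * sc6);
          uc  -= sp.ke_over_eps * q[i] * q[j] / sp.cutoff;
        }
        brk[0] += ulj; brk[1] += uc;
        fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
        fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    // planar restraint U = k (z - zp)^2
    double dzp = z[i] - sp.zplane;
    brk[4] += sp.kplane * dzp * dzp;
    fz[i] += -2.0 * sp.kplane * dzp;
    // hard walls U = k * overshoot^2
    if (x[i] < sp.xlo) { double d = sp.xlo - x[i]; brk[5] += sp.kwall*d*d; fx[i] += 2.0*sp.kwall*d; }
    if (x[i] > sp.xhi) { double d = x[i] - sp.xhi; brk[5] += sp.kwall*d*d; fx[i] -= 2.0*sp.kwall*d; }
    if (y[i] < sp.ylo) { double d = sp.ylo - y[i]; brk[5] += sp.kwall*d*d; fy[i] += 2.0*sp.kwall*d; }
    if (y[i] > sp.yhi) { double d = y[i] - sp.yhi; brk[5] += sp.kwall*d*d; fy[i] -= 2.0*sp.kwall*d; }
    if (sp.corral_on && x[i] > sp.corral_x) {
      double d = x[i] - sp.corral_x;
      brk[5] += sp.kwall * d * d;
      fx[i] -= 2.0 * sp.kwall * d;
    }
    if (core) {
      double v, g[3];
      grid_eval(*core, x[i], y[i], z[i], &v, g);  // clamped by policy
      brk[2] += v;
      fx[i] -= g[0]; fy[i] -= g[1]; fz[i] -= g[2];
    }
    if (phix) {
      double v, g[3];
      int bad = grid_eval(*phix, x[i], y[i], z[i], &v, g);
      if (bad)
        stop("particle %d left the electrostatic map region", i + 1);
      brk[3] += q[i] * v;
      fx[i] -= q[i] * g[0]; fy[i] -= q[i] * g[1]; fz[i] -= q[i] * g[2];
    }
  }
}

static SysParams sys_from_list(const List &sys) {
  SysParams sp;
  sp.xlo = as<double>(sys["box_x_lo"]); sp.xhi = as<double>(sys["box_x_hi"]);
  sp.ylo = as<double>(sys["box_y_lo"]); sp.yhi = as<double>(sys["box_y_hi"]);
  sp.kwall = as<double>(sys["wall_force_constant"]);
  sp.kplane = as<double>(sys["planar_force_constant"]);
  sp.zplane = as<double>(sys["diffusion_plane_z"]);
  sp.corral_x = as<double>(sys["corral_boundary_x"]);
  sp.corral_on = as<bool>(sys["corral_constraint"]);
  sp.pairs_on = as<bool>(sys["include_pairs"]);
  sp.cutoff = as<double>(sys["cutoff"]);
  sp.ke_over_eps = as<double>(sys["coulomb_constant"]) /
                   as<double>(sys["pair_dielectric"]);
  return sp;
}

// [[Rcpp::export]]
List energy_forces_cpp(NumericMatrix pos, NumericVector q, NumericVector eps,
                       NumericVector rmh, List sys,
                       Nullable<List> core_grid, Nullable<List> phix_grid) {
  int n = pos.nrow();
  SysParams sp = sys_from_list(sys);
  Grid3 coreg, phixg;
  Grid3 *corep = NULL, *phixp = NULL;
  List keep_core, keep_phix;
  if (core_grid.isNotNull()) { keep_core = core_grid.get(); coreg = grid_from_list(keep_core); corep = &coreg; }
  if (phix_grid.isNotNull()) { keep_phix = phix_grid.get(); phixg = grid_from_list(keep_phix); phixp = &phixg; }
  std::vector<double> x(n), y(n), z(n), fx(n,0.0), fy(n,0.0), fz(n,0.0);
  for (int i = 0; i < n; ++i) { x[i]=pos(i,0); y[i]=pos(i,1); z[i]=pos(i,2); }
  double brk[6];
  forces(x.data(), y.data(), z.data(), n, REAL(q), REAL(eps), REAL(rmh),
         sp, corep, phixp, fx.data(), fy.data(), fz.data(), brk);
  NumericMatrix f(n, 3);
  for (int i = 0; i < n; ++i) { f(i,0)=fx[i]; f(i,1)=fy[i]; f(i,2)=fz[i]; }
  NumericVector b = NumericVector::create(
    _["pair_lj"] = brk[0], _["pair_coulomb"] = brk[1], _["core_grid"] = brk[2],
    _["phix_grid"] = brk[3], _["planar_restraint"] = brk[4],
    _["wall_restraint"] = brk[5]);
  return List::create(_["breakdown"] = b, _["forces"] = f);
}

// BAOAB Langevin propagation. Positions/velocities updated in place copies;
// snapshots recorded every snap_every steps (frame 0 = initial state).
// [[Rcpp::export]]
List ld_run_cpp(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
                NumericVector q, NumericVector eps, NumericVector rmh,
                List sys, Nullable<List> core_grid, Nullable<List> phix_grid,
                double dt, double gamma, double temperature,
                int n_steps, int snap_every, bool record_velocities) {
  int n = pos.nrow();
  SysParams sp = sys_from_list(sys);
  Grid3 coreg, phixg;
  Grid3 *corep = NULL, *phixp = NULL;
  List keep_core, keep_phix;
  if (core_grid.isNotNull()) { keep_core = core_grid.get(); coreg = grid_from_list(keep_core); corep = &coreg; }
  if (phix_grid.isNotNull()) { keep_phix = phix_grid.get(); phixg = grid_from_list(keep_phix); phixp = &phixg; }

  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n);
  std::vector<double> fx(n,0.0), fy(n,0.0), fz(n,0.0);
  for (int i = 0; i < n; ++i) {
    x[i]=pos(i,0); y[i]=pos(i,1); z[i]=pos(i,2);
    vx[i]=vel(i,0); vy[i]=vel(i,1); vz[i]=vel(i,2);
  }
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);
  std::vector<double> im(n), sig(n);   // 1/m (AKMA), OU noise amplitude
  for (int i = 0; i < n; ++i) {
    im[i] = KCAL_TO_AKMA / mass[i];
    sig[i] = std::sqrt(KB * temperature * KCAL_TO_AKMA / mass[i]);
  }
  int nsnap = n_steps / snap_every + 1;
  NumericMatrix sx(nsnap, n), sy(nsnap, n), sz(nsnap, n);
  NumericMatrix svx, svy, svz;
  if (record_velocities) {
    svx = NumericMatrix(nsnap, n); svy = NumericMatrix(nsnap, n);
    svz = NumericMatrix(nsnap, n);
  }
  NumericVector times(nsnap);
  double brk[6];
  forces(x.data(), y.data(), z.data(), n, REAL(q), REAL(eps), REAL(rmh),
         sp, corep, phixp, fx.data(), fy.data(), fz.data(), brk);
  int isnap = 0;
  for (int i = 0; i < n; ++i) { sx(0,i)=x[i]; sy(0,i)=y[i]; sz(0,i)=z[i]; }
  if (record_velocities)
    for (int i = 0; i < n; ++i) { svx(0,i)=vx[i]; svy(0,i)=vy[i]; svz(0,i)=vz[i]; }
  times[0] = 0.0;
  isnap = 1;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {      // B: half kick
      vx[i] += 0.5 * dt * fx[i] * im[i];
      vy[i] += 0.5 * dt * fy[i] * im[i];
      vz[i] += 0.5 * dt * fz[i] * im[i];
      // A: half drift
      x[i] += 0.5 * dt * vx[i];
      y[i] += 0.5 * dt * vy[i];
      z[i] += 0.5 * dt * vz[i];
    }
    if (gamma > 0.0) {                 // O: Ornstein-Uhlenbeck
      for (int i = 0; i < n; ++i) {
        vx[i] = c1 * vx[i] + c2 * sig[i] * norm_rand();
        vy[i] = c1 * vy[i] + c2 * sig[i] * norm_rand();
        vz[i] = c1 * vz[i] + c2 * sig[i] * norm_rand();
      }
    }
    for (int i = 0; i < n; ++i) {      // A: half drift
      x[i] += 0.5 * dt * vx[i];
      y[i] += 0.5 * dt * vy[i];
      z[i] += 0.5 * dt * vz[i];
    }
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    forces(x.data(), y.data(), z.data(), n, REAL(q), REAL(eps), REAL(rmh),
           sp, corep, phixp, fx.data(), fy.data(), fz.data(), brk);
    for (int i = 0; i < n; ++i) {      // B: half kick
      vx[i] += 0.5 * dt * fx[i] * im[i];
      vy[i] += 0.5 * dt * fy[i] * im[i];
      vz[i] += 0.5 * dt * fz[i] * im[i];
    }
    if (step % snap_every == 0) {
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(x[i]) || !std::isfinite(vx[i]))
          stop("integration instability: particle %d non-finite at step %d",
               i + 1, step);
        sx(isnap,i)=x[i]; sy(isnap,i)=y[i]; sz(isnap,i)=z[i];
      }
      if (record_velocities)
        for (int i = 0; i < n; ++i) { svx(isnap,i)=vx[i]; svy(isnap,i)=vy[i]; svz(isnap,i)=vz[i]; }
      times[isnap] = step * dt;
      ++isnap;
    }
    if (step % 20000 == 0) checkUserInterrupt();
  }
  NumericMatrix fpos(n, 3), fvel(n, 3);
  for (int i = 0; i < n; ++i) {
    fpos(i,0)=x[i]; fpos(i,1)=y[i]; fpos(i,2)=z[i];
    fvel(i,0)=vx[i]; fvel(i,1)=vy[i]; fvel(i,2)=vz[i];
  }
  List out = List::create(_["times"] = times, _["x"] = sx, _["y"] = sy,
                          _["z"] = sz, _["final_pos"] = fpos,
                          _["final_vel"] = fvel);
  if (record_velocities) {
    out["vx"] = svx; out["vy"] = svy; out["vz"] = svz;
  }
  return out;
}
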