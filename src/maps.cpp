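#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Core-repulsion map: 100 kcal/mol at nodes inside any augmented-radius
// sphere, 0 elsewhere (indicator of the lipid-excluded region).
// [[Rcpp::export]]
NumericVector core_map_cpp(NumericVector origin, NumericVector spacing,
                           IntegerVector counts, NumericMatrix atoms,
                           double augment, double height) {
  int nx = counts[0], ny = counts[1], nz = counts[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);  // zero-initialized
  double ox = origin[0], oy = origin[1], oz = origin[2];
  double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  for (int a = 0; a < atoms.nrow(); ++a) {
    double ar = atoms(a,3) + augment;
    if (ar <= 0) continue;
    double ax = atoms(a,0), ay = atoms(a,1), az = atoms(a,2);
    int ilo = std::max(0, (int)std::ceil((ax - ar - ox)/hx));
    int ihi = std::min(nx-1, (int)std::floor((ax + ar - ox)/hx));
    int jlo = std::max(0, (int)std::ceil((ay - ar - oy)/hy));
    int jhi = std::min(ny-1, (int)std::floor((ay + ar - oy)/hy));
    int klo = std::max(0, (int)std::ceil((az - ar - oz)/hz));
    int khi = std::min(nz-1, (int)std::floor((az + ar - oz)/hz));
    double r2 = ar * ar;
    for (int k = klo; k <= khi; ++k) {
      double dz = oz + k*hz - az;
      for (int j = jlo; j <= jhi; ++j) {
        double dy = oy + j*hy - ay;
        double dyz = dy*dy + dz*dz;
        if (dyz > r2) continue;
        for (int i = ilo; i <= ihi; ++i) {
          double dx = ox + i*hx - ax;
          if (dx*dx + dyz <= r2)
            out[(size_t)i + (size_t)nx*((size_t)j + (size_t)ny*k)] = height;
        }
      }
    }
  }
  return out;
}

// Does an open (below-threshold) 4-connected path cross the map from the
// first x-column to the last? BFS on the open-cell indicator, column-major
// with x fastest.
// [[Rcpp::export]]
bool crossing_channel_cpp(LogicalVector open, int nx, int ny) {
  std::vector<unsigned char> seen((size_t)nx * ny, 0);
  std::vector<int> stack;
  stack.reserve(nx * ny / 4);
  for (int j = 0; j < ny; ++j) {
    size_t m = (size_t)nx * j;
    if (open[m]) { seen[m] = 1; stack.push_back((int)m); }
  }
  while (!stack.empty()) {
    int m = stack.back(); stack.pop_back();
    int i = m % nx, j = m / nx;
    if (i == nx - 1) return true;
    const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
    for (int d = 0; d < 4; ++d) {
      int ii = i + di[d], jj = j + dj[d];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
      size_t mm = (size_t)ii + (size_t)nx * jj;
      if (!seen[mm] && open[mm]) { seen[mm] = 1; stack.push_back((int)mm); }
    }
  }
  return false;
}
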