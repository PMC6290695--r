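#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// D2Q9 BGK channel solver, lattice units. Geometry comes in as a solid
// mask (nx x ny). Walls: half-way bounce-back. Inlet (first column):
// Zou-He velocity boundary at the prescribed profile. Outlet (last
// column): Zou-He pressure boundary at unit density, with plain
// neighbour copies at the wall-adjacent corner nodes. Returns the
// steady velocity and density fields in lattice units.

static const int EX[9] = {0, 1, 0, -1, 0, 1, -1, -1, 1};
static const int EY[9] = {0, 0, 1, 0, -1, 1, 1, -1, -1};
static const int OPP[9] = {0, 3, 4, 1, 2, 7, 8, 5, 6};
static const double W[9] = {4.0 / 9.0, 1.0 / 9.0, 1.0 / 9.0, 1.0 / 9.0,
                            1.0 / 9.0, 1.0 / 36.0, 1.0 / 36.0, 1.0 / 36.0,
                            1.0 / 36.0};

static inline double feq(int k, double rho, double ux, double uy) {
  double eu = EX[k] * ux + EY[k] * uy;
  double u2 = ux * ux + uy * uy;
  return W[k] * rho * (1.0 + 3.0 * eu + 4.5 * eu * eu - 1.5 * u2);
}

// [[Rcpp::export]]
List lbm_solve_cpp(LogicalMatrix solid, NumericVector u_inlet, double tau,
                   double tol, int max_iter, int check_every) {
  int nx = solid.nrow(), ny = solid.ncol();
  int nn = nx * ny;
  std::vector<double> f(9 * nn), ftmp(9 * nn);
  std::vector<char> sol(nn);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) sol[j * nx + i] = solid(i, j) ? 1 : 0;

  // init at rest except inlet profile
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int id = j * nx + i;
      double ux = (i == 0 && !sol[id]) ? u_inlet[j] : 0.0;
      for (int k = 0; k < 9; ++k) f[k * nn + id] = feq(k, 1.0, ux, 0.0);
    }

  double omega = 1.0 / tau;
  std::vector<double> ux_old(nn, 0.0), uy_old(nn, 0.0);
  bool converged = false;
  int it = 0;
  NumericMatrix UX(nx, ny), UY(nx, ny), RHO(nx, ny);
  for (it = 1; it <= max_iter; ++it) {
    // collide
    for (int id = 0; id < nn; ++id) {
      if (sol[id]) continue;
      double rho = 0.0, mx = 0.0, my = 0.0;
      double fk[9];
      for (int k = 0; k < 9; ++k) {
        fk[k] = f[k * nn + id];
        rho += fk[k];
        mx += EX[k] * fk[k];
        my += EY[k] * fk[k];
      }
      double ux = mx / rho, uy = my / rho;
      for (int k = 0; k < 9; ++k)
        ftmp[k * nn + id] = fk[k] + omega * (feq(k, rho, ux, uy) - fk[k]);
    }
    // stream with half-way bounce-back off solids and domain walls
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int id = j * nx + i;
        if (sol[id]) continue;
        for (int k = 0; k < 9; ++k) {
          int si = i - EX[k], sj = j - EY[k];
          if (si < 0 || si >= nx) { // handled by inlet/outlet BC below
            f[k * nn + id] = ftmp[OPP[k] * nn + id];
            continue;
          }
          if (sj < 0 || sj >= ny || sol[sj * nx + si])
            f[k * nn + id] = ftmp[OPP[k] * nn + id];
          else
            f[k * nn + id] = ftmp[k * nn + sj * nx + si];
        }
      }
    // inlet: Zou-He velocity boundary (prescribed ux profile, free
    // density, so a pressure gradient can develop to drive the flow)
    for (int j = 0; j < ny; ++j) {
      int id = j * nx + 0;
      if (sol[id]) continue;
      double ux = u_inlet[j];
      double f0 = f[0 * nn + id], f2 = f[2 * nn + id], f4 = f[4 * nn + id];
      double f3 = f[3 * nn + id], f6 = f[6 * nn + id], f7 = f[7 * nn + id];
      double rho = (f0 + f2 + f4 + 2.0 * (f3 + f6 + f7)) / (1.0 - ux);
      f[1 * nn + id] = f3 + (2.0 / 3.0) * rho * ux;
      f[5 * nn + id] = f7 - 0.5 * (f2 - f4) + (1.0 / 6.0) * rho * ux;
      f[8 * nn + id] = f6 + 0.5 * (f2 - f4) + (1.0 / 6.0) * rho * ux;
    }
    // outlet: Zou-He pressure boundary (rho = 1) at interior nodes,
    // which anchors the pressure level; wall-adjacent corner nodes are
    // ill-posed for Zou-He and take a plain copy of the neighbour column
    for (int j = 0; j < ny; ++j) {
      int id = j * nx + (nx - 1);
      if (sol[id]) continue;
      int src = j * nx + (nx - 2);
      bool corner = (j == 0 || sol[(j - 1) * nx + (nx - 1)]) ||
                    (j == ny - 1 || sol[(j + 1) * nx + (nx - 1)]);
      if (corner) {
        if (!sol[src])
          for (int k = 0; k < 9; ++k) f[k * nn + id] = f[k * nn + src];
        continue;
      }
      double f0 = f[0 * nn + id], f2 = f[2 * nn + id], f4 = f[4 * nn + id];
      double f1 = f[1 * nn + id], f5 = f[5 * nn + id], f8 = f[8 * nn + id];
      double ux = -1.0 + (f0 + f2 + f4 + 2.0 * (f1 + f5 + f8));
      f[3 * nn + id] = f1 - (2.0 / 3.0) * ux;
      f[7 * nn + id] = f5 + 0.5 * (f2 - f4) - (1.0 / 6.0) * ux;
      f[6 * nn + id] = f8 - 0.5 * (f2 - f4) - (1.0 / 6.0) * ux;
    }
    if (it % check_every == 0) {
      double dmax = 0.0, umax = 0.0;
      for (int id = 0; id < nn; ++id) {
        if (sol[id]) continue;
        double rho = 0.0, mx = 0.0, my = 0.0;
        for (int k = 0; k < 9; ++k) {
          double fk = f[k * nn + id];
          rho += fk; mx += EX[k] * fk; my += EY[k] * fk;
        }
        double ux = mx / rho, uy = my / rho;
        double du = std::fabs(ux - ux_old[id]) + std::fabs(uy - uy_old[id]);
        if (du > dmax) dmax = du;
        double um = std::fabs(ux) + std::fabs(uy);
        if (um > umax) umax = um;
        ux_old[id] = ux; uy_old[id] = uy;
      }
      if (umax > 0 && dmax / umax < tol) { converged = true; break; }
    }
  }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int id = j * nx + i;
      if (sol[id]) { UX(i, j) = 0.0; UY(i, j) = 0.0; RHO(i, j) = 1.0; continue; }
      double rho = 0.0, mx = 0.0, my = 0.0;
      for (int k = 0; k < 9; ++k) {
        double fk = f[k * nn + id];
        rho += fk; mx += EX[k] * fk; my += EY[k] * fk;
      }
      UX(i, j) = mx / rho;
      UY(i, j) = my / rho;
      RHO(i, j) = rho;
    }
  return List::create(_["ux"] = UX, _["uy"] = UY, _["rho"] = RHO,
                      _["iters"] = it, _["converged"] = converged);
}
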