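#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Signed scalar pair force (positive = repulsive) as a function of the
// center distance d for radii sum R:
//   overlap  del = R - d > 0 : kh*del^{3/2} - adh*kh*del   (Hertz + adhesion)
//   gap 0 <= s < t           : Hookean tether, linearly tapered over the
//                              outer half of the range so the force is
//                              continuous at the cutoff
//   s >= t                   : 0
static inline double scalar_force(double d, double R, double kh, double adh,
                                  double kt, double trange) {
  double del = R - d;
  if (del > 0.0) return kh * std::pow(del, 1.5) - adh * kh * del;
  double s = -del;
  if (trange <= 0.0 || s >= trange) return 0.0;
  double half = 0.5 * trange;
  if (s <= half) return -kt * s;
  return -kt * (trange - s);
}

// Stent strut agents are bare metal: pure Hertzian repulsion, no
// adhesion and no extracellular-matrix tether.
static inline double scalar_force_strut(double d, double R, double kh) {
  double del = R - d;
  return (del > 0.0) ? kh * std::pow(del, 1.5) : 0.0;
}

// [[Rcpp::export]]
NumericVector pair_force_cpp(double ax, double ay, double bx, double by,
                             double ra, double rb, double kh, double adh,
                             double kt, double trange) {
  double dx = ax - bx, dy = ay - by;
  double d = std::sqrt(dx * dx + dy * dy);
  if (d < 1e-12) stop("degenerate geometry: coincident agent centers");
  double f = scalar_force(d, ra + rb, kh, adh, kt, trange);
  return NumericVector::create(f * dx / d, f * dy / d);
}

// Uniform spatial binning over the point bounding box.
struct Bins {
  double x0, y0, cell;
  int nbx, nby;
  std::vector<int> head, nxt;
  Bins(const NumericVector &x, const NumericVector &y, double cell_size)
      : cell(cell_size) {
    int n = x.size();
    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      if (x[i] < xmin) xmin = x[i];
      if (x[i] > xmax) xmax = x[i];
      if (y[i] < ymin) ymin = y[i];
      if (y[i] > ymax) ymax = y[i];
    }
    x0 = xmin; y0 = ymin;
    nbx = std::max(1, (int)std::floor((xmax - xmin) / cell) + 1);
    nby = std::max(1, (int)std::floor((ymax - ymin) / cell) + 1);
    head.assign((size_t)nbx * nby, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int bx = std::min(nbx - 1, (int)((x[i] - x0) / cell));
      int by = std::min(nby - 1, (int)((y[i] - y0) / cell));
      int b = by * nbx + bx;
      nxt[i] = head[b];
      head[b] = i;
    }
  }
};

// Forces and contact stress (sum of contact-force magnitudes) per agent.
static void forces_stress(const NumericVector &x, const NumericVector &y,
                          const NumericVector &r, const LogicalVector &strut,
                          const IntegerVector &li1, const IntegerVector &li2,
                          const NumericVector &lrest, double klink, double kh,
                          double adh, double kt, double trange,
                          std::vector<double> &fx, std::vector<double> &fy,
                          std::vector<double> &st) {
  int n = x.size();
  fx.assign(n, 0.0); fy.assign(n, 0.0); st.assign(n, 0.0);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) if (r[i] > rmax) rmax = r[i];
  double cut = 2.0 * rmax + trange;
  Bins bins(x, y, cut);
  for (int i = 0; i < n; ++i) {
    int bx = std::min(bins.nbx - 1, (int)((x[i] - bins.x0) / bins.cell));
    int by = std::min(bins.nby - 1, (int)((y[i] - bins.y0) / bins.cell));
    for (int dby = -1; dby <= 1; ++dby) {
      int cy = by + dby;
      if (cy < 0 || cy >= bins.nby) continue;
      for (int dbx = -1; dbx <= 1; ++dbx) {
        int cx = bx + dbx;
        if (cx < 0 || cx >= bins.nbx) continue;
        for (int j = bins.head[cy * bins.nbx + cx]; j >= 0; j = bins.nxt[j]) {
          if (j >= i) continue; // each pair once
          double dx = x[i] - x[j], dy = y[i] - y[j];
          double R = r[i] + r[j];
          if (std::fabs(dx) > R + trange || std::fabs(dy) > R + trange)
            continue;
          double d2 = dx * dx + dy * dy;
          double reach = R + trange;
          if (d2 >= reach * reach) continue;
          double d = std::sqrt(d2);
          if (d < 1e-12)
            stop("degenerate geometry: coincident agent centers");
          double f = (strut[i] || strut[j])
                         ? scalar_force_strut(d, R, kh)
                         : scalar_force(d, R, kh, adh, kt, trange);
          double ux = dx / d, uy = dy / d;
          fx[i] += f * ux; fy[i] += f * uy;
          fx[j] -= f * ux; fy[j] -= f * uy;
          if (d < R) { // contact stress
            double m = std::fabs(f);
            st[i] += m; st[j] += m;
          }
        }
      }
    }
  }
  // IEL chain springs (Hookean, both tension and compression)
  for (int k = 0; k < li1.size(); ++k) {
    int i = li1[k], j = li2[k];
    double dx = x[i] - x[j], dy = y[i] - y[j];
    double d = std::sqrt(dx * dx + dy * dy);
    if (d < 1e-12) stop("degenerate geometry: coincident chain agents");
    double f = -klink * (d - lrest[k]); // negative = attraction when taut
    fx[i] += f * dx / d; fy[i] += f * dy / d;
    fx[j] -= f * dx / d; fy[j] -= f * dy / d;
  }
}

// [[Rcpp::export]]
List forces_cpp(NumericVector x, NumericVector y, NumericVector r,
                LogicalVector strut, IntegerVector li1, IntegerVector li2,
                NumericVector lrest, double klink, double kh, double adh,
                double kt, double trange) {
  std::vector<double> fx, fy, st;
  forces_stress(x, y, r, strut, li1, li2, lrest, klink, kh, adh, kt, trange,
                fx, fy, st);
  return List::create(_["fx"] = wrap(fx), _["fy"] = wrap(fy),
                      _["stress"] = wrap(st));
}

// Overdamped relaxation: positions move along the net force with an
// adaptive pseudo-timestep (halved on overshoot of the force norm,
// gently re-grown otherwise); per-iteration displacement is capped.
// fixed agents do not move; conx agents move only vertically.
// [[Rcpp::export]]
List equilibrate_cpp(NumericVector x, NumericVector y, NumericVector r,
                     LogicalVector fixed, LogicalVector conx,
                     LogicalVector strut, IntegerVector li1, IntegerVector li2,
                     NumericVector lrest, double klink, double kh,
                     double adh, double kt, double trange, double tol,
                     int max_iter) {
  int n = x.size();
  NumericVector px = clone(x), py = clone(y);
  std::vector<double> fx, fy, st;
  double rmin = R_PosInf;
  for (int i = 0; i < n; ++i) if (r[i] < rmin) rmin = r[i];
  double step_cap = 0.2 * rmin;
  // FIRE relaxation: inertial descent with velocity mixing, timestep
  // grown while moving downhill and cut (with a velocity reset) on
  // uphill power; robust on stiff Hertzian contacts and force-law kinks
  double kscale = 1.5 * kh * std::sqrt(rmin) + kt + adh * kh;
  double dt_max = 1.0 / std::sqrt(std::max(kscale / rmin, 1e-12)) * 0.5;
  // time unit from stiffness/mobility: dt stable ~ sqrt(m/k), m = 1
  dt_max = 0.5 / std::sqrt(std::max(kscale, 1e-12));
  double dt = 0.1 * dt_max;
  const double alpha0 = 0.1;
  double alpha = alpha0;
  int n_pos = 0;
  std::vector<double> vx(n, 0.0), vy(n, 0.0);
  double max_resid = R_PosInf;
  int iter = 0;
  bool converged = false;
  for (iter = 0; iter < max_iter; ++iter) {
    forces_stress(px, py, r, strut, li1, li2, lrest, klink, kh, adh, kt,
                  trange, fx, fy, st);
    double maxF = 0.0, P = 0.0, vnorm2 = 0.0, fnorm2 = 0.0;
    for (int i = 0; i < n; ++i) {
      if (fixed[i]) { fx[i] = 0.0; fy[i] = 0.0; continue; }
      if (conx[i]) fx[i] = 0.0;
      double m = std::sqrt(fx[i] * fx[i] + fy[i] * fy[i]);
      if (m > maxF) maxF = m;
      P += fx[i] * vx[i] + fy[i] * vy[i];
      vnorm2 += vx[i] * vx[i] + vy[i] * vy[i];
      fnorm2 += fx[i] * fx[i] + fy[i] * fy[i];
    }
    max_resid = maxF;
    if (maxF < tol) { converged = true; break; }
    if (P > 0.0) {
      if (++n_pos > 5) {
        dt = std::min(dt * 1.1, dt_max);
        alpha *= 0.99;
      }
    } else {
      n_pos = 0;
      dt *= 0.5;
      alpha = alpha0;
      std::fill(vx.begin(), vx.end(), 0.0);
      std::fill(vy.begin(), vy.end(), 0.0);
      vnorm2 = 0.0;
    }
    double vn = std::sqrt(vnorm2), fn = std::sqrt(fnorm2);
    double mix = (fn > 0.0) ? alpha * vn / fn : 0.0;
    // per-agent velocity clamp: no agent moves more than step_cap per
    // iteration, and the excess momentum is discarded — deep overlaps
    // (fresh daughter cells) separate without launching their cluster
    double vcap = step_cap / dt;
    for (int i = 0; i < n; ++i) {
      if (fixed[i]) continue;
      vx[i] = (1.0 - alpha) * vx[i] + mix * fx[i] + dt * fx[i];
      vy[i] = (1.0 - alpha) * vy[i] + mix * fy[i] + dt * fy[i];
      if (conx[i]) vx[i] = 0.0;
      double v = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i]);
      if (v > vcap) { vx[i] *= vcap / v; vy[i] *= vcap / v; }
      px[i] += dt * vx[i];
      py[i] += dt * vy[i];
    }
  }
  return List::create(_["x"] = px, _["y"] = py, _["converged"] = converged,
                      _["iters"] = iter, _["max_resid"] = max_resid);
}

// Count, for each agent, neighbors with center distance < factor*(ri+rj).
// [[Rcpp::export]]
IntegerVector neighbor_counts_cpp(NumericVector x, NumericVector y,
                                  NumericVector r, double factor) {
  int n = x.size();
  IntegerVector cnt(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) if (r[i] > rmax) rmax = r[i];
  double cut = 2.0 * rmax * factor;
  Bins bins(x, y, std::max(cut, 1e-9));
  for (int i = 0; i < n; ++i) {
    int bx = std::min(bins.nbx - 1, (int)((x[i] - bins.x0) / bins.cell));
    int by = std::min(bins.nby - 1, (int)((y[i] - bins.y0) / bins.cell));
    for (int dby = -1; dby <= 1; ++dby) {
      int cy = by + dby;
      if (cy < 0 || cy >= bins.nby) continue;
      for (int dbx = -1; dbx <= 1; ++dbx) {
        int cx = bx + dbx;
        if (cx < 0 || cx >= bins.nbx) continue;
        for (int j = bins.head[cy * bins.nbx + cx]; j >= 0; j = bins.nxt[j]) {
          if (j >= i) continue;
          double dx = x[i] - x[j], dy = y[i] - y[j];
          double lim = factor * (r[i] + r[j]);
          if (dx * dx + dy * dy < lim * lim) { ++cnt[i]; ++cnt[j]; }
        }
      }
    }
  }
  return cnt;
}
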