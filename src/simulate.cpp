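// Coupled LBM-DEM time loop: D2Q9 BGK fluid with body + platelet reaction
// forcing, unresolved (drag-law) platelet transport, soft-sphere contacts,
// shear/contact activation, spring adhesion bonds and Poisson platelet
// injection.  Mirrors the reference R formulas in R/dem.R and R/coupling.R.
//
// Fluid state is in lattice units; platelet state in physical units (m, s).
// Per step: collide+stream (using last step's spread reaction forces) ->
// sample fields at platelets -> DEM forces -> activation -> bond update ->
// integrate motion -> spread new reaction forces -> inject/remove.
//
// RNG: R's generator (set.seed on the R side gives bit-reproducible runs).

#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <cmath>

using namespace Rcpp;

static const int CX[9] = {0, 1, 1, 0, -1, -1, -1, 0, 1};
static const int CY[9] = {0, 0, 1, 1, 1, 0, -1, -1, -1};
static const double W[9] = {4.0 / 9.0,
                            1.0 / 9.0, 1.0 / 36.0, 1.0 / 9.0, 1.0 / 36.0,
                            1.0 / 9.0, 1.0 / 36.0, 1.0 / 9.0, 1.0 / 36.0};
static const int OPP[9] = {0, 5, 6, 7, 8, 1, 2, 3, 4};

struct Bond {
  int id_i, id_j;        // id_j = -1 for a wall anchor
  double ax, ay;         // wall anchor point (m); unused for pair bonds
  double rest;           // rest separation (m)
  double t0;             // formation time (s)
};

struct Grid {
  int nx, ny, margin;
  double dx;
  const int* mask;
  // continuous 0-based node coordinates of physical position (x, y)
  inline void coords(double x, double y, double& gx, double& gy) const {
    gx = x / dx - 0.5;
    gy = y / dx - 0.5 + margin;
  }
  inline int wrapx(int i) const {
    i %= nx; if (i < 0) i += nx; return i;
  }
  inline int clampy(int j) const {
    if (j < 0) return 0;
    if (j > ny - 2) return ny - 2;
    return j;
  }
};

// bilinear stencil; returns 4 linear indices + raw weights
static inline void stencil(const Grid& g, double x, double y,
                           int idx[4], double w[4]) {
  double gx, gy;
  g.coords(x, y, gx, gy);
  int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy);
  double fx = gx - i0, fy = gy - j0;
  j0 = g.clampy(j0);
  int i0w = g.wrapx(i0), i1w = g.wrapx(i0 + 1);
  idx[0] = i0w + g.nx * j0;       w[0] = (1 - fx) * (1 - fy);
  idx[1] = i1w + g.nx * j0;       w[1] = fx * (1 - fy);
  idx[2] = i0w + g.nx * (j0 + 1); w[2] = (1 - fx) * fy;
  idx[3] = i1w + g.nx * (j0 + 1); w[3] = fx * fy;
}

// masked bilinear interpolation (solid weights redistributed to fluid)
static inline double interp_masked(const Grid& g, const double* field,
                                   double x, double y, bool& ok) {
  int idx[4]; double w[4];
  stencil(g, x, y, idx, w);
  double tot = 0, val = 0;
  for (int q = 0; q < 4; ++q) {
    if (g.mask[idx[q]]) { tot += w[q]; val += w[q] * field[idx[q]]; }
  }
  ok = tot > 0;
  return ok ? val / tot : 0.0;
}

// plain bilinear interpolation (fields defined on all nodes, e.g. phi)
static inline double interp_plain(const Grid& g, const double* field,
                                  double x, double y) {
  int idx[4]; double w[4];
  stencil(g, x, y, idx, w);
  double val = 0;
  for (int q = 0; q < 4; ++q) val += w[q] * field[idx[q]];
  return val;
}

// Disc (quartic) kernel over the platelet footprint, used for BOTH fluid
// velocity interpolation and reaction-force spreading so the two are
// adjoint (momentum-exchange identity).  Weights w = (1 - (r/rk)^2)^2 on
// fluid nodes within rk of the centre, normalised to sum 1.  A particle
// of diameter ~2.5 dx overlaps several cells; point-wise (bilinear)
// exchange at that size ratio makes the explicit two-way coupling
// unstable, footprint spreading keeps the per-step feedback gain < 1.
#define KMAX 64
struct DiscKernel {
  int n;
  int idx[KMAX];
  double w[KMAX];
};
static inline bool disc_kernel(const Grid& g, double x, double y, double rk,
                               DiscKernel& K) {
  double gx, gy;
  g.coords(x, y, gx, gy);
  int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy);
  int span = (int)std::ceil(rk / g.dx) + 1;
  K.n = 0;
  double tot = 0;
  for (int dj = -span; dj <= span; ++dj) {
    int j = j0 + dj;
    if (j < 0 || j >= g.ny) continue;
    for (int di = -span; di <= span; ++di) {
      int i = g.wrapx(i0 + di);
      int idx = i + g.nx * j;
      if (!g.mask[idx]) continue;
      // physical distance from node centre to (x, y), x periodic
      double ddx = (i0 + di - gx) * g.dx;   // unwrapped offset
      double ddy = (j - gy) * g.dx;
      double r2 = ddx * ddx + ddy * ddy;
      if (r2 >= rk * rk) continue;
      double q = 1.0 - r2 / (rk * rk);
      double wq = q * q;
      if (K.n < KMAX) { K.idx[K.n] = idx; K.w[K.n] = wq; K.n++; tot += wq; }
    }
  }
  if (K.n == 0 || tot <= 0) return false;
  for (int k = 0; k < K.n; ++k) K.w[k] /= tot;
  return true;
}

// union-find for thrombus census
struct UF {
  std::vector<int> p;
  UF(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int i) { while (p[i] != i) { p[i] = p[p[i]]; i = p[i]; } return i; }
  void join(int a, int b) { p[find(a)] = find(b); }
};

// [[Rcpp::export]]
List cpp_simulate(NumericVector f0, IntegerVector mask_, int nx, int ny,
                  int margin, NumericVector phi_, double half_width,
                  double dx, double dt, double tau, double rho, double mu,
                  double gx_lat,
                  NumericMatrix platelets0, List par,
                  double conc2d, bool inject,
                  double inlet_y_lo, double inlet_y_hi,
                  double domain_length,
                  double kernel_radius, double force_relax,
                  int n_steps, int n_sub, int diag_every, int snapshot_every,
                  double q0, double occl_frac, int occl_sustain,
                  int max_platelets) {
  const size_t n = (size_t)nx * ny;
  if ((size_t)f0.size() != n * 9) stop("f0 must have length nx*ny*9");

  // parameters
  const double a = as<double>(par["a"]);
  const double m_p = as<double>(par["m"]);
  const double I_p = as<double>(par["I"]);
  const double k_coll = as<double>(par["k_coll"]);
  const double eta_coll = as<double>(par["eta_coll"]);
  const double k_adh = as<double>(par["k_adh"]);
  const double delta_break = as<double>(par["delta_break"]);
  const double tau_crit = as<double>(par["tau_crit"]);
  const double vort_factor = as<double>(par["vort_factor"]);
  const double b_depth = as<double>(par["b_depth"]);

  // unit conversions
  const double c_vel = dx / dt;                   // lattice u -> m/s
  const double c_stress = rho * dx * dx / (dt * dt);
  const double c_force = dt * dt / (rho * b_depth * dx * dx * dx); // N -> lat
  const double c_q = dx * dx / dt;                // lattice colsum -> m^2/s
  const double gamma_t = 6.0 * M_PI * a * mu;     // translational drag
  const double gamma_r = 8.0 * M_PI * mu * a * a * a;
  const double dts = dt / n_sub;
  const double decay_t = std::exp(-dts * gamma_t / m_p);
  const double decay_r = std::exp(-dts * gamma_r / I_p);
  // damping clamped at critical damping (reduced mass m/2 for a pair,
  // m against the static wall)
  const double eta_pair = std::min(eta_coll,
                                   2.0 * std::sqrt(k_coll * m_p / 2.0));
  const double eta_wall = std::min(eta_coll,
                                   2.0 * std::sqrt(k_coll * m_p));
  (void)force_relax;   // superseded by the implicit exchange; kept in API
  const double omega_bgk = 1.0 / tau;
  const double sfac = 1.0 - 1.0 / (2.0 * tau);

  // grids
  std::vector<int> msk(mask_.begin(), mask_.end());
  std::vector<double> phi(phi_.begin(), phi_.end());
  Grid G{nx, ny, margin, dx, msk.data()};
  std::vector<int> nb(n * 9);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int idx = i + nx * j;
      for (int k = 0; k < 9; ++k) {
        int ii = i + CX[k]; if (ii < 0) ii += nx; else if (ii >= nx) ii -= nx;
        int jj = j + CY[k]; if (jj < 0) jj += ny; else if (jj >= ny) jj -= ny;
        nb[idx + n * k] = ii + nx * jj;
      }
    }
  // gradient of phi (per metre), central differences on the full grid
  std::vector<double> gpx(n), gpy(n);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int idx = i + nx * j;
      int ip = G.wrapx(i + 1) + nx * j, im = G.wrapx(i - 1) + nx * j;
      gpx[idx] = (phi[ip] - phi[im]) / (2 * dx);
      int jp = (j < ny - 1) ? j + 1 : j, jm = (j > 0) ? j - 1 : j;
      gpy[idx] = (phi[i + nx * jp] - phi[i + nx * jm]) /
        ((jp - jm) * dx);
    }
  // wall-adjacent fluid nodes (for the wall shear diagnostic)
  std::vector<int> wall_nodes;
  for (size_t idx = 0; idx < n; ++idx) {
    if (!msk[idx]) continue;
    for (int k = 1; k < 9; ++k)
      if (!msk[nb[idx + n * k]]) { wall_nodes.push_back((int)idx); break; }
  }

  // fluid buffers
  std::vector<double> fa(f0.begin(), f0.end()), fb(fa);
  std::vector<double> ux(n, 0.0), uy(n, 0.0), rr(n, 1.0);
  // Diagonally-implicit particle forcing: the exchanged force at a node
  // is applied as F = C - B u_new with C the u-independent part and
  // B = sum_p gamma_lat w_p^2 the node's drag-sink coefficient, so the
  // node momentum update u_new = (j + g + C)/(rho + B) is stable for any
  // exchange gain (explicit spreading diverges for gamma_lat sum w^2 > 1,
  // which dense thrombi reach at coarse time steps).
  std::vector<double> pcx(n, 0.0), pcy(n, 0.0);   // C (lattice force)
  std::vector<double> pB(n, 0.0);                 // B (lattice)
  // lattice drag coefficient: force (lattice) per unit lattice velocity
  const double gamma_lat = gamma_t * c_force * c_vel;

  // platelet state (physical units); ids stable
  std::vector<double> px, py, vx, vy, om, act_time;
  std::vector<int> act, pid;
  int next_id = 0;
  for (int p = 0; p < platelets0.nrow(); ++p) {
    px.push_back(platelets0(p, 0)); py.push_back(platelets0(p, 1));
    vx.push_back(platelets0(p, 2)); vy.push_back(platelets0(p, 3));
    om.push_back(platelets0(p, 4));
    act.push_back((int)platelets0(p, 5));
    act_time.push_back(platelets0(p, 5) > 0 ? 0.0 : NA_REAL);
    pid.push_back(next_id++);
  }

  std::vector<Bond> bonds;
  std::unordered_set<long long> bond_keys;      // pair: lo*M+hi; wall: id
  const long long M = 1LL << 31;
  auto pair_key = [&](int a_, int b_) {
    long long lo = std::min(a_, b_), hi = std::max(a_, b_);
    return lo * M + hi;
  };
  auto wall_key = [&](int a_) { return -((long long)a_ + 2); };

  // outputs
  int n_diag = n_steps / diag_every + 1;
  NumericMatrix diag(n_diag, 10);
  colnames(diag) = CharacterVector::create(
    "time", "flow_rate", "wall_shear_max", "n_platelets", "n_activated",
    "n_activated_total", "n_bonds", "largest_thrombus", "n_thrombi",
    "momentum_exchange");
  long n_act_total = 0;                         // cumulative, never removed
  for (int p = 0; p < (int)act.size(); ++p) n_act_total += act[p];
  int diag_row = 0;
  std::vector<double> plog;                     // platelet snapshot log
  int plog_cols = 9;

  double mass0 = 0;
  for (size_t idx = 0; idx < n; ++idx)
    if (msk[idx]) for (int k = 0; k < 9; ++k) mass0 += fa[idx + n * k];

  double occl_time = NA_REAL;
  long below_since = -1;
  double q_latest = q0;
  double max_overlap = 0.0, max_newton = 0.0, mass_drift = 0.0;
  double mex_resid = 0.0;                       // exchange bookkeeping
  bool aborted = false;
  std::string abort_msg;

  // scratch per-platelet arrays
  std::vector<double> fx_tot, fy_tot, fpx_pair, fpy_pair,
    ufx, ufy, vort, shear, dragx, dragy;
  std::vector<char> in_contact_act;
  // per-step memo of nodal shear/vorticity (platelet stencils overlap)
  std::vector<double> shear_node(n, 0.0), vort_node(n, 0.0);
  std::vector<long> node_stamp(n, -1);
  // contact broad-phase cell lists
  std::vector<int> cl_head, cl_next, cl_cx, cl_cy;

  double fpost[9];
  long step = 0;
  double mex_applied = 0.0;                     // applied exchange, last step
  for (step = 0; step < n_steps; ++step) {
    // ---- LBM collide + stream (fused with moment computation) ----
    double q_lat = 0.0;
    mex_applied = 0.0;
    for (size_t idx = 0; idx < n; ++idx) {
      if (!msk[idx]) continue;
      double r = 0, jx = 0, jy = 0;
      for (int k = 0; k < 9; ++k) {
        double fk = fa[idx + n * k];
        r += fk; jx += fk * CX[k]; jy += fk * CY[k];
      }
      double u = jx / r, v = jy / r;
      rr[idx] = r; ux[idx] = u; uy[idx] = v;
      q_lat += u;
      double usq = u * u + v * v;
      // implicit-in-u particle force at this node
      double B = pB[idx];
      double Fpx = 0.0, Fpy = 0.0;
      if (B > 0) {
        double unew = (jx + gx_lat + pcx[idx]) / (r + B);
        double vnew = (jy + pcy[idx]) / (r + B);
        Fpx = pcx[idx] - B * unew;
        Fpy = pcy[idx] - B * vnew;
        mex_applied += Fpx;
      }
      double Fx = gx_lat + Fpx, Fy = Fpy;
      for (int k = 0; k < 9; ++k) {
        double cu = CX[k] * u + CY[k] * v;
        double feq = r * W[k] * (1 + 3 * cu + 4.5 * cu * cu - 1.5 * usq);
        fpost[k] = fa[idx + n * k] - omega_bgk * (fa[idx + n * k] - feq) +
          3.0 * W[k] * (Fx * CX[k] + Fy * CY[k]);
      }
      fb[idx] = fpost[0];
      for (int k = 1; k < 9; ++k) {
        int dest = nb[idx + n * k];
        if (msk[dest]) fb[(size_t)dest + n * k] = fpost[k];
        else fb[idx + n * OPP[k]] = fpost[k];
      }
    }
    double q_now = (q_lat / nx) * c_q;
    q_latest = q_now;
    if (ISNA(q0)) { q0 = q_now; }

    // ---- platelet phase (fields frozen at time t) ----
    int np = (int)px.size();
    fx_tot.assign(np, 0.0); fy_tot.assign(np, 0.0);
    fpx_pair.assign(np, 0.0); fpy_pair.assign(np, 0.0);
    ufx.assign(np, 0.0); ufy.assign(np, 0.0);
    vort.assign(np, 0.0); shear.assign(np, 0.0);
    dragx.assign(np, 0.0); dragy.assign(np, 0.0);
    in_contact_act.assign(np, 0);

    // field sampling: footprint-averaged velocity, bilinear shear/vorticity
    DiscKernel K;
    for (int p = 0; p < np; ++p) {
      bool ok1 = disc_kernel(G, px[p], py[p], kernel_radius, K);
      if (ok1) {
        double sx = 0, sy = 0;
        for (int k = 0; k < K.n; ++k) {
          sx += K.w[k] * ux[K.idx[k]];
          sy += K.w[k] * uy[K.idx[k]];
        }
        ufx[p] = sx * c_vel; ufy[p] = sy * c_vel;
      }
      if (!ok1) {
        aborted = true;
        char buf[256];
        snprintf(buf, sizeof(buf),
                 "platelet inside wall (id %d at x=%.4g um, y=%.4g um, "
                 "v=(%.4g,%.4g) m/s, phi=%.4g um, half_width=%.4g um)",
                 pid[p], px[p] * 1e6, py[p] * 1e6, vx[p], vy[p],
                 interp_plain(G, phi.data(), px[p], py[p]) * 1e6,
                 half_width * 1e6);
        abort_msg = buf;
        break;
      }
      // vorticity and shear from the 4 surrounding nodes
      int idq[4]; double wq[4];
      stencil(G, px[p], py[p], idq, wq);
      double wv = 0, sv = 0, wtot = 0;
      for (int q = 0; q < 4; ++q) {
        int idx = idq[q];
        if (!msk[idx]) continue;
        if (node_stamp[idx] != step) {
          node_stamp[idx] = step;
          // node vorticity dv/dx - du/dy (solid-neighbour u is 0: no-slip)
          int i = idx % nx, j = idx / nx;
          int ip = G.wrapx(i + 1) + nx * j, im = G.wrapx(i - 1) + nx * j;
          int jp = i + nx * std::min(j + 1, ny - 1);
          int jm = i + nx * std::max(j - 1, 0);
          vort_node[idx] = ((uy[ip] - uy[im]) - (ux[jp] - ux[jm])) / 2.0;
          // node shear scalar from non-equilibrium populations
          double u = ux[idx], v = uy[idx], r = rr[idx];
          double usq = u * u + v * v;
          double sxx = 0, syy = 0, sxy = 0;
          for (int k = 0; k < 9; ++k) {
            double cu = CX[k] * u + CY[k] * v;
            double feq = r * W[k] * (1 + 3 * cu + 4.5 * cu * cu - 1.5 * usq);
            double fneq = fa[idx + n * k] - feq;
            sxx += fneq * CX[k] * CX[k];
            syy += fneq * CY[k] * CY[k];
            sxy += fneq * CX[k] * CY[k];
          }
          sxx *= -sfac; syy *= -sfac; sxy *= -sfac;
          double dd = 0.5 * (sxx - syy);
          shear_node[idx] = std::sqrt(dd * dd + sxy * sxy);
        }
        wv += wq[q] * vort_node[idx];
        sv += wq[q] * shear_node[idx];
        wtot += wq[q];
      }
      if (wtot > 0) { vort[p] = (wv / wtot) / dt; shear[p] = (sv / wtot) * c_stress; }
    }
    if (aborted) break;

    // DEM sub-stepping: contacts, activation, bonds and motion advance
    // n_sub times per fluid step with the sampled fields held frozen
    for (int sub = 0; sub < n_sub; ++sub) {
    fx_tot.assign(np, 0.0); fy_tot.assign(np, 0.0);

    // pairwise contacts + activation-by-contact bookkeeping; a uniform
    // cell grid (cell >= interaction radius 2a) gives an O(N) broad phase
    std::vector<std::pair<int,int> > touching;
    {
      const double sumr = 2 * a;
      auto handle_pair = [&](int p, int q) {
        double ddx = px[p] - px[q], ddy = py[p] - py[q];
        double d2 = ddx * ddx + ddy * ddy;
        if (d2 >= sumr * sumr || d2 == 0) return;
        double d = std::sqrt(d2);
        double nxn = ddx / d, nyn = ddy / d;     // from q towards p
        double overlap = sumr - d;
        if (overlap / a > max_overlap) max_overlap = overlap / a;
        touching.push_back(std::make_pair(p, q));
        // elastic repulsion (equal and opposite)
        double fe = k_coll * overlap;
        // normal damping, coefficient clamped at critical damping of the
        // pair (stability; the printed coefficient is far overcritical)
        double vn = (vx[p] - vx[q]) * nxn + (vy[p] - vy[q]) * nyn;
        double fm = fe - eta_pair * vn;
        fx_tot[p] += fm * nxn; fy_tot[p] += fm * nyn;
        fx_tot[q] -= fm * nxn; fy_tot[q] -= fm * nyn;
        fpx_pair[p] += fm * nxn; fpy_pair[p] += fm * nyn;
        fpx_pair[q] -= fm * nxn; fpy_pair[q] -= fm * nyn;
      };
      int ncx = std::max(1, (int)std::floor(domain_length / sumr));
      double y0 = -(margin + 0.5) * dx;
      double Hy = ny * dx;
      int ncy = std::max(1, (int)std::floor(Hy / sumr));
      if (ncx < 3 || np < 16) {
        for (int p = 0; p < np; ++p)
          for (int q = p + 1; q < np; ++q) handle_pair(p, q);
      } else {
        double hx = domain_length / ncx, hy = Hy / ncy;
        cl_head.assign((size_t)ncx * ncy, -1);
        cl_next.assign(np, -1);
        cl_cx.resize(np); cl_cy.resize(np);
        for (int p = 0; p < np; ++p) {
          int cx = (int)std::floor(px[p] / hx) % ncx; if (cx < 0) cx += ncx;
          int cy = (int)std::floor((py[p] - y0) / hy);
          if (cy < 0) cy = 0; else if (cy >= ncy) cy = ncy - 1;
          cl_cx[p] = cx; cl_cy[p] = cy;
          cl_next[p] = cl_head[cx + ncx * cy];
          cl_head[cx + ncx * cy] = p;
        }
        for (int p = 0; p < np; ++p) {
          for (int dcy = -1; dcy <= 1; ++dcy) {
            int cy = cl_cy[p] + dcy;
            if (cy < 0 || cy >= ncy) continue;
            for (int dcx = -1; dcx <= 1; ++dcx) {
              int cx = (cl_cx[p] + dcx) % ncx; if (cx < 0) cx += ncx;
              for (int q = cl_head[cx + ncx * cy]; q >= 0; q = cl_next[q]) {
                if (q > p) handle_pair(p, q);
              }
            }
          }
        }
      }
    }

    // wall contact
    for (int p = 0; p < np; ++p) {
      double ph = interp_plain(G, phi.data(), px[p], py[p]);
      double wall_dist = half_width - ph;        // centre-to-wall distance
      double overlap = a - wall_dist;
      if (overlap <= 0) continue;
      if (overlap / a > max_overlap) max_overlap = overlap / a;
      double gx = interp_plain(G, gpx.data(), px[p], py[p]);
      double gy = interp_plain(G, gpy.data(), px[p], py[p]);
      double gn = std::sqrt(gx * gx + gy * gy);
      if (gn < 1e-12) continue;
      double nxn = -gx / gn, nyn = -gy / gn;     // away from wall
      double fe = k_coll * overlap;
      fx_tot[p] += fe * nxn; fy_tot[p] += fe * nyn;
      double vn = vx[p] * nxn + vy[p] * nyn;
      double fd = -eta_wall * vn;
      fx_tot[p] += fd * nxn; fy_tot[p] += fd * nyn;
    }

    // ---- activation: critical shear or touching an activated platelet ----
    double t_now = (step + 1) * dt;
    for (int p = 0; p < np; ++p) {
      if (!act[p] && shear[p] >= tau_crit) {
        act[p] = 1; act_time[p] = t_now; n_act_total++;
      }
    }
    for (size_t c = 0; c < touching.size(); ++c) {
      int p = touching[c].first, q = touching[c].second;
      if (act[p] && !act[q]) { act[q] = 1; act_time[q] = t_now; n_act_total++; }
      else if (act[q] && !act[p]) { act[p] = 1; act_time[p] = t_now; n_act_total++; }
    }

    // ---- bond lifecycle ----
    // index lookup for current ids
    std::vector<int> id2idx;
    {
      int maxid = next_id;
      id2idx.assign(maxid, -1);
      for (int p = 0; p < np; ++p) id2idx[pid[p]] = p;
    }
    // formation: activated pairs in contact
    for (size_t c = 0; c < touching.size(); ++c) {
      int p = touching[c].first, q = touching[c].second;
      if (!(act[p] && act[q])) continue;
      long long key = pair_key(pid[p], pid[q]);
      if (bond_keys.count(key)) continue;
      double d = std::sqrt((px[p] - px[q]) * (px[p] - px[q]) +
                           (py[p] - py[q]) * (py[p] - py[q]));
      Bond b; b.id_i = pid[p]; b.id_j = pid[q];
      b.ax = 0; b.ay = 0; b.rest = d; b.t0 = t_now;
      bonds.push_back(b); bond_keys.insert(key);
    }
    // formation: activated platelet touching the wall
    for (int p = 0; p < np; ++p) {
      if (!act[p]) continue;
      long long key = wall_key(pid[p]);
      if (bond_keys.count(key)) continue;
      double ph = interp_plain(G, phi.data(), px[p], py[p]);
      double wall_dist = half_width - ph;
      if (wall_dist > a) continue;               // not touching
      double gx = interp_plain(G, gpx.data(), px[p], py[p]);
      double gy = interp_plain(G, gpy.data(), px[p], py[p]);
      double gn = std::sqrt(gx * gx + gy * gy);
      if (gn < 1e-12) continue;
      Bond b; b.id_i = pid[p]; b.id_j = -1;
      b.ax = px[p] + (gx / gn) * wall_dist;      // nearest wall point
      b.ay = py[p] + (gy / gn) * wall_dist;
      b.rest = std::max(wall_dist, 0.0);
      b.t0 = t_now;
      bonds.push_back(b); bond_keys.insert(key);
    }
    // forces + rupture
    {
      size_t keep = 0;
      for (size_t c = 0; c < bonds.size(); ++c) {
        Bond& b = bonds[c];
        int p = (b.id_i < (int)id2idx.size()) ? id2idx[b.id_i] : -1;
        int q = (b.id_j >= 0 && b.id_j < (int)id2idx.size())
          ? id2idx[b.id_j] : -1;
        bool drop = false;
        if (p < 0 || (b.id_j >= 0 && q < 0)) {
          drop = true;                           // endpoint left the domain
        } else {
          double tx, ty;                         // towards the partner
          if (b.id_j >= 0) { tx = px[q] - px[p]; ty = py[q] - py[p]; }
          else { tx = b.ax - px[p]; ty = b.ay - py[p]; }
          double d = std::sqrt(tx * tx + ty * ty);
          double ext = d - b.rest;
          if (ext > delta_break) {
            drop = true;                         // rupture
          } else if (ext > 0 && d > 0) {
            double fm = k_adh * ext;
            double nxn = tx / d, nyn = ty / d;
            fx_tot[p] += fm * nxn; fy_tot[p] += fm * nyn;
            if (b.id_j >= 0) {
              fx_tot[q] -= fm * nxn; fy_tot[q] -= fm * nyn;
              fpx_pair[p] += fm * nxn; fpy_pair[p] += fm * nyn;
              fpx_pair[q] -= fm * nxn; fpy_pair[q] -= fm * nyn;
            }
          }
        }
        if (drop) {
          bond_keys.erase(b.id_j >= 0 ? pair_key(b.id_i, b.id_j)
                                      : wall_key(b.id_i));
        } else {
          bonds[keep++] = b;
        }
      }
      bonds.resize(keep);
    }

    // ---- integrate motion (exponential drag; impulses after) ----
    for (int p = 0; p < np; ++p) {
      // drag recorded before the velocity update (reaction on the fluid)
      dragx[p] = -gamma_t * (vx[p] - ufx[p]);
      dragy[p] = -gamma_t * (vy[p] - ufy[p]);
      double vtx = ufx[p] + fx_tot[p] / gamma_t;
      double vty = ufy[p] + fy_tot[p] / gamma_t;
      vx[p] = vtx + (vx[p] - vtx) * decay_t;
      vy[p] = vty + (vy[p] - vty) * decay_t;
      double omt = vort_factor * vort[p];
      om[p] = omt + (om[p] - omt) * decay_r;
      px[p] += vx[p] * dts; py[p] += vy[p] * dts;
      if (!R_finite(px[p]) || !R_finite(vx[p]) || !R_finite(py[p])) {
        aborted = true; abort_msg = "non-finite platelet state"; break;
      }
    }
    if (aborted) break;
    }  // end DEM substeps
    if (aborted) break;

    // ---- spread reaction (-drag) onto the lattice for the next step ----
    // Same footprint kernel as the interpolation (adjoint).  The spread
    // target F_p = -drag reaction is split into its u-independent part C
    // and the drag-sink coefficient B for the implicit application above:
    //   C_node = sum_p w_p (-drag_p) c_force + B_node u_node
    std::fill(pcx.begin(), pcx.end(), 0.0);
    std::fill(pcy.begin(), pcy.end(), 0.0);
    std::fill(pB.begin(), pB.end(), 0.0);
    {
      double target_x = 0, target_y = 0, spread_x = 0, spread_y = 0;
      for (int p = 0; p < np; ++p) {
        if (!disc_kernel(G, px[p], py[p], kernel_radius, K)) continue;
        for (int k = 0; k < K.n; ++k) {
          pcx[K.idx[k]] += K.w[k] * (-dragx[p]) * c_force;
          pcy[K.idx[k]] += K.w[k] * (-dragy[p]) * c_force;
          pB[K.idx[k]] += gamma_lat * K.w[k] * K.w[k];
        }
        target_x += (-dragx[p]) * c_force;
        target_y += (-dragy[p]) * c_force;
      }
      for (size_t idx = 0; idx < n; ++idx) {
        spread_x += pcx[idx]; spread_y += pcy[idx];
        pcx[idx] += pB[idx] * ux[idx];
        pcy[idx] += pB[idx] * uy[idx];
      }
      // spread-conservation identity: total spread target equals the
      // total platelet reaction (weights are normalised)
      double scale = std::max(std::fabs(target_x) + std::fabs(target_y),
                              1e-300);
      double mres = (std::fabs(spread_x - target_x) +
                     std::fabs(spread_y - target_y)) / scale;
      if (np > 0 && mres > mex_resid) mex_resid = mres;
    }

    // ---- removal at the outlet ----
    for (int p = np - 1; p >= 0; --p) {
      if (px[p] > domain_length || px[p] < -dx) {
        px.erase(px.begin() + p); py.erase(py.begin() + p);
        vx.erase(vx.begin() + p); vy.erase(vy.begin() + p);
        om.erase(om.begin() + p); act.erase(act.begin() + p);
        act_time.erase(act_time.begin() + p); pid.erase(pid.begin() + p);
      }
    }

    // ---- injection: Bernoulli approximation of Poisson arrivals ----
    if (inject && (int)px.size() < max_platelets) {
      double rate = conc2d * std::max(q_latest, 0.0);
      if (R::unif_rand() < rate * dt) {
        for (int attempt = 0; attempt < 10; ++attempt) {
          double xn = R::unif_rand() * dx;
          double yn = inlet_y_lo + R::unif_rand() * (inlet_y_hi - inlet_y_lo);
          bool free_spot = true;
          for (size_t p = 0; p < px.size(); ++p) {
            double ddx = px[p] - xn, ddy = py[p] - yn;
            if (ddx * ddx + ddy * ddy < 4 * a * a) { free_spot = false; break; }
          }
          if (!free_spot) continue;
          bool ok1, ok2;
          double ufx0 = interp_masked(G, ux.data(), xn, yn, ok1) * c_vel;
          double ufy0 = interp_masked(G, uy.data(), xn, yn, ok2) * c_vel;
          if (!ok1) continue;
          px.push_back(xn); py.push_back(yn);
          vx.push_back(ufx0); vy.push_back(ufy0);
          om.push_back(0.0); act.push_back(0);
          act_time.push_back(NA_REAL); pid.push_back(next_id++);
          break;
        }
      }
    }

    // ---- occlusion tracking (per step) ----
    if (!ISNA(q0) && q0 > 0) {
      if (q_now < occl_frac * q0) {
        if (below_since < 0) below_since = step;
        if (ISNA(occl_time) && step - below_since + 1 >= occl_sustain)
          occl_time = (below_since + 1) * dt;
      } else {
        below_since = -1;
        if (!ISNA(occl_time)) occl_time = NA_REAL;  // reopened: not sustained
      }
    }

    fa.swap(fb);

    // ---- diagnostics ----
    if ((step + 1) % diag_every == 0 || step == n_steps - 1) {
      // newton residual over pair forces
      double sx = 0, sy = 0;
      for (int p = 0; p < (int)px.size() && p < (int)fpx_pair.size(); ++p) {
        sx += fpx_pair[p]; sy += fpy_pair[p];
      }
      double nres = std::sqrt(sx * sx + sy * sy);
      if (nres > max_newton) max_newton = nres;
      double mass = 0;
      for (size_t idx = 0; idx < n; ++idx)
        if (msk[idx]) for (int k = 0; k < 9; ++k) mass += fa[idx + n * k];
      double mdrift = std::fabs(mass - mass0) / mass0;
      if (mdrift > mass_drift) mass_drift = mdrift;
      // wall shear max
      double wsmax = 0, umax2 = 0;
      for (size_t c = 0; c < wall_nodes.size(); ++c) {
        int idx = wall_nodes[c];
        double u = ux[idx], v = uy[idx], r = rr[idx];
        double usq = u * u + v * v;
        double sxx = 0, syy = 0, sxy = 0;
        for (int k = 0; k < 9; ++k) {
          double cu = CX[k] * u + CY[k] * v;
          double feq = r * W[k] * (1 + 3 * cu + 4.5 * cu * cu - 1.5 * usq);
          double fneq = fa[(size_t)idx + n * k] - feq;
          sxx += fneq * CX[k] * CX[k];
          syy += fneq * CY[k] * CY[k];
          sxy += fneq * CX[k] * CY[k];
        }
        sxx *= -sfac; syy *= -sfac; sxy *= -sfac;
        double dd = 0.5 * (sxx - syy);
        double smax = std::sqrt(dd * dd + sxy * sxy);
        if (smax > wsmax) wsmax = smax;
      }
      for (size_t idx = 0; idx < n; ++idx) {
        if (!msk[idx]) continue;
        double u2 = ux[idx] * ux[idx] + uy[idx] * uy[idx];
        if (u2 > umax2) umax2 = u2;
      }
      if (umax2 > 0.09) { aborted = true; abort_msg = "Mach guard tripped"; }
      // census
      int npn = (int)px.size();
      int nact = 0;
      for (int p = 0; p < npn; ++p) nact += act[p];
      std::vector<int> id2i(next_id, -1);
      for (int p = 0; p < npn; ++p) id2i[pid[p]] = p;
      UF uf(npn);
      for (size_t c = 0; c < bonds.size(); ++c) {
        if (bonds[c].id_j < 0) continue;
        int p = id2i[bonds[c].id_i], q = id2i[bonds[c].id_j];
        if (p >= 0 && q >= 0) uf.join(p, q);
      }
      std::vector<int> csize(npn, 0);
      int largest = 0, ncomp = 0;
      for (int p = 0; p < npn; ++p) {
        int r = uf.find(p);
        if (++csize[r] > largest) largest = csize[r];
      }
      for (int p = 0; p < npn; ++p)
        if (uf.find(p) == p && csize[p] >= 2) ncomp++;
      // momentum exchanged with the fluid this step (lattice force sum)
      double mex = mex_applied;
      if (diag_row < n_diag) {
        diag(diag_row, 0) = (step + 1) * dt;
        diag(diag_row, 1) = q_now;
        diag(diag_row, 2) = wsmax * c_stress;
        diag(diag_row, 3) = npn;
        diag(diag_row, 4) = nact;
        diag(diag_row, 5) = (double)n_act_total;
        diag(diag_row, 6) = (double)bonds.size();
        diag(diag_row, 7) = largest;
        diag(diag_row, 8) = ncomp;
        diag(diag_row, 9) = mex;
        diag_row++;
      }
      Rcpp::checkUserInterrupt();
      if (aborted) break;
    }

    // ---- platelet snapshot log ----
    if (snapshot_every > 0 && (step + 1) % snapshot_every == 0) {
      for (size_t p = 0; p < px.size(); ++p) {
        plog.push_back((step + 1) * dt);
        plog.push_back(pid[p]);
        plog.push_back(px[p]); plog.push_back(py[p]);
        plog.push_back(vx[p]); plog.push_back(vy[p]);
        plog.push_back(om[p]); plog.push_back(act[p]);
        plog.push_back(act_time[p]);
      }
    }
  }

  // final platelet table
  int npn = (int)px.size();
  NumericMatrix pl(npn, 8);
  colnames(pl) = CharacterVector::create(
    "id", "x", "y", "vx", "vy", "omega", "activated", "activation_time");
  for (int p = 0; p < npn; ++p) {
    pl(p, 0) = pid[p]; pl(p, 1) = px[p]; pl(p, 2) = py[p];
    pl(p, 3) = vx[p]; pl(p, 4) = vy[p]; pl(p, 5) = om[p];
    pl(p, 6) = act[p]; pl(p, 7) = act_time[p];
  }
  NumericMatrix bd((int)bonds.size(), 6);
  colnames(bd) = CharacterVector::create(
    "id_i", "id_j", "anchor_x", "anchor_y", "rest", "t_form");
  for (int c = 0; c < (int)bonds.size(); ++c) {
    bd(c, 0) = bonds[c].id_i; bd(c, 1) = bonds[c].id_j;
    bd(c, 2) = bonds[c].ax; bd(c, 3) = bonds[c].ay;
    bd(c, 4) = bonds[c].rest; bd(c, 5) = bonds[c].t0;
  }
  NumericMatrix plm((int)(plog.size() / plog_cols), plog_cols);
  for (int r0 = 0; r0 < plm.nrow(); ++r0)
    for (int c0 = 0; c0 < plog_cols; ++c0)
      plm(r0, c0) = plog[(size_t)r0 * plog_cols + c0];
  colnames(plm) = CharacterVector::create(
    "time", "id", "x", "y", "vx", "vy", "omega", "activated",
    "activation_time");

  NumericVector fout(fa.begin(), fa.end());
  return List::create(
    _["diagnostics"] = diag(Range(0, std::max(diag_row - 1, 0)), _),
    _["platelets"] = pl,
    _["bonds"] = bd,
    _["platelet_log"] = plm,
    _["f"] = fout,
    _["q0"] = q0,
    _["occlusion_time"] = occl_time,
    _["steps_run"] = (double)step,
    _["aborted"] = aborted,
    _["abort_reason"] = abort_msg,
    _["checks"] = List::create(
      _["max_overlap_frac"] = max_overlap,
      _["max_newton_resid"] = max_newton,
      _["mass_drift_rel"] = mass_drift,
      _["mex_resid_rel"] = mex_resid));
}
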