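// D2Q9 BGK lattice-Boltzmann kernel with body/particle forcing,
// half-way bounce-back walls and fully periodic wrap.
//
// Lattice layout: node (i, j) -> idx = i + nx * j, i = 0..nx-1 (flow
// direction, periodic), j = 0..ny-1.  Populations are stored as a
// nx*ny*9 vector, direction k at idx + nx*ny*k.  All quantities are in
// lattice units (dx = dt = rho0 = 1); unit conversion lives on the R side.
//
// Direction order (weights 4/9, then alternating 1/9 axis / 1/36 diagonal):
//   0:( 0, 0)  1:( 1, 0)  2:( 1, 1)  3:( 0, 1)  4:(-1, 1)
//   5:(-1, 0)  6:(-1,-1)  7:( 0,-1)  8:( 1,-1)

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const int CX[9] = {0, 1, 1, 0, -1, -1, -1, 0, 1};
static const int CY[9] = {0, 0, 1, 1, 1, 0, -1, -1, -1};
static const double W[9] = {4.0 / 9.0,
                            1.0 / 9.0, 1.0 / 36.0, 1.0 / 9.0, 1.0 / 36.0,
                            1.0 / 9.0, 1.0 / 36.0, 1.0 / 9.0, 1.0 / 36.0};
static const int OPP[9] = {0, 5, 6, 7, 8, 1, 2, 3, 4};

// Streaming neighbour table: for each node and direction, the linear index
// of the destination node (periodic torus; solid rows block in practice).
static std::vector<int> make_neighbors(int nx, int ny) {
  std::vector<int> nb((size_t)nx * ny * 9);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      int idx = i + nx * j;
      for (int k = 0; k < 9; ++k) {
        int ii = i + CX[k];
        int jj = j + CY[k];
        if (ii < 0) ii += nx; else if (ii >= nx) ii -= nx;
        if (jj < 0) jj += ny; else if (jj >= ny) jj -= ny;
        nb[(size_t)idx + (size_t)nx * ny * k] = ii + nx * jj;
      }
    }
  }
  return nb;
}

// One collide+stream step, writing post-streaming populations into fnew.
// force_x/force_y: per-node lattice force density (already includes any
// uniform body force).  Returns false if any post-collision population
// went negative (caller decides how to fail).
static bool step_kernel(const std::vector<double>& f,
                        std::vector<double>& fnew,
                        const std::vector<int>& mask,
                        const std::vector<int>& nb,
                        int nx, int ny, double tau,
                        const double* force_x, const double* force_y,
                        bool check_negative) {
  const size_t n = (size_t)nx * ny;
  const double omega = 1.0 / tau;
  bool ok = true;
  double fpost[9];
  for (size_t idx = 0; idx < n; ++idx) {
    if (!mask[idx]) continue;
    // moments (Eq. 2-3: velocity from bare first moment, no half-force shift)
    double rho = 0.0, jx = 0.0, jy = 0.0;
    for (int k = 0; k < 9; ++k) {
      double fk = f[idx + n * k];
      rho += fk;
      jx += fk * CX[k];
      jy += fk * CY[k];
    }
    double ux = jx / rho, uy = jy / rho;
    double usq = ux * ux + uy * uy;
    double Fx = force_x[idx], Fy = force_y[idx];
    for (int k = 0; k < 9; ++k) {
      double cu = CX[k] * ux + CY[k] * uy;
      double feq = rho * W[k] *
        (1.0 + 3.0 * cu + 4.5 * cu * cu - 1.5 * usq);
      double val = f[idx + n * k] - omega * (f[idx + n * k] - feq) +
        3.0 * W[k] * (Fx * CX[k] + Fy * CY[k]);
      if (check_negative && val < 0.0) ok = false;
      fpost[k] = val;
    }
    // stream (push), half-way bounce-back into solid neighbours
    fnew[idx] = fpost[0];
    for (int k = 1; k < 9; ++k) {
      int dest = nb[idx + n * k];
      if (mask[dest]) {
        fnew[(size_t)dest + n * k] = fpost[k];
      } else {
        fnew[idx + n * OPP[k]] = fpost[k];
      }
    }
  }
  return ok;
}

static void unpack_force(const NumericVector& fv, size_t n,
                         std::vector<double>& out) {
  out.assign(n, 0.0);
  if (fv.size() == 1) {
    std::fill(out.begin(), out.end(), fv[0]);
  } else if ((size_t)fv.size() == n) {
    std::copy(fv.begin(), fv.end(), out.begin());
  } else {
    stop("force field must have length 1 or nx*ny");
  }
}

// [[Rcpp::export]]
List cpp_lbm_step(NumericVector f, IntegerVector mask, int nx, int ny,
                  double tau, NumericVector force_x, NumericVector force_y) {
  const size_t n = (size_t)nx * ny;
  if ((size_t)f.size() != n * 9) stop("f must have length nx*ny*9");
  std::vector<double> fa(f.begin(), f.end());
  std::vector<double> fb(fa);
  std::vector<int> msk(mask.begin(), mask.end());
  std::vector<int> nb = make_neighbors(nx, ny);
  std::vector<double> fx, fy;
  unpack_force(force_x, n, fx);
  unpack_force(force_y, n, fy);
  bool ok = step_kernel(fa, fb, msk, nb, nx, ny, tau, fx.data(), fy.data(),
                        true);
  NumericVector out(fb.begin(), fb.end());
  return List::create(_["f"] = out, _["stable"] = ok);
}

// Run up to max_steps, checking the relative change of total x-momentum
// over each check_every window; stops when |dQ|/|Q| < rtol (per window).
// [[Rcpp::export]]
List cpp_lbm_run(NumericVector f, IntegerVector mask, int nx, int ny,
                 double tau, NumericVector force_x, NumericVector force_y,
                 int max_steps, int check_every, double rtol) {
  const size_t n = (size_t)nx * ny;
  if ((size_t)f.size() != n * 9) stop("f must have length nx*ny*9");
  std::vector<double> fa(f.begin(), f.end());
  std::vector<double> fb(fa);
  std::vector<int> msk(mask.begin(), mask.end());
  std::vector<int> nb = make_neighbors(nx, ny);
  std::vector<double> fx, fy;
  unpack_force(force_x, n, fx);
  unpack_force(force_y, n, fy);

  double q_prev = NA_REAL;
  bool converged = false;
  int steps = 0;
  double resid = NA_REAL;
  for (int s = 1; s <= max_steps; ++s) {
    bool ok = step_kernel(fa, fb, msk, nb, nx, ny, tau, fx.data(), fy.data(),
                          false);
    (void)ok;
    fa.swap(fb);
    steps = s;
    if (s % check_every == 0) {
      double q = 0.0;
      double umax2 = 0.0;
      for (size_t idx = 0; idx < n; ++idx) {
        if (!msk[idx]) continue;
        double rho = 0.0, jx = 0.0, jy = 0.0;
        for (int k = 0; k < 9; ++k) {
          double fk = fa[idx + n * k];
          rho += fk;
          jx += fk * CX[k];
          jy += fk * CY[k];
        }
        q += jx / rho;
        double u2 = (jx * jx + jy * jy) / (rho * rho);
        if (u2 > umax2) umax2 = u2;
      }
      if (umax2 > 0.09)
        stop("LBM instability: lattice |u| exceeded 0.3 (Mach guard)");
      if (!ISNA(q_prev) && q != 0.0) {
        resid = std::fabs(q - q_prev) / std::max(std::fabs(q), 1e-300);
        if (resid < rtol) { converged = true; break; }
      }
      q_prev = q;
      Rcpp::checkUserInterrupt();
    }
  }
  NumericVector out(fa.begin(), fa.end());
  return List::create(_["f"] = out, _["steps"] = steps,
                      _["converged"] = converged, _["resid"] = resid);
}

// Macroscopic density and velocity fields (lattice units).
// [[Rcpp::export]]
List cpp_macroscopics(NumericVector f, IntegerVector mask, int nx, int ny) {
  const size_t n = (size_t)nx * ny;
  NumericVector rho(n), ux(n), uy(n);
  for (size_t idx = 0; idx < n; ++idx) {
    if (!mask[idx]) { rho[idx] = NA_REAL; ux[idx] = 0; uy[idx] = 0; continue; }
    double r = 0.0, jx = 0.0, jy = 0.0;
    for (int k = 0; k < 9; ++k) {
      double fk = f[idx + n * k];
      r += fk; jx += fk * CX[k]; jy += fk * CY[k];
    }
    rho[idx] = r; ux[idx] = jx / r; uy[idx] = jy / r;
  }
  return List::create(_["rho"] = rho, _["ux"] = ux, _["uy"] = uy);
}

// Maximum-shear scalar from non-equilibrium populations (lattice units):
//   sigma_ab = -(1 - 1/(2 tau)) * sum_k fneq_k c_ka c_kb
//   tau_max  = sqrt(((sxx - syy)/2)^2 + sxy^2)
// [[Rcpp::export]]
NumericVector cpp_shear_stress(NumericVector f, IntegerVector mask,
                               int nx, int ny, double tau) {
  const size_t n = (size_t)nx * ny;
  NumericVector out(n);
  const double fac = 1.0 - 1.0 / (2.0 * tau);
  for (size_t idx = 0; idx < n; ++idx) {
    if (!mask[idx]) { out[idx] = NA_REAL; continue; }
    double r = 0.0, jx = 0.0, jy = 0.0;
    for (int k = 0; k < 9; ++k) {
      double fk = f[idx + n * k];
      r += fk; jx += fk * CX[k]; jy += fk * CY[k];
    }
    double ux = jx / r, uy = jy / r;
    double usq = ux * ux + uy * uy;
    double sxx = 0.0, syy = 0.0, sxy = 0.0;
    for (int k = 0; k < 9; ++k) {
      double cu = CX[k] * ux + CY[k] * uy;
      double feq = r * W[k] * (1.0 + 3.0 * cu + 4.5 * cu * cu - 1.5 * usq);
      double fneq = f[idx + n * k] - feq;
      sxx += fneq * CX[k] * CX[k];
      syy += fneq * CY[k] * CY[k];
      sxy += fneq * CX[k] * CY[k];
    }
    sxx *= -fac; syy *= -fac; sxy *= -fac;
    double d = 0.5 * (sxx - syy);
    out[idx] = std::sqrt(d * d + sxy * sxy);
  }
  return out;
}

// Minimum Euclidean distance from each lattice node to a sampled curve
// (x periodic with period xper).  Used for normal-offset wall masks.
// [[Rcpp::export]]
NumericVector cpp_dist_to_curve(NumericVector node_x, NumericVector node_y,
                                NumericVector curve_x, NumericVector curve_y,
                                double xper) {
  int nn = node_x.size(), nc = curve_x.size();
  NumericVector out(nn);
  for (int p = 0; p < nn; ++p) {
    double best = R_PosInf;
    double x0 = node_x[p], y0 = node_y[p];
    for (int q = 0; q < nc; ++q) {
      double dx = std::fabs(curve_x[q] - x0);
      if (xper > 0 && dx > 0.5 * xper) dx = xper - dx;
      double dy = curve_y[q] - y0;
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}
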