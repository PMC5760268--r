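# D2Q9 BGK solver: R-level state handling and diagnostics around the
# compiled kernel in src/lbm.cpp.  Direction order (matching the kernel):
#   0:(0,0) 1:(1,0) 2:(1,1) 3:(0,1) 4:(-1,1) 5:(-1,0) 6:(-1,-1) 7:(0,-1) 8:(1,-1)

d2q9_weights <- function() {
  c(4 / 9, 1 / 9, 1 / 36, 1 / 9, 1 / 36, 1 / 9, 1 / 36, 1 / 9, 1 / 36)
}
d2q9_cx <- function() c(0, 1, 1, 0, -1, -1, -1, 0, 1)
d2q9_cy <- function() c(0, 0, 1, 1, 1, 0, -1, -1, -1)

#' D2Q9 equilibrium distribution
#'
#' \eqn{f_i^{eq} = \rho w_i [1 + 3(c_i\cdot u) + \frac{9}{2}(c_i\cdot u)^2
#' - \frac{3}{2}(u\cdot u)]} in lattice units.
#'
#' @param rho Density (lattice units).
#' @param u Velocity 2-vector (lattice units; |u| should stay well below
#'   the sound speed, warn above 0.3).
#' @return Numeric 9-vector of equilibrium populations.
#' @examples
#' lbm_equilibrium(1, c(0, 0))  # the nine weights
#' @export
lbm_equilibrium <- function(rho, u) {
  stopifnot(length(u) == 2, rho > 0)
  if (sqrt(sum(u^2)) >= 0.3)
    warning("lattice velocity |u| >= 0.3: outside the low-Mach regime")
  w <- d2q9_weights()
  cu <- d2q9_cx() * u[1] + d2q9_cy() * u[2]
  rho * w * (1 + 3 * cu + 4.5 * cu^2 - 1.5 * sum(u^2))
}

#' Relaxation time from lattice viscosity
#'
#' \eqn{\tau = (6\nu + 1)/2} for the D2Q9 BGK model (lattice units).
#'
#' @param nu_lattice Kinematic viscosity in lattice units (> 0).
#' @return Relaxation time (> 1/2).
#' @export
tau_from_viscosity <- function(nu_lattice) {
  stopifnot(nu_lattice > 0)
  (6 * nu_lattice + 1) / 2
}

#' Lattice unit system
#'
#' Conversion factors between physical and lattice units for a given grid
#' spacing, time step and fluid.  Lattice density is 1 at \code{rho}.
#'
#' @param dx Grid spacing (m).
#' @param dt Time step (s).
#' @param rho Fluid density (kg/m^3).
#' @param nu Kinematic viscosity (m^2/s).
#' @return List with \code{nu_lat}, \code{tau} and multiplicative factors
#'   \code{velocity} (lattice -> m/s), \code{stress} (lattice -> Pa),
#'   \code{force_density} (N/m^3 -> lattice force density) and
#'   \code{flow_rate} (lattice column sum -> m^2/s).
#' @export
lattice_units <- function(dx, dt, rho = 1030, nu = 1.2e-6) {
  stopifnot(dx > 0, dt > 0, rho > 0, nu > 0)
  nu_lat <- nu * dt / dx^2
  list(dx = dx, dt = dt, rho = rho, nu = nu, mu = rho * nu,
       nu_lat = nu_lat, tau = tau_from_viscosity(nu_lat),
       velocity = dx / dt,
       stress = rho * dx^2 / dt^2,
       force_density = dt^2 / (rho * dx),
       flow_rate = dx^2 / dt)
}

#' Initialise a lattice-Boltzmann state
#'
#' Populations start at the rest equilibrium (\eqn{\rho = 1}, \eqn{u = 0}).
#'
#' @param geometry A \code{channel_geometry}.
#' @param units A \code{\link{lattice_units}} list; its \code{dx} must match
#'   the geometry's.
#' @return An object of class \code{lattice_state}.
#' @export
lattice_state <- function(geometry, units) {
  stopifnot(inherits(geometry, "channel_geometry"))
  if (abs(units$dx - geometry$dx) > 1e-9 * geometry$dx)
    stop("units$dx does not match geometry$dx")
  n <- geometry$nx * geometry$ny
  f <- rep(d2q9_weights(), each = n)
  structure(list(f = f, geometry = geometry, units = units,
                 nx = geometry$nx, ny = geometry$ny,
                 tau = units$tau, mask = geometry$mask),
            class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  mac <- lbm_macroscopics(x)
  umax <- max(abs(mac$ux), abs(mac$uy), na.rm = TRUE)
  cat(sprintf("lattice_state %d x %d, tau = %.4f, max lattice |u| ~ %.3g\n",
              x$nx, x$ny, x$tau, umax))
  invisible(x)
}

#' Lattice body-force density for a pressure drop
#'
#' Pressure drive for periodic channels: a pressure drop \code{dp} over
#' length \code{L} is applied as the uniform body-force density
#' \code{dp/L}, converted to lattice units.
#'
#' @param dp Pressure drop (Pa).
#' @param L Channel length (m).
#' @param units A \code{\link{lattice_units}} list.
#' @return Scalar lattice force density (use as the x-component of
#'   \code{body_force} in \code{\link{lbm_step}}).
#' @export
body_force_lattice <- function(dp, L, units) {
  (dp / L) * units$force_density
}

#' Advance the solver by one collide-and-stream step
#'
#' BGK relaxation toward local equilibrium, forcing term
#' \eqn{3 w_i (\vec F \cdot \vec c_i)}, streaming with half-way bounce-back
#' at solid nodes and periodic wrap in x.
#'
#' @param state A \code{lattice_state}.
#' @param body_force Uniform force density 2-vector in lattice units
#'   (e.g. \code{c(body_force_lattice, 0)} for a pressure drive).
#' @param particle_force Optional per-node force-density fields, a list
#'   \code{list(x =, y =)} of nx x ny matrices (lattice units), added to the
#'   body force.
#' @return The updated \code{lattice_state}.
#' @export
lbm_step <- function(state, body_force = c(0, 0), particle_force = NULL) {
  stopifnot(inherits(state, "lattice_state"), length(body_force) == 2)
  n <- state$nx * state$ny
  fx <- body_force[1]; fy <- body_force[2]
  if (!is.null(particle_force)) {
    fx <- as.numeric(particle_force$x) + fx
    fy <- as.numeric(particle_force$y) + fy
  }
  res <- cpp_lbm_step(state$f, state$mask, state$nx, state$ny, state$tau,
                      fx, fy)
  if (!res$stable)
    stop("LBM instability: negative population after collision ",
         "(reduce the time step or forcing)")
  state$f <- res$f
  state
}

#' Run the solver to steady state
#'
#' Steps until the relative change of total x-momentum over a
#' \code{check_every} window drops below \code{rtol}, or \code{max_steps}
#' is reached.
#'
#' @inheritParams lbm_step
#' @param max_steps Step budget.
#' @param check_every Convergence check interval (steps).
#' @param rtol Relative flow-change tolerance per window.
#' @param require_convergence Error (with the residual) if not converged.
#' @return The updated state, with attributes \code{steps},
#'   \code{converged} and \code{resid}.
#' @export
lbm_run_steady <- function(state, body_force = c(0, 0),
                           max_steps = 40000L, check_every = 100L,
                           rtol = 1e-8, require_convergence = TRUE) {
  stopifnot(inherits(state, "lattice_state"))
  res <- cpp_lbm_run(state$f, state$mask, state$nx, state$ny, state$tau,
                     body_force[1], body_force[2],
                     as.integer(max_steps), as.integer(check_every), rtol)
  if (require_convergence && !res$converged)
    stop(sprintf(
      "LBM did not converge in %d steps (last residual %.3g > rtol %.3g)",
      res$steps, res$resid, rtol))
  state$f <- res$f
  attr(state, "steps") <- res$steps
  attr(state, "converged") <- res$converged
  attr(state, "resid") <- res$resid
  state
}

#' Macroscopic fields of a lattice state
#'
#' @param state A \code{lattice_state}.
#' @param physical Convert velocity to m/s (default TRUE).
#' @return List of nx x ny matrices \code{rho} (lattice units; NA at solid
#'   nodes), \code{ux}, \code{uy}.
#' @export
lbm_macroscopics <- function(state, physical = TRUE) {
  mac <- cpp_macroscopics(state$f, state$mask, state$nx, state$ny)
  fac <- if (physical) state$units$velocity else 1
  list(rho = matrix(mac$rho, state$nx, state$ny),
       ux = matrix(mac$ux, state$nx, state$ny) * fac,
       uy = matrix(mac$uy, state$nx, state$ny) * fac)
}

#' Maximum-shear stress field
#'
#' Deviatoric stress from the non-equilibrium populations,
#' \eqn{\sigma_{\alpha\beta} = -(1 - 1/(2\tau)) \sum_i f_i^{neq}
#' c_{i\alpha} c_{i\beta}}, reduced to the maximum-shear scalar
#' \eqn{\tau_{max} = \sqrt{((\sigma_{xx}-\sigma_{yy})/2)^2 +
#' \sigma_{xy}^2}}.  Reduces to \eqn{|\mu\, du/dy|} in unidirectional shear.
#'
#' @param state A \code{lattice_state}.
#' @return nx x ny matrix in Pa (NA at solid nodes).
#' @export
shear_stress_field <- function(state) {
  s <- cpp_shear_stress(state$f, state$mask, state$nx, state$ny, state$tau)
  matrix(s, state$nx, state$ny) * state$units$stress
}

#' Wall shear stress
#'
#' Maximum of the shear-stress field over fluid nodes adjacent to a solid
#' node (the discrete wall value, sampled half a lattice spacing off the
#' wall plane).
#'
#' @param state A \code{lattice_state}.
#' @return Scalar wall shear stress (Pa).
#' @export
wall_shear_stress <- function(state) {
  s <- shear_stress_field(state)
  m <- state$mask
  nx <- state$nx; ny <- state$ny
  solid <- m == 0L
  near_wall <- matrix(FALSE, nx, ny)
  near_wall[, -1] <- near_wall[, -1] | solid[, -ny]
  near_wall[, -ny] <- near_wall[, -ny] | solid[, -1]
  near_wall[-1, ] <- near_wall[-1, ] | solid[-nx, ]
  near_wall[-nx, ] <- near_wall[-nx, ] | solid[-1, ]
  near_wall[1, ] <- near_wall[1, ] | solid[nx, ]
  near_wall[nx, ] <- near_wall[nx, ] | solid[1, ]
  near_wall <- near_wall & m == 1L
  if (!any(near_wall)) return(NA_real_)
  max(s[near_wall], na.rm = TRUE)
}

#' Cross-sectional flow rate
#'
#' Integrates \eqn{u_x} over each vertical cross-section (node sum times
#' \code{dx}) and averages over all sections; for incompressible steady
#' flow the sections agree to the compressibility error.
#'
#' @param state A \code{lattice_state}.
#' @return Flow rate per unit depth (m^2/s).  If any cross-section is fully
#'   solid the returned value is 0 with attribute \code{occluded = TRUE}.
#' @export
flow_rate <- function(state) {
  mac <- cpp_macroscopics(state$f, state$mask, state$nx, state$ny)
  ux <- matrix(mac$ux, state$nx, state$ny)
  m <- state$mask
  if (any(rowSums(m) == 0)) {
    return(structure(0, occluded = TRUE))
  }
  q_cols <- rowSums(ux * m)                   # lattice column sums
  mean(q_cols) * state$units$flow_rate
}

#' Apparent bounce-back wall offset
#'
#' Measures, on a cheap 1D force-driven Poiseuille problem, where the
#' half-way bounce-back walls of the BGK scheme effectively sit at a given
#' relaxation time and channel width: the converged velocity profile is fit
#' with a parabola and the offset of its root beyond the half-way plane is
#' returned in lattice units.  Positive values mean the channel is
#' effectively wider than its geometric node count.  Used to size lattices
#' so the effective hydraulic width equals the target diameter.
#'
#' @param tau Relaxation time (> 0.5).
#' @param nfluid Number of transverse fluid rows.
#' @return Wall offset in units of \code{dx} (per wall).
#' @export
bounceback_wall_offset <- function(tau, nfluid) {
  stopifnot(tau > 0.5, nfluid >= 8)
  nx <- 4L; ny <- as.integer(nfluid) + 2L
  mask <- matrix(1L, nx, ny); mask[, 1] <- 0L; mask[, ny] <- 0L
  f <- rep(d2q9_weights(), each = nx * ny)
  res <- cpp_lbm_run(f, mask, nx, ny, tau, 1e-8, 0, 400000L, 100L, 1e-11)
  mac <- cpp_macroscopics(res$f, mask, nx, ny)
  prof <- matrix(mac$ux, nx, ny)[1L, 2:(ny - 1L)]
  yj <- seq_len(nfluid) - 0.5
  cf <- stats::lm.fit(cbind(1, yj, yj^2), prof)$coefficients
  roots <- sort(Re(polyroot(cf)))
  ## average the two (symmetric) offsets beyond the half-way planes 0, nfluid
  ((-roots[1]) + (roots[2] - nfluid)) / 2
}
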