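# Discrete-element platelet mechanics: parameter containers and the
# reference (pure R) force/torque/update laws.  The production coupled
# loop in src/simulate.cpp mirrors these formulas; tests cross-check the
# two paths on single steps.

#' Contact and adhesion parameters
#'
#' Defaults: collision stiffness \code{k_coll = 0.005} N/m with damping
#' coefficient \code{eta_coll = 0.005} N s/m acting on the normal relative
#' velocity, adhesion stiffness \code{k_adh = 0.008} N/m (a bond stretched
#' by 10 nm pulls with 80 pN), bond rupture extension
#' \code{delta_break = 50} nm, and critical shear stress for activation
#' \code{tau_crit = 0.65} Pa.
#'
#' @param k_coll Collision spring stiffness (N/m).
#' @param eta_coll Collision damping coefficient (N s/m), applied to the
#'   normal component of the relative velocity and capped at the impulse
#'   that cancels it (overdamped contact limit).
#' @param k_adh Adhesion spring stiffness (N/m).
#' @param delta_break Bond rupture extension (m).
#' @param tau_crit Critical shear stress for activation (Pa); \code{Inf}
#'   disables shear activation.
#' @return List of class \code{contact_params}.
#' @export
contact_params <- function(k_coll = 0.005, eta_coll = 0.005,
                           k_adh = 0.008, delta_break = 50e-9,
                           tau_crit = 0.65) {
  stopifnot(k_coll > 0, eta_coll >= 0, k_adh > 0, delta_break > 0,
            tau_crit > 0)
  structure(list(k_coll = k_coll, eta_coll = eta_coll, k_adh = k_adh,
                 delta_break = delta_break, tau_crit = tau_crit),
            class = "contact_params")
}

#' Platelet mass and moment of inertia
#'
#' Platelets are rigid spheres of the fluid's density (buoyancy is
#' neglected because the densities match): \eqn{m = \rho (4/3)\pi a^3},
#' \eqn{I = (2/5) m a^2}.
#'
#' @param a Platelet radius (m).
#' @param rho_p Platelet density (kg/m^3), defaulting to plasma density.
#' @return List with \code{a}, \code{m} and \code{I}.
#' @export
platelet_inertia <- function(a, rho_p = 1030) {
  stopifnot(a > 0, rho_p > 0)
  m <- rho_p * (4 / 3) * pi * a^3
  list(a = a, m = m, I = 2 / 5 * m * a^2)
}

#' Stokes drag on a platelet
#'
#' \eqn{\vec F_d = -6\pi a \mu (\vec V_p - \vec V_f)}.
#'
#' @param V_p Platelet velocity 2-vector (m/s).
#' @param V_f Fluid velocity at the platelet centre (m/s).
#' @param a Platelet radius (m).
#' @param mu Dynamic viscosity (Pa s).
#' @return Force 2-vector (N).
#' @export
stokes_drag <- function(V_p, V_f, a, mu) {
  stopifnot(a > 0, mu > 0, length(V_p) == 2, length(V_f) == 2)
  -6 * pi * a * mu * (V_p - V_f)
}

#' Soft-sphere collision force
#'
#' Elastic repulsion proportional to the overlap depth plus a damping term
#' opposing the normal relative velocity:
#' \eqn{\vec F = k_{coll}\,\delta_n \hat n - \eta_{coll} (\vec v_{rel}
#' \cdot \hat n)\hat n}, acting on the platelet whose outward normal is
#' \eqn{\hat n} (pointing from the other body towards it).  Zero without
#' overlap; the pair receives equal and opposite forces.
#'
#' @param overlap Overlap depth (m); forces are zero for \code{overlap <= 0}.
#' @param normal Unit 2-vector from the other body towards this platelet.
#' @param v_rel Relative velocity of this platelet w.r.t. the other (m/s).
#' @param params A \code{\link{contact_params}} list.
#' @return Force 2-vector (N) on this platelet.
#' @export
collision_force <- function(overlap, normal, v_rel, params) {
  stopifnot(length(normal) == 2, length(v_rel) == 2)
  if (overlap <= 0) return(c(0, 0))
  vn <- sum(v_rel * normal)
  params$k_coll * overlap * normal - params$eta_coll * vn * normal
}

#' Adhesion spring force
#'
#' \eqn{\vec F_{adh} = k_{adh}\,\delta_n \hat n}: a bond stretched by
#' \eqn{\delta_n} beyond its rest separation pulls the platelet back
#' towards its partner along the bond normal.  Zero for unstretched bonds
#' (compression is handled by the collision force).
#'
#' @param delta_n Bond extension beyond the rest separation (m).
#' @param normal Unit 2-vector from this platelet towards its bond partner.
#' @param params A \code{\link{contact_params}} list.
#' @return Force 2-vector (N).
#' @export
adhesion_force <- function(delta_n, normal, params) {
  stopifnot(length(normal) == 2)
  if (delta_n <= 0) return(c(0, 0))
  params$k_adh * delta_n * normal
}

#' Fluid torque on a platelet
#'
#' \eqn{M_{F,z} = 8\pi\mu a^3(\omega_{xy} - \Omega_z)}: the platelet spins
#' up towards the local fluid vorticity.  \code{vorticity_factor} rescales
#' the vorticity term (set to 0.5 for the classical rotational Stokes
#' torque based on half the vorticity; default 1 as printed in the model).
#'
#' @param omega_xy Local fluid vorticity (1/s).
#' @param Omega_z Platelet angular velocity (1/s).
#' @param a Platelet radius (m).
#' @param mu Dynamic viscosity (Pa s).
#' @param vorticity_factor Factor applied to \code{omega_xy} (default 1).
#' @return Torque (N m).
#' @export
fluid_torque <- function(omega_xy, Omega_z, a, mu, vorticity_factor = 1) {
  stopifnot(a > 0, mu > 0)
  8 * pi * mu * a^3 * (vorticity_factor * omega_xy - Omega_z)
}

#' Shear- and contact-induced activation update
#'
#' A platelet activates when the shear stress sampled at its centre reaches
#' \code{params$tau_crit}, or when it touches an activated platelet
#' (surface gap <= 0).  Activation is irreversible and has no
#' time-accumulation: sub-threshold shear never activates, regardless of
#' exposure time.
#'
#' @param activated Logical vector of current activation flags.
#' @param local_shear Shear stress at each platelet centre (Pa).
#' @param contacts Two-column matrix of indices of touching pairs (may have
#'   zero rows).
#' @param params A \code{\link{contact_params}} list.
#' @return Updated logical activation vector (a superset of the input).
#' @export
update_activation <- function(activated, local_shear, contacts, params) {
  stopifnot(length(activated) == length(local_shear))
  new_act <- activated | (local_shear >= params$tau_crit)
  if (!is.null(contacts) && nrow(contacts) > 0) {
    touched <- new_act[contacts[, 1]] | new_act[contacts[, 2]]
    new_act[contacts[, 1]] <- new_act[contacts[, 1]] | touched
    new_act[contacts[, 2]] <- new_act[contacts[, 2]] | touched
  }
  new_act
}

#' One time step of platelet motion
#'
#' Advances velocity, angular velocity and position under Stokes drag,
#' fluid torque and any additional forces.  The linear drag and torque
#' relaxations (time constants \eqn{m/6\pi a\mu} and
#' \eqn{I/8\pi\mu a^3}, both comparable to or below the time step) are
#' integrated exactly (exponential integrator); the remaining forces are
#' held constant over the step; the position uses the end-of-step velocity.
#'
#' @param pos Position 2-vector (m).
#' @param vel Velocity 2-vector (m/s).
#' @param Omega Angular velocity (1/s).
#' @param V_f Fluid velocity at the centre (m/s).
#' @param omega_f Fluid vorticity at the centre (1/s).
#' @param F_other Non-drag force 2-vector (collision + adhesion) (N).
#' @param inertia A \code{\link{platelet_inertia}} list.
#' @param mu Dynamic viscosity (Pa s).
#' @param dt Time step (s).
#' @param vorticity_factor Passed to \code{\link{fluid_torque}}.
#' @return List with updated \code{pos}, \code{vel}, \code{Omega}.
#' @export
integrate_motion <- function(pos, vel, Omega, V_f, omega_f, F_other,
                             inertia, mu, dt, vorticity_factor = 1) {
  stopifnot(dt > 0)
  if (any(!is.finite(F_other)))
    stop("non-finite force in platelet motion update")
  gamma <- 6 * pi * inertia$a * mu            # translational drag coeff
  tc <- inertia$m / gamma
  v_target <- V_f + F_other / gamma           # quasi-steady velocity
  decay <- exp(-dt / tc)
  vel_new <- v_target + (vel - v_target) * decay
  gr <- 8 * pi * mu * inertia$a^3             # rotational drag coeff
  tr <- inertia$I / gr
  om_target <- vorticity_factor * omega_f
  Omega_new <- om_target + (Omega - om_target) * exp(-dt / tr)
  list(pos = pos + vel_new * dt, vel = vel_new, Omega = Omega_new)
}
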