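# Scenario orchestration: analytic references, the Poiseuille validation
# harness, pressure calibration, the full coupled thrombosis run and the
# thrombus census.

#' Exact plane-Poiseuille flow rate and wall shear stress
#'
#' \eqn{Q = H^3 \Delta p/(12\mu L)} and \eqn{\tau_w = H\Delta p/(2L)}.
#'
#' @param H Channel height (m).
#' @param L Channel length (m).
#' @param mu Dynamic viscosity (Pa s).
#' @param dp Pressure drop (Pa).
#' @return List with \code{Q} (m^2/s, per unit depth) and \code{tau_w} (Pa).
#' @examples
#' poiseuille_exact(25e-6, 314e-6, 1.236e-3, 5)  # Q ~ 1.68e-8, tau_w ~ 0.199
#' @export
poiseuille_exact <- function(H, L, mu, dp) {
  stopifnot(H > 0, L > 0, mu > 0)
  list(Q = H^3 * dp / (12 * mu * L), tau_w = H * dp / (2 * L))
}

#' Straight-channel validation against plane Poiseuille flow
#'
#' Runs the solver to steady state in a straight channel for each pressure
#' drop and tabulates flow rate and wall shear stress against the closed
#' forms, reporting percent differences.
#'
#' @param grid \code{c(nx, ny)}: axial nodes and transverse fluid rows.
#' @param dp_list Pressure drops (Pa).
#' @param D Channel height (m).
#' @param L Channel length (m).
#' @param rho Fluid density (kg/m^3).
#' @param nu Kinematic viscosity (m^2/s).
#' @param dt Time step (s).
#' @param max_steps,rtol Steady-state controls (see
#'   \code{\link{lbm_run_steady}}).
#' @return data.frame with columns \code{dp}, \code{Q_exact}, \code{Q_lbm},
#'   \code{Q_diff_pct}, \code{tw_exact}, \code{tw_lbm}, \code{tw_diff_pct},
#'   \code{steps}.
#' @export
run_validation <- function(grid = c(600, 48),
                           dp_list = c(5, 10, 15, 20, 30),
                           D = 25e-6, L = 314e-6,
                           rho = 1030, nu = 1.2e-6, dt = 2e-7,
                           max_steps = 40000L, rtol = 1e-8) {
  geom <- straight_channel(D = D, nx = grid[1], ny = grid[2], L = L,
                           dt = dt, nu = nu)
  units <- lattice_units(geom$dx, dt, rho, nu)
  mu <- rho * nu
  out <- lapply(dp_list, function(dp) {
    st <- lattice_state(geom, units)
    gx <- body_force_lattice(dp, L, units)
    st <- lbm_run_steady(st, c(gx, 0), max_steps = max_steps, rtol = rtol)
    ex <- poiseuille_exact(D, L, mu, dp)
    Q <- flow_rate(st)
    tw <- wall_shear_stress(st)
    data.frame(dp = dp,
               Q_exact = ex$Q, Q_lbm = Q,
               Q_diff_pct = 100 * abs(Q - ex$Q) / ex$Q,
               tw_exact = ex$tau_w, tw_lbm = tw,
               tw_diff_pct = 100 * abs(tw - ex$tau_w) / ex$tau_w,
               steps = attr(st, "steps"))
  })
  do.call(rbind, out)
}

#' Calibrate the pressure drop for a target particle-free flow rate
#'
#' Runs the particle-free solver to steady state and secant-iterates on
#' \eqn{Q(\Delta p)} (linear in the Stokes regime, so two runs usually
#' suffice) until the target is met within \code{tol}.
#'
#' @param geometry A \code{channel_geometry}.
#' @param target_Q Target flow rate (m^2/s, per unit depth).
#' @param rho,nu Fluid properties.
#' @param dt Time step (s).
#' @param dp0 Initial guess (Pa).
#' @param tol Relative tolerance on the achieved flow rate.
#' @param max_iter Secant iteration budget.
#' @param max_steps Per-run step budget.
#' @return The calibrated pressure drop (Pa), with attribute \code{Q}.
#' @export
calibrate_pressure_for_flow <- function(geometry, target_Q,
                                        rho = 1030, nu = 1.2e-6, dt = 2e-7,
                                        dp0 = 10, tol = 0.005,
                                        max_iter = 5, max_steps = 60000L) {
  stopifnot(target_Q > 0, dp0 > 0)
  units <- lattice_units(geometry$dx, dt, rho, nu)
  run_q <- function(dp) {
    st <- lattice_state(geometry, units)
    gx <- body_force_lattice(dp, geometry$L, units)
    st <- lbm_run_steady(st, c(gx, 0), max_steps = max_steps)
    flow_rate(st)
  }
  dp <- dp0
  Q <- run_q(dp)
  for (it in seq_len(max_iter)) {
    if (abs(Q - target_Q) / target_Q < tol)
      return(structure(dp, Q = Q, iterations = it - 1L))
    dp_new <- dp * target_Q / Q            # secant through the origin
    if (!is.finite(dp_new) || dp_new <= 0)
      stop("pressure calibration diverged (Q = ", Q, " at dp = ", dp, ")")
    dp <- dp_new
    Q <- run_q(dp)
  }
  if (abs(Q - target_Q) / target_Q >= tol)
    stop("pressure calibration did not converge within ", max_iter,
         " iterations")
  structure(dp, Q = Q, iterations = max_iter)
}

#' Simulation configuration
#'
#' Assembles and validates the configuration of a coupled thrombosis run.
#' All arguments are optional; defaults reproduce the baseline tortuous
#' arteriole study conditions (D = 25 um, L = 314 um, plasma-like fluid,
#' normal 2.4 um platelets at physiological concentration).
#'
#' @param geometry Either a \code{channel_geometry} or a list with fields
#'   \code{TI} (or \code{A} and \code{lambda}), \code{D}, \code{L},
#'   \code{nx}, and optionally \code{mode} ("fixed-length"/"equal-arc") and
#'   \code{wall_rule}.
#' @param fluid List with \code{rho} (kg/m^3) and \code{nu} (m^2/s).
#' @param drive List with exactly one of \code{dp} (Pa) or \code{target_Q}
#'   (m^2/s): constant pressure drop, or pressure calibrated to an initial
#'   flow rate.
#' @param platelets List: \code{diameter} (m), \code{concentration}
#'   (platelets/m^3), \code{n_init}, \code{inject}, \code{contact} (a
#'   \code{\link{contact_params}}), \code{vorticity_factor},
#'   \code{b_depth} (m; out-of-plane depth converting point forces to
#'   per-depth densities, default = platelet diameter), \code{b_inject}
#'   (m; depth converting the volume concentration to a 2D arrival rate,
#'   default = channel diameter), \code{rho_p}.
#' @param numerics List: \code{dt} (s), \code{duration} (s) or
#'   \code{steps}, \code{seed}.
#' @param output List: \code{diag_every}, \code{snapshot_every} (steps; 0
#'   disables the platelet log), \code{occl_frac}, \code{occl_sustain}
#'   (steps), \code{max_platelets}.
#' @return Validated list of class \code{sim_config}.
#' @export
sim_config <- function(geometry = list(), fluid = list(), drive = list(),
                       platelets = list(), numerics = list(),
                       output = list()) {
  fl <- utils::modifyList(list(rho = 1030, nu = 1.2e-6), fluid)
  dr <- utils::modifyList(list(dp = NULL, target_Q = NULL), drive)
  pl <- utils::modifyList(
    list(diameter = 2.4e-6, concentration = 3e14, n_init = 50L,
         inject = TRUE, contact = contact_params(), vorticity_factor = 1,
         b_depth = NULL, b_inject = NULL, rho_p = 1030), platelets)
  nm <- utils::modifyList(
    list(dt = 2e-7, duration = NULL, steps = NULL, seed = 1L,
         force_relax = NULL), numerics)
  if (!is.null(nm$force_relax))
    stopifnot(nm$force_relax > 0, nm$force_relax <= 1)
  ou <- utils::modifyList(
    list(diag_every = 500L, snapshot_every = 0L, occl_frac = 0.05,
         occl_sustain = 10000L, max_platelets = 4096L), output)

  if (!inherits(geometry, "channel_geometry")) {
    ge <- utils::modifyList(
      list(TI = 0.16, A = NULL, lambda = NULL, D = 25e-6, L = 314e-6,
           nx = 320L, mode = "fixed-length", wall_rule = "normal"),
      geometry)
    if (is.null(ge$A) || is.null(ge$lambda)) {
      pr <- ti_preset(ge$TI, L = ge$L, mode = ge$mode)
      ge$A <- pr$A; ge$lambda <- pr$lambda
    }
    geometry <- ge
  }
  if (is.null(dr$dp) == is.null(dr$target_Q))
    stop("exactly one of drive$dp or drive$target_Q must be set")
  stopifnot(fl$rho > 0, fl$nu > 0, pl$diameter > 0, pl$concentration >= 0,
            nm$dt > 0)
  if (is.null(pl$b_depth)) pl$b_depth <- pl$diameter
  if (is.null(nm$steps)) {
    if (is.null(nm$duration)) nm$duration <- 1.0
    nm$steps <- as.integer(round(nm$duration / nm$dt))
  }
  nm$duration <- nm$steps * nm$dt
  structure(list(geometry = geometry, fluid = fl, drive = dr,
                 platelets = pl, numerics = nm, output = ou),
            class = "sim_config")
}

## resolve a sim_config geometry spec into a wall-shift-corrected lattice
resolve_geometry <- function(config) {
  ge <- config$geometry
  if (inherits(ge, "channel_geometry")) return(ge)
  dx <- 2 * ge$lambda / ge$nx
  tau <- lattice_units(dx, config$numerics$dt, config$fluid$rho,
                       config$fluid$nu)$tau
  delta <- bounceback_wall_offset(tau, max(round(ge$D / dx), 8))
  build_channel(ge$A, ge$lambda, ge$D, ge$nx,
                wall_rule = ge$wall_rule, wall_shift = delta)
}

## rejection-sample n platelet centres in the wall-safe fluid region
seed_platelets <- function(geometry, n, a, state) {
  mac <- lbm_macroscopics(state)
  keep_x <- numeric(0); keep_y <- numeric(0)
  guard <- 0
  while (length(keep_x) < n && guard < 200) {
    guard <- guard + 1
    m <- 4 * n
    xs <- stats::runif(m, 0, geometry$nx * geometry$dx)
    ys <- stats::runif(m, min(geometry$y), max(geometry$y))
    ok <- vapply(seq_len(m), function(k) {
      st <- bilinear_stencil(geometry, c(xs[k], ys[k]))
      ph <- sum(st$w * geometry$phi[cbind(st$i, st$j)])
      ph <= geometry$half_width - a
    }, logical(1))
    xs <- xs[ok]; ys <- ys[ok]
    for (k in seq_along(xs)) {
      if (length(keep_x) >= n) break
      if (length(keep_x) > 0 &&
          any((keep_x - xs[k])^2 + (keep_y - ys[k])^2 < (2 * a)^2)) next
      keep_x <- c(keep_x, xs[k]); keep_y <- c(keep_y, ys[k])
    }
  }
  if (length(keep_x) < n)
    stop("could not place ", n, " non-overlapping platelets")
  vx <- vapply(seq_len(n), function(k)
    interpolate_field(mac$ux, geometry, c(keep_x[k], keep_y[k])), 0)
  vy <- vapply(seq_len(n), function(k)
    interpolate_field(mac$uy, geometry, c(keep_x[k], keep_y[k])), 0)
  cbind(x = keep_x, y = keep_y, vx = vx, vy = vy,
        omega = 0, activated = 0)
}

#' Run a coupled thrombosis simulation
#'
#' Full pipeline: resolve the geometry (with bounce-back wall-offset
#' correction), converge the particle-free flow, seed the initial
#' platelets, then advance the coupled LBM-DEM loop (collide/stream with
#' body + platelet reaction forces, field sampling at platelets, contact
#' and adhesion forces, shear/contact activation, bond bookkeeping, motion
#' integration, inlet injection) for the configured duration.
#'
#' @param config A \code{\link{sim_config}}.
#' @param progress Unused placeholder for API stability.
#' @return List of class \code{occlusim_run}: \code{diagnostics}
#'   (data.frame time series), \code{platelets}, \code{bonds},
#'   \code{platelet_log} (data.frames), \code{census} (final
#'   \code{\link{thrombus_census}}), \code{occlusion_time} (s or NA),
#'   \code{q0} (initial particle-free flow rate), \code{state} (final
#'   \code{lattice_state}), \code{geometry}, \code{config}, \code{checks}
#'   (invariant monitors).
#' @export
run_simulation <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$numerics$seed)
  geom <- resolve_geometry(config)
  units <- lattice_units(geom$dx, config$numerics$dt, config$fluid$rho,
                         config$fluid$nu)
  pl <- config$platelets
  a <- pl$diameter / 2
  inert <- platelet_inertia(a, pl$rho_p)
  cp <- pl$contact

  ## contact-spring resolution check; integer substepping if violated
  t_contact <- 2 * pi * sqrt((inert$m / 2) / cp$k_coll)
  n_sub <- max(1L, as.integer(ceiling(config$numerics$dt / (t_contact / 6))))

  ## force under-relaxation: default to the inverse of the dimensionless
  ## explicit-exchange gain gamma_lat = 6 pi a mu dt / (rho b dx^2), so
  ## the per-step drag feedback stays below unity at any (dt, dx)
  force_relax <- config$numerics$force_relax
  if (is.null(force_relax)) {
    gamma_lat <- 6 * pi * a * units$mu * config$numerics$dt /
      (config$fluid$rho * pl$b_depth * geom$dx^2)
    force_relax <- min(1, 1 / gamma_lat)
  }

  ## injection depth: converts the volume concentration to a 2D arrival
  ## rate; defaults to the channel diameter (the force-density depth
  ## b_depth stays at the platelet's own span)
  b_inject <- pl$b_inject
  if (is.null(b_inject)) b_inject <- geom$D

  ## drive
  dp <- config$drive$dp
  if (is.null(dp))
    dp <- as.numeric(calibrate_pressure_for_flow(
      geom, config$drive$target_Q, rho = config$fluid$rho,
      nu = config$fluid$nu, dt = config$numerics$dt))
  gx <- body_force_lattice(dp, geom$L, units)

  ## particle-free steady state
  st <- lattice_state(geom, units)
  st <- lbm_run_steady(st, c(gx, 0))
  q0 <- as.numeric(flow_rate(st))

  init <- seed_platelets(geom, pl$n_init, a, st)

  ## wall-safe injection band at the inlet
  yc0 <- channel_center_y(0, geom$A, if (is.na(geom$lambda)) 1 else
    geom$lambda, geom$D)
  if (geom$A == 0) yc0 <- geom$half_width
  band <- geom$half_width - a
  par <- list(a = a, m = inert$m, I = inert$I,
              k_coll = cp$k_coll, eta_coll = cp$eta_coll,
              k_adh = cp$k_adh, delta_break = cp$delta_break,
              tau_crit = cp$tau_crit,
              vort_factor = pl$vorticity_factor, b_depth = pl$b_depth)
  res <- cpp_simulate(
    st$f, geom$mask, geom$nx, geom$ny, geom$margin,
    as.numeric(geom$phi), geom$half_width,
    geom$dx, config$numerics$dt, units$tau, config$fluid$rho, units$mu,
    gx, init, par,
    pl$concentration * b_inject, isTRUE(pl$inject),
    yc0 - band, yc0 + band, geom$nx * geom$dx,
    1.25 * max(a, geom$dx), force_relax,
    as.integer(config$numerics$steps), n_sub,
    as.integer(config$output$diag_every),
    as.integer(config$output$snapshot_every),
    q0, config$output$occl_frac, as.integer(config$output$occl_sustain),
    as.integer(config$output$max_platelets))
  if (isTRUE(res$aborted))
    stop("simulation aborted at step ", res$steps_run, ": ",
         res$abort_reason)

  diag <- as.data.frame(res$diagnostics)
  names(diag) <- c("time", "flow_rate", "wall_shear_max", "n_platelets",
                   "n_activated", "n_activated_total", "n_bonds",
                   "largest_thrombus", "n_thrombi", "momentum_exchange")
  platelets <- as.data.frame(res$platelets)
  bonds <- as.data.frame(res$bonds)
  plog <- as.data.frame(res$platelet_log)
  st$f <- res$f
  structure(list(
    diagnostics = diag, platelets = platelets, bonds = bonds,
    platelet_log = plog,
    census = thrombus_census(bonds, platelets),
    occlusion_time = res$occlusion_time, q0 = q0, dp = dp,
    state = st, geometry = geom, config = config, n_sub = n_sub,
    force_relax = force_relax,
    checks = res$checks
  ), class = "occlusim_run")
}

#' @export
print.occlusim_run <- function(x, ...) {
  d <- x$diagnostics
  cat("Coupled LBM-DEM thrombosis run\n")
  cat(sprintf("  duration %.4g s (%d steps), dp = %.4g Pa, Q0 = %.4g m^2/s\n",
              x$config$numerics$duration, x$config$numerics$steps, x$dp,
              x$q0))
  n <- nrow(d)
  cat(sprintf("  final: Q = %.4g m^2/s, %d platelets (%d activated), %d bonds\n",
              d$flow_rate[n], d$n_platelets[n], d$n_activated[n],
              d$n_bonds[n]))
  if (!is.na(x$occlusion_time))
    cat(sprintf("  occlusion at t = %.4g s\n", x$occlusion_time))
  invisible(x)
}

#' Thrombus census from the bond graph
#'
#' Thrombi are the connected components of the adhesion-bond graph
#' (platelet-platelet bonds join platelets; a wall bond marks its
#' component as wall-attached).  Platelets without bonds are not part of
#' any thrombus.
#'
#' @param bonds data.frame with columns \code{id_i}, \code{id_j} (-1 for a
#'   wall anchor), as returned by \code{\link{run_simulation}}.
#' @param platelets data.frame with columns \code{id}, \code{x}, \code{y}.
#' @return data.frame with one row per thrombus: \code{thrombus},
#'   \code{size}, \code{wall_attached}, \code{xmin}, \code{xmax},
#'   \code{ymin}, \code{ymax}; attribute \code{members} maps platelet ids
#'   to thrombus index.
#' @export
thrombus_census <- function(bonds, platelets) {
  empty <- data.frame(thrombus = integer(0), size = integer(0),
                      wall_attached = logical(0),
                      xmin = numeric(0), xmax = numeric(0),
                      ymin = numeric(0), ymax = numeric(0))
  if (is.null(bonds) || nrow(bonds) == 0) return(empty)
  ids <- sort(unique(c(bonds$id_i, bonds$id_j[bonds$id_j >= 0])))
  ids <- ids[ids %in% platelets$id]
  if (length(ids) == 0) return(empty)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  pair <- bonds[bonds$id_j >= 0 &
                  bonds$id_i %in% ids & bonds$id_j %in% ids, , drop = FALSE]
  if (nrow(pair) > 0) {
    eidx <- rbind(match(pair$id_i, ids), match(pair$id_j, ids))
    g <- igraph::add_edges(g, as.vector(eidx))
  }
  comp <- igraph::components(g)
  wall_ids <- bonds$id_i[bonds$id_j < 0]
  rows <- lapply(seq_len(comp$no), function(cid) {
    mem <- ids[comp$membership == cid]
    px <- platelets$x[match(mem, platelets$id)]
    py <- platelets$y[match(mem, platelets$id)]
    data.frame(thrombus = cid, size = length(mem),
               wall_attached = any(mem %in% wall_ids),
               xmin = min(px), xmax = max(px),
               ymin = min(py), ymax = max(py))
  })
  out <- do.call(rbind, rows)
  membership <- stats::setNames(comp$membership, ids)
  attr(out, "members") <- membership
  out
}
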