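# D2Q9 BGK solver: equilibrium, relaxation-time mapping, conservation,
# Poiseuille accuracy, stress extraction and flow-rate diagnostics.

test_that("equilibrium populations reproduce the weights and moments", {
  w <- lbm_equilibrium(1, c(0, 0))
  expect_equal(w, c(4/9, 1/9, 1/36, 1/9, 1/36, 1/9, 1/36, 1/9, 1/36))
  expect_equal(sum(w), 1)
  dirs <- d2q9_dirs()
  set.seed(42)
  for (k in 1:20) {
    rho <- runif(1, 0.8, 1.2)
    u <- runif(2, -0.1, 0.1)
    fe <- lbm_equilibrium(rho, u)
    expect_equal(sum(fe), rho, tolerance = 1e-12)
    expect_equal(sum(fe * dirs$cx), rho * u[1], tolerance = 1e-12)
    expect_equal(sum(fe * dirs$cy), rho * u[2], tolerance = 1e-12)
  }
  expect_warning(lbm_equilibrium(1, c(0.35, 0)), "0.3")
})

test_that("relaxation time maps viscosity per tau = (6 nu + 1)/2", {
  expect_equal(tau_from_viscosity(1 / 6), 1)
  expect_equal(tau_from_viscosity(1e-9), 0.5, tolerance = 1e-7)
  nu_lat <- 1.2e-6 * 2e-7 / (0.523e-6)^2
  expect_equal(tau_from_viscosity(nu_lat), 3.132, tolerance = 1e-3)
  expect_error(tau_from_viscosity(0))
})

test_that("uniform rest equilibrium is a fixed point of collide-stream", {
  geom <- straight_channel(D = 25e-6, nx = 12, ny = 10)
  units <- lattice_units(geom$dx, 2e-7, plasma$rho, plasma$nu)
  st <- lattice_state(geom, units)
  st2 <- lbm_step(st, c(0, 0))
  expect_equal(st2$f, st$f, tolerance = 1e-15)
})

test_that("forcing adds exactly the prescribed momentum on a periodic torus", {
  nx <- 10L; ny <- 8L
  mask <- matrix(1L, nx, ny)                       # no walls at all
  f <- rep(c(4/9, 1/9, 1/36, 1/9, 1/36, 1/9, 1/36, 1/9, 1/36),
           each = nx * ny)
  Fx <- 1e-5
  dirs <- d2q9_dirs()
  mom <- function(fv) {
    m <- matrix(fv, nx * ny, 9)
    sum(m %*% dirs$cx)
  }
  f1 <- occlusim:::cpp_lbm_step(f, as.integer(mask), nx, ny, 0.9, Fx, 0)$f
  f2 <- occlusim:::cpp_lbm_step(f1, as.integer(mask), nx, ny, 0.9, Fx, 0)$f
  expect_equal(mom(f1) - mom(f), nx * ny * Fx, tolerance = 1e-9)
  expect_equal(mom(f2) - mom(f1), nx * ny * Fx, tolerance = 1e-9)
})

test_that("mass is conserved to round-off with walls and periodic wrap", {
  pr <- ti_preset(0.16)
  geom <- build_channel(pr$A, pr$lambda, 25e-6, nx = 96)
  units <- lattice_units(geom$dx, 2e-6, plasma$rho, plasma$nu)
  st <- lattice_state(geom, units)
  gx <- body_force_lattice(20, geom$L, units)
  mass0 <- sum(matrix(st$f, ncol = 9)[geom$mask == 1L, ])
  for (k in 1:200) st <- lbm_step(st, c(gx, 0))
  mass <- sum(matrix(st$f, ncol = 9)[geom$mask == 1L, ])
  expect_lt(abs(mass - mass0) / mass0, 1e-12)
})

test_that("steady Poiseuille: parabolic profile, flow rate, linearity", {
  ## 48 transverse rows; narrow axial extent since the flow is x-invariant
  geom <- straight_channel(D = 25e-6, nx = 8, ny = 48, L = 314e-6,
                           dt = 2e-7, nu = plasma$nu)
  units <- lattice_units(geom$dx, 2e-7, plasma$rho, plasma$nu)
  gx10 <- body_force_lattice(10, 314e-6, units)
  st <- lattice_state(geom, units)
  st <- lbm_run_steady(st, c(gx10, 0))
  mac <- lbm_macroscopics(st)
  prof <- mac$ux[1, geom$mask[1, ] == 1L]
  y <- geom$y[geom$mask[1, ] == 1L]
  H <- 25e-6
  mu <- plasma$mu
  exact <- 10 / (2 * mu * 314e-6) * y * (H - y)
  expect_lt(sqrt(mean((prof - exact)^2)) / max(exact), 0.02)  # L2 < 2%
  ex <- poiseuille_exact(H, 314e-6, mu, 10)
  Q10 <- flow_rate(st)
  expect_equal(Q10, ex$Q, tolerance = 0.01)
  ## stress extraction agrees with mu |du/dy| from the measured profile
  s <- shear_stress_field(st)[1, geom$mask[1, ] == 1L]
  n <- length(prof)
  dudy <- (prof[3:n] - prof[1:(n - 2)]) / (2 * geom$dx)
  expect_equal(s[2:(n - 1)], mu * abs(dudy), tolerance = 0.01)
  ## interior stress is linear in y (max-shear scalar of plane Poiseuille)
  tw <- poiseuille_exact(H, 314e-6, mu, 10)$tau_w
  expect_equal(s[2:(n - 1)], tw * abs(1 - 2 * y[2:(n - 1)] / H),
               tolerance = 0.03)
  ## Stokes linearity: doubling dp doubles Q
  st5 <- lbm_run_steady(lattice_state(geom, units),
                        c(body_force_lattice(5, 314e-6, units), 0))
  expect_equal(Q10 / flow_rate(st5), 2, tolerance = 0.01)
  ## Galilean zero: no drive, no flow
  st0 <- lbm_run_steady(lattice_state(geom, units), c(0, 0),
                        max_steps = 2000L, require_convergence = FALSE)
  expect_lt(abs(flow_rate(st0)), 1e-20)
})

test_that("uniform advection has zero shear stress", {
  nx <- 12L; ny <- 8L
  mask <- matrix(1L, nx, ny)
  fe <- lbm_equilibrium(1, c(0.02, 0.01))
  f <- rep(fe, each = nx * ny)
  for (k in 1:20)
    f <- occlusim:::cpp_lbm_step(f, as.integer(mask), nx, ny, 0.8, 0, 0)$f
  s <- occlusim:::cpp_shear_stress(f, as.integer(mask), nx, ny, 0.8)
  expect_lt(max(abs(s)), 1e-14)
})

test_that("flow rate is zero at rest and flags occluded sections", {
  geom <- straight_channel(D = 25e-6, nx = 12, ny = 10)
  units <- lattice_units(geom$dx, 2e-7, plasma$rho, plasma$nu)
  st <- lattice_state(geom, units)
  expect_equal(as.numeric(flow_rate(st)), 0)
  geom$mask[5, ] <- 0L                             # wall across the channel
  st2 <- lattice_state(geom, units)
  st2$mask <- geom$mask
  q <- flow_rate(st2)
  expect_equal(as.numeric(q), 0)
  expect_true(isTRUE(attr(q, "occluded")))
})

test_that("gross over-forcing raises the instability error", {
  geom <- straight_channel(D = 25e-6, nx = 12, ny = 10)
  units <- lattice_units(geom$dx, 2e-7, plasma$rho, plasma$nu)
  st <- lattice_state(geom, units)
  expect_error(lbm_step(st, c(0.5, 0)), "instability")
})
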