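# Platelet mechanics: drag, contact, adhesion, torque, activation rules
# and the motion integrator.

test_that("Stokes drag law: magnitude, direction, zero slip", {
  mu <- plasma$mu
  expect_equal(stokes_drag(c(1e-3, 2e-3), c(1e-3, 2e-3), 1.2e-6, mu),
               c(0, 0))
  F <- stokes_drag(c(1e-4, 0), c(0, 0), 1.2e-6, mu)
  expect_equal(sqrt(sum(F^2)), 2.80e-12, tolerance = 0.005)
  set.seed(7)
  for (k in 1:10) {
    vp <- runif(2, -1, 1); vf <- runif(2, -1, 1)
    F <- stokes_drag(vp, vf, 1.2e-6, mu)
    expect_lt(sum(F * (vp - vf)), 0)               # antiparallel to slip
    expect_equal(F / sqrt(sum(F^2)),
                 -(vp - vf) / sqrt(sum((vp - vf)^2)), tolerance = 1e-10)
  }
})

test_that("soft-sphere collision: zero without overlap, k*delta elastic part", {
  p <- contact_params()
  expect_equal(collision_force(0, c(1, 0), c(0, 0), p), c(0, 0))
  expect_equal(collision_force(-1e-9, c(1, 0), c(1, 1), p), c(0, 0))
  F <- collision_force(1e-8, c(1, 0), c(0, 0), p)
  expect_equal(F, c(0.005 * 1e-8, 0))              # 5e-11 N, repulsive
  ## damping opposes the normal relative velocity
  Fd <- collision_force(1e-8, c(1, 0), c(-1e-3, 5e-4), p)
  expect_gt(Fd[1], F[1])                           # approach -> extra push
  expect_equal(Fd[2], 0)                           # normal-only damping
})

test_that("head-on pair collision conserves momentum, dissipates energy", {
  ## two equal platelets integrated with the reference R laws at fine dt
  mu <- plasma$mu
  inert <- platelet_inertia(1.2e-6)
  p <- contact_params(eta_coll = 0.2 * 2 * sqrt(0.005 * inert$m / 2))
  dt <- 2e-9
  x1 <- c(-1.205e-6, 0); x2 <- c(1.205e-6, 0)
  v1 <- c(1e-3, 0); v2 <- c(-1e-3, 0)
  mom0 <- inert$m * (v1 + v2)
  ke <- function(v1, v2) 0.5 * inert$m * (sum(v1^2) + sum(v2^2))
  ke_prev <- ke(v1, v2)
  for (k in 1:8000) {
    d <- x1 - x2
    dist <- sqrt(sum(d^2))
    ov <- 2 * 1.2e-6 - dist
    n12 <- d / dist
    F1 <- collision_force(ov, n12, v1 - v2, p)
    ## vacuum test: no drag, so pass V_f = v and zero out the drag part
    s1 <- integrate_motion(x1, v1, 0, v1, 0, F1, inert, mu, dt)
    s2 <- integrate_motion(x2, v2, 0, v2, 0, -F1, inert, mu, dt)
    x1 <- s1$pos; v1 <- s1$vel; x2 <- s2$pos; v2 <- s2$vel
  }
  expect_equal(inert$m * (v1 + v2), mom0, tolerance = 1e-12)
  expect_lt(ke(v1, v2), ke_prev * (1 + 1e-9))      # non-increasing
  expect_gt(sqrt(sum((x1 - x2)^2)), 2 * 1.2e-6)    # separated again
})

test_that("adhesion spring: 10 nm extension pulls with ~80 pN", {
  p <- contact_params()
  F <- adhesion_force(10e-9, c(0, 1), p)
  expect_equal(F, c(0, 8e-11))                     # order 1e2 pN
  expect_equal(adhesion_force(0, c(0, 1), p), c(0, 0))
  expect_equal(adhesion_force(-5e-9, c(0, 1), p), c(0, 0))
})

test_that("fluid torque: magnitude and spin-up to the local vorticity", {
  mu <- plasma$mu
  expect_equal(fluid_torque(100, 100, 1.2e-6, mu), 0)
  expect_equal(fluid_torque(100, 0, 1.2e-6, mu), 5.37e-18,
               tolerance = 0.002)
  expect_equal(fluid_torque(100, 0, 1.2e-6, mu, vorticity_factor = 0.5),
               fluid_torque(50, 0, 1.2e-6, mu))
  ## free platelet in steady shear: Omega approaches omega exponentially
  inert <- platelet_inertia(1.2e-6)
  omega_f <- 500
  Om <- 0
  dt <- 2e-7
  tr <- inert$I / (8 * pi * mu * 1.2e-6^3)
  for (k in 1:10) {
    s <- integrate_motion(c(0, 0), c(0, 0), Om, c(0, 0), omega_f,
                          c(0, 0), inert, mu, dt)
    Om <- s$Omega
    expect_equal(Om, omega_f * (1 - exp(-k * dt / tr)), tolerance = 1e-9)
  }
  expect_equal(Om, omega_f, tolerance = 0.1)       # nearly co-rotating
})

test_that("activation: threshold, no time accumulation, contact spreading", {
  p <- contact_params()                            # tau_crit = 0.65 Pa
  act <- update_activation(c(FALSE, FALSE), c(0.70, 0.30), NULL, p)
  expect_equal(act, c(TRUE, FALSE))
  ## sub-threshold shear never activates, however long it lasts
  act <- c(FALSE)
  for (k in 1:5000) act <- update_activation(act, 0.60, NULL, p)
  expect_false(act)
  ## touching an activated platelet activates immediately
  act <- update_activation(c(TRUE, FALSE), c(0, 0),
                           matrix(c(1L, 2L), 1), p)
  expect_equal(act, c(TRUE, TRUE))
  ## irreversible: an activated platelet stays activated at zero shear
  expect_true(update_activation(TRUE, 0, NULL, p))
})

test_that("motion integrator: fixed point and exact drag relaxation", {
  mu <- plasma$mu
  inert <- platelet_inertia(1.2e-6)
  s <- integrate_motion(c(1e-5, 1e-5), c(2e-3, 0), 10, c(2e-3, 0), 10,
                        c(0, 0), inert, mu, 2e-7)
  expect_equal(s$vel, c(2e-3, 0))
  expect_equal(s$Omega, 10)
  ## drag-only relaxation: time constant m/(6 pi a mu) ~ 0.33 us,
  ## integrator matches the analytic exponential to < 1% at dt = 0.2 us
  tc <- inert$m / (6 * pi * 1.2e-6 * mu)
  expect_equal(tc, 0.33e-6, tolerance = 0.02)
  v <- c(1e-3, 0)
  for (k in 1:6) {
    s <- integrate_motion(c(0, 0), v, 0, c(0, 0), 0, c(0, 0),
                          inert, mu, 2e-7)
    v <- s$vel
    expect_equal(v[1], 1e-3 * exp(-k * 2e-7 / tc), tolerance = 0.01)
  }
  expect_error(integrate_motion(c(0, 0), c(0, 0), 0, c(0, 0), 0,
                                c(NaN, 0), inert, mu, 2e-7),
               "non-finite")
})

test_that("platelet inertia matches the rigid-sphere formulas", {
  inert <- platelet_inertia(1.2e-6, 1030)
  expect_equal(inert$m, 1030 * 4 / 3 * pi * (1.2e-6)^3)
  expect_equal(inert$I, 0.4 * inert$m * (1.2e-6)^2)
})
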