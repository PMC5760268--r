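# Fluid-particle exchange: interpolation, force spreading, and the
# momentum-exchange identity through the solver.

make_geom <- function() straight_channel(D = 25e-6, nx = 16, ny = 12)

test_that("bilinear interpolation: node values, uniform and linear fields", {
  geom <- make_geom()
  fld <- matrix(runif(geom$nx * geom$ny), geom$nx, geom$ny)
  ## exactly on a node
  i <- 5L; j <- 6L
  expect_equal(interpolate_field(fld, geom, c(geom$x[i], geom$y[j])),
               fld[i, j])
  ## uniform field is exact anywhere
  u <- matrix(3.7, geom$nx, geom$ny)
  expect_equal(interpolate_field(u, geom, c(11e-6, 13e-6)), 3.7)
  ## linear field u = c*y recovered exactly away from solid rows
  lin <- matrix(rep(2e3 * geom$y, each = geom$nx), geom$nx, geom$ny)
  for (pos in list(c(5e-6, 9e-6), c(17.3e-6, 12.2e-6), c(30e-6, 18e-6)))
    expect_equal(interpolate_field(lin, geom, pos), 2e3 * pos[2],
                 tolerance = 1e-10)
  ## a position deep inside the wall has no fluid support
  expect_error(interpolate_field(fld, geom, c(10e-6, -4e-6)), "solid")
})

test_that("force spreading conserves the total reaction force", {
  geom <- make_geom()
  units <- lattice_units(geom$dx, 2e-7, plasma$rho, plasma$nu)
  b <- 2.4e-6
  conv <- units$force_density / (geom$dx^2 * b)
  ## no platelets
  f0 <- spread_reaction_force(matrix(numeric(0), 0, 2),
                              matrix(numeric(0), 0, 2), geom, units, b)
  expect_equal(sum(f0$x) + sum(f0$y), 0)
  ## a platelet exactly at a node puts its whole force on that node
  f1 <- spread_reaction_force(matrix(c(geom$x[4], geom$y[5]), 1),
                              matrix(c(3e-12, -1e-12), 1), geom, units, b)
  expect_equal(f1$x[4, 5], 3e-12 * conv)
  expect_equal(sum(f1$x != 0), 1)
  ## random interior configurations: sum of spread = sum of reactions
  set.seed(11)
  n <- 25
  pos <- cbind(runif(n, 2e-6, 38e-6), runif(n, 3e-6, 22e-6))
  forces <- matrix(rnorm(2 * n, sd = 1e-12), n, 2)
  fs <- spread_reaction_force(pos, forces, geom, units, b)
  expect_equal(sum(fs$x) / conv, sum(forces[, 1]), tolerance = 1e-10)
  expect_equal(sum(fs$y) / conv, sum(forces[, 2]), tolerance = 1e-10)
})

test_that("particle forcing changes fluid momentum by exactly the spread sum", {
  ## fully periodic torus, so no wall sink of momentum
  nx <- 12L; ny <- 10L
  mask <- matrix(1L, nx, ny)
  f <- rep(lbm_equilibrium(1, c(0, 0)), each = nx * ny)
  pf <- matrix(0, nx, ny)
  pf[3, 4] <- 2e-6; pf[8, 7] <- -0.5e-6
  dirs <- d2q9_dirs()
  mom <- function(fv) sum(matrix(fv, nx * ny, 9) %*% dirs$cx)
  f1 <- occlusim:::cpp_lbm_step(f, as.integer(mask), nx, ny, 1.1,
                                as.numeric(pf), 0)$f
  ## identity up to the cancellation error of summing ~1e3 O(1) populations
  expect_equal(mom(f1) - mom(f), sum(pf), tolerance = 1e-6)
})

test_that("a free platelet in Poiseuille flow rides its streamline", {
  cfg <- tiny_coupled_config(duration = 1000 * 4e-7, n_init = 1L,
                             tau_crit = Inf, dp = 16,
                             snapshot_every = 100L)
  run <- run_simulation(cfg)
  pl <- run$platelets
  expect_equal(nrow(pl), 1L)
  mac <- lbm_macroscopics(run$state)
  uf <- interpolate_field(mac$ux, run$geometry, c(pl$x, pl$y))
  ## terminal slip: the platelet moves with the footprint-averaged local
  ## fluid velocity (within ~1% of the centre value for a ~1.5 um kernel)
  expect_lt(abs(pl$vx - uf) / uf, 0.015)
  expect_lt(abs(pl$vy), 0.02 * uf)
  ## y drift stays below a platelet radius over the run
  log <- run$platelet_log
  expect_lt(max(log$y) - min(log$y), 1.2e-6)
})

test_that("an adhering platelet population reduces the flow rate", {
  ## tau_crit = 0: everything activates and sticks; drag blockage must
  ## lower Q below the particle-free steady value at the same dp
  cfg <- tiny_coupled_config(duration = 4000 * 4e-7, n_init = 30L,
                             tau_crit = 1e-9, dp = 16)
  run <- run_simulation(cfg)
  d <- run$diagnostics
  expect_gt(tail(d$n_bonds, 1), 0)
  expect_lt(tail(d$flow_rate, 1), 0.995 * run$q0)
  ## and the momentum-exchange identity held throughout
  expect_lt(run$checks$mex_resid_rel, 1e-10)
})
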