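# Driver-level operations: analytic references, calibration, census,
# configuration validation, determinism and output writers.

test_that("plane-Poiseuille closed forms reproduce the reference table", {
  mu <- plasma$mu
  ex <- poiseuille_exact(25e-6, 314e-6, mu, 5)
  expect_equal(ex$Q, 1.68e-8, tolerance = 0.005)
  expect_equal(ex$tau_w, 0.199, tolerance = 0.005)
  expect_equal(poiseuille_exact(25e-6, 314e-6, mu, 30)$tau_w, 1.194,
               tolerance = 0.005)
  ex0 <- poiseuille_exact(25e-6, 314e-6, mu, 0)
  expect_equal(ex0$Q, 0)
  expect_equal(ex0$tau_w, 0)
})

test_that("pressure calibration hits a target flow and is linear", {
  geom <- straight_channel(D = 25e-6, nx = 8, ny = 24, L = 314e-6,
                           dt = 2e-7, nu = plasma$nu)
  target <- poiseuille_exact(25e-6, 314e-6, plasma$mu, 20)$Q
  dp <- calibrate_pressure_for_flow(geom, target, dt = 2e-7)
  expect_equal(as.numeric(dp), 20, tolerance = 0.02)
  expect_equal(attr(dp, "Q"), target, tolerance = 0.005)
  dp2 <- calibrate_pressure_for_flow(geom, 2 * target, dt = 2e-7)
  expect_equal(as.numeric(dp2) / as.numeric(dp), 2, tolerance = 0.01)
  expect_error(calibrate_pressure_for_flow(geom, -1e-8), "target_Q")
})

test_that("thrombus census equals an exhaustive DFS on random bond graphs", {
  empty <- thrombus_census(data.frame(id_i = numeric(0),
                                      id_j = numeric(0)),
                           data.frame(id = 1, x = 0, y = 0))
  expect_equal(nrow(empty), 0L)
  two <- thrombus_census(
    data.frame(id_i = 4, id_j = 9, anchor_x = 0, anchor_y = 0,
               rest = 0, t_form = 0),
    data.frame(id = c(4, 9), x = c(0, 1e-6), y = c(0, 0)))
  expect_equal(two$size, 2L)
  expect_false(two$wall_attached)
  set.seed(99)
  for (trial in 1:8) {
    n <- sample(5:25, 1)
    ids <- sample(0:99, n)
    ne <- sample(1:20, 1)
    e <- cbind(sample(ids, ne, replace = TRUE),
               sample(ids, ne, replace = TRUE))
    e <- e[e[, 1] != e[, 2], , drop = FALSE]
    if (nrow(e) == 0) next
    nw <- sample(0:3, 1)                           # some wall anchors
    bonds <- data.frame(
      id_i = c(e[, 1], sample(ids, nw)),
      id_j = c(e[, 2], rep(-1, nw)),
      anchor_x = 0, anchor_y = 0, rest = 0, t_form = 0)
    platelets <- data.frame(id = ids, x = runif(n), y = runif(n))
    cen <- thrombus_census(bonds, platelets)
    ## oracle: exhaustive DFS over the platelets that carry bonds
    verts <- sort(unique(c(e[, 1], e[, 2], bonds$id_i[bonds$id_j < 0])))
    oracle <- dfs_components(verts, e)
    expect_equal(nrow(cen), length(unique(oracle)))
    expect_equal(sort(cen$size),
                 sort(as.integer(table(oracle))))
  }
})

test_that("configuration validation enforces the drive contract", {
  expect_error(sim_config(drive = list()), "exactly one")
  expect_error(sim_config(drive = list(dp = 20, target_Q = 5e-8)),
               "exactly one")
  expect_error(sim_config(drive = list(dp = 20),
                          numerics = list(force_relax = 0)))
  cfg <- sim_config(drive = list(dp = 20),
                    numerics = list(duration = 1e-4))
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$platelets$b_depth, cfg$platelets$diameter)
  expect_equal(cfg$numerics$steps, 500L)
})

test_that("identical configuration and seed give bit-identical outputs", {
  cfg <- tiny_coupled_config(duration = 600 * 4e-7, n_init = 12L,
                             inject = TRUE, tau_crit = 0.3, seed = 5L,
                             snapshot_every = 200L)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$diagnostics, r2$diagnostics)
  expect_identical(r1$platelets, r2$platelets)
  expect_identical(r1$bonds, r2$bonds)
  expect_identical(r1$platelet_log, r2$platelet_log)
  ## a different seed changes the trajectories
  cfg2 <- tiny_coupled_config(duration = 600 * 4e-7, n_init = 12L,
                              inject = TRUE, tau_crit = 0.3, seed = 6L,
                              snapshot_every = 200L)
  r3 <- run_simulation(cfg2)
  expect_false(identical(r1$platelets, r3$platelets))
})

test_that("output writers produce readable CSV, VTK and JSON artifacts", {
  cfg <- tiny_coupled_config(duration = 200 * 4e-7, n_init = 5L,
                             snapshot_every = 100L)
  run <- run_simulation(cfg)
  td <- tempfile(); dir.create(td)
  dcsv <- write_diagnostics_csv(run, file.path(td, "diag.csv"))
  d <- utils::read.csv(dcsv)
  expect_equal(d$flow_rate, run$diagnostics$flow_rate)
  pcsv <- write_platelet_csv(run, file.path(td, "platelets.csv"))
  expect_true(nrow(utils::read.csv(pcsv)) > 0)
  vtk <- write_vtk_snapshot(run$state, file.path(td, "snap.vtk"))
  head <- readLines(vtk, n = 5)
  expect_match(head[1], "vtk DataFile")
  expect_match(head[4], "STRUCTURED_POINTS")
  man <- write_run_manifest(run, file.path(td, "manifest.json"))
  m <- jsonlite::read_json(man)
  expect_equal(m$config$numerics$seed, 1)
  expect_equal(m$package, "occlusim")
  unlink(td, recursive = TRUE)
})
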