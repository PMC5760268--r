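# Output writers: CSV time series, platelet logs, legacy-ASCII VTK
# structured-grid snapshots and a JSON run manifest.

#' Write the diagnostics time series to CSV
#'
#' @param run An \code{occlusim_run} (or a diagnostics data.frame).
#' @param path Output file.
#' @export
write_diagnostics_csv <- function(run, path) {
  d <- if (inherits(run, "occlusim_run")) run$diagnostics else run
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write the platelet trajectory log to CSV
#'
#' @param run An \code{occlusim_run} with a non-empty \code{platelet_log}
#'   (set \code{output$snapshot_every} in the config).
#' @param path Output file.
#' @export
write_platelet_csv <- function(run, path) {
  utils::write.csv(run$platelet_log, path, row.names = FALSE)
  invisible(path)
}

#' Write a field snapshot as a legacy-ASCII VTK structured-points file
#'
#' Exports density, velocity, shear stress and the fluid mask of a lattice
#' state on the uniform grid, readable by ParaView and pyvista.
#'
#' @param state A \code{lattice_state}.
#' @param path Output file (conventionally \code{.vtk}).
#' @export
write_vtk_snapshot <- function(state, path) {
  nx <- state$nx; ny <- state$ny
  mac <- lbm_macroscopics(state)
  shear <- shear_stress_field(state)
  num <- function(v) {
    v[!is.finite(v)] <- 0
    formatC(v, format = "g", digits = 7)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "occlusim field snapshot", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nx, ny),
               sprintf("ORIGIN %g %g 0", state$geometry$x[1],
                       state$geometry$y[1]),
               sprintf("SPACING %g %g 1", state$geometry$dx,
                       state$geometry$dx),
               sprintf("POINT_DATA %d", nx * ny)), con)
  writeLines(c("SCALARS density double 1", "LOOKUP_TABLE default"), con)
  writeLines(num(as.numeric(mac$rho)), con)
  writeLines(c("SCALARS shear_stress double 1", "LOOKUP_TABLE default"), con)
  writeLines(num(as.numeric(shear)), con)
  writeLines(c("SCALARS mask int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(state$mask)), con)
  writeLines("VECTORS velocity double", con)
  writeLines(paste(num(as.numeric(mac$ux)), num(as.numeric(mac$uy)), "0"),
             con)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records all configuration parameters, the seed, the calibrated pressure
#' drop and the package version, for reproducibility.
#'
#' @param run An \code{occlusim_run}.
#' @param path Output file.
#' @export
write_run_manifest <- function(run, path) {
  cfg <- run$config
  cfg$geometry <- if (inherits(cfg$geometry, "channel_geometry")) {
    g <- cfg$geometry
    list(A = g$A, lambda = g$lambda, D = g$D, nx = g$nx,
         wall_rule = g$wall_rule)
  } else cfg$geometry
  cfg$platelets$contact <- unclass(cfg$platelets$contact)
  manifest <- list(
    package = "occlusim",
    version = as.character(utils::packageVersion("occlusim")),
    config = unclass(cfg),
    dp = run$dp, q0 = run$q0, n_sub = run$n_sub,
    occlusion_time = run$occlusion_time,
    seed = cfg$numerics$seed)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
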