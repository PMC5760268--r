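# Scenario presets for the study conditions: straight-channel validation,
# matched-initial-flow tortuosity cases, constant-pressure tortuosity
# cases, and the platelet-size sweep.

#' Validation preset: straight-channel pressure drops and grids
#'
#' @return List with the five pressure drops (Pa) and the fine and coarse
#'   validation grids.
#' @export
preset_validation <- function() {
  list(dp = c(5, 10, 15, 20, 30),
       grid_fine = c(600L, 48L), grid_coarse = c(300L, 24L),
       D = 25e-6, L = 314e-6, rho = 1030, nu = 1.2e-6, dt = 2e-7)
}

#' Matched-initial-flow tortuosity preset
#'
#' The three tortuosity levels with the pressure drops that give the same
#' initial flow rate of about 5.39e-8 m^2/s.
#'
#' @return data.frame with \code{TI}, \code{dp} (Pa) and \code{Q}
#'   (m^2/s).
#' @export
preset_matched_flow <- function() {
  data.frame(TI = c(0.08, 0.16, 0.24),
             dp = c(17.30, 20.00, 24.47),
             Q = c(5.394e-8, 5.393e-8, 5.394e-8))
}

#' Scenario configuration for a tortuosity level
#'
#' @param TI Tortuosity index.
#' @param drive \code{"matched-flow"} (pressure calibrated to the common
#'   initial flow rate) or \code{"constant-dp"} (fixed \code{dp}).
#' @param dp Pressure drop (Pa) for \code{"constant-dp"} (default 20).
#' @param diameter Platelet diameter (m).
#' @param duration Simulated time (s).
#' @param seed RNG seed.
#' @param nx Axial lattice nodes.
#' @param numerics,output,platelets Extra overrides merged into the
#'   corresponding \code{\link{sim_config}} sections.
#' @return A \code{\link{sim_config}}.
#' @export
scenario_tortuosity <- function(TI, drive = c("constant-dp", "matched-flow"),
                                dp = 20, diameter = 2.4e-6, duration = 1.0,
                                seed = 1L, nx = 320L, numerics = list(),
                                output = list(), platelets = list()) {
  drive <- match.arg(drive)
  dr <- if (drive == "constant-dp") list(dp = dp)
        else list(target_Q = 5.393e-8)
  sim_config(
    geometry = list(TI = TI, D = 25e-6, L = 314e-6, nx = nx),
    drive = dr,
    platelets = utils::modifyList(list(diameter = diameter), platelets),
    numerics = utils::modifyList(list(duration = duration, seed = seed),
                                 numerics),
    output = output)
}

#' Platelet-size sweep configurations
#'
#' The three platelet diameters studied at TI = 0.16 under a constant
#' pressure drop.
#'
#' @param dp Pressure drop (Pa).
#' @param duration Simulated time (s).
#' @param seed RNG seed.
#' @param ... Overrides passed to \code{\link{scenario_tortuosity}}.
#' @return Named list of three \code{\link{sim_config}} objects
#'   (\code{"1.9um"}, \code{"2.4um"}, \code{"3.1um"}).
#' @export
scenario_platelet_size <- function(dp = 20, duration = 1.0, seed = 1L, ...) {
  sizes <- c(1.9e-6, 2.4e-6, 3.1e-6)
  out <- lapply(sizes, function(d)
    scenario_tortuosity(TI = 0.16, drive = "constant-dp", dp = dp,
                        diameter = d, duration = duration, seed = seed, ...))
  names(out) <- c("1.9um", "2.4um", "3.1um")
  out
}
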