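#' Cosine centerline of a tortuous channel
#'
#' Height of the channel centerline above its mean position,
#' \eqn{g(x) = A \cos(2\pi x/\lambda)}, over the two-period domain
#' \eqn{0 \le x \le 2\lambda}.
#'
#' @param x Axial position(s) in metres; must lie in \code{[0, 2*lambda]}.
#' @param A Amplitude in metres (\code{A >= 0}).
#' @param lambda Wavelength in metres (\code{lambda > 0}).
#' @return Centerline height(s) in metres, in \code{[-A, A]}.
#' @examples
#' centerline(0, A = 25e-6, lambda = 104.17e-6)       # = A
#' centerline(104.17e-6 / 4, 25e-6, 104.17e-6)        # ~ 0
#' @export
centerline <- function(x, A, lambda) {
  stopifnot(is.numeric(x), length(A) == 1L, length(lambda) == 1L)
  if (A < 0) stop("amplitude A must be >= 0")
  if (lambda <= 0) stop("wavelength lambda must be > 0")
  if (any(x < -1e-12 * lambda | x > 2 * lambda * (1 + 1e-12)))
    stop("x outside the channel domain [0, 2*lambda]")
  A * cos(2 * pi * x / lambda)
}

#' Tortuosity index of a cosine channel
#'
#' @param A Amplitude (m).
#' @param lambda Wavelength (m).
#' @return Dimensionless ratio \code{A/lambda}.
#' @export
tortuosity_index <- function(A, lambda) A / lambda

#' Minimum radius of curvature of the cosine centerline
#'
#' The curvature of \eqn{g(x) = A\cos(2\pi x/\lambda)} is largest at the
#' extrema, where the radius of curvature is
#' \eqn{R_c = 1/(A (2\pi/\lambda)^2)}.
#'
#' @param A Amplitude (m); \code{A = 0} returns \code{Inf} (straight channel).
#' @param lambda Wavelength (m).
#' @return Radius of curvature in metres.
#' @examples
#' radius_of_curvature_min(25e-6, 104.17e-6)  # ~ 11 um (TI = 0.24, A = D = 25 um)
#' @export
radius_of_curvature_min <- function(A, lambda) {
  stopifnot(A >= 0, lambda > 0)
  if (A == 0) return(Inf)
  1 / (A * (2 * pi / lambda)^2)
}

#' Arc length of the two-period cosine centerline
#'
#' @param A Amplitude (m).
#' @param lambda Wavelength (m).
#' @return Arc length of \eqn{g(x)} over \code{[0, 2*lambda]} in metres.
#' @export
arc_length <- function(A, lambda) {
  k <- 2 * pi * A / lambda
  2 * lambda * stats::integrate(function(s) sqrt(1 + k^2 * sin(2 * pi * s)^2),
                                0, 1, rel.tol = 1e-10)$value
}

#' Dean number
#'
#' Secondary-flow strength in a curved conduit,
#' \eqn{Dn = (\rho V D/\mu)\sqrt{D/R_c}}.
#'
#' @param rho Fluid density (kg/m^3).
#' @param V Mean velocity (m/s).
#' @param D Channel diameter (m).
#' @param mu Dynamic viscosity (Pa s).
#' @param Rc Radius of curvature (m); \code{Inf} gives 0 (straight channel).
#' @return Dimensionless Dean number.
#' @export
dean_number <- function(rho, V, D, mu, Rc) {
  stopifnot(rho > 0, V >= 0, D > 0, mu > 0)
  if (any(Rc <= 0)) stop("radius of curvature Rc must be positive")
  (rho * V * D / mu) * sqrt(D / Rc)
}

#' Geometry presets for a given tortuosity index
#'
#' Resolves a tortuosity index into an (amplitude, wavelength) pair.  Two
#' conventions are supported, since a fixed axial length and a fixed arc
#' length cannot hold simultaneously across tortuosity levels:
#' \describe{
#'   \item{\code{"fixed-length"}}{axial length \code{L} is fixed;
#'     \code{lambda = L/2} and \code{A = TI*lambda}.  Default, and the
#'     convention matching an axial grid of fixed node count.}
#'   \item{\code{"equal-arc"}}{the centerline arc length is fixed at
#'     \code{arc_target}; \code{lambda} is solved from
#'     \code{S = 2*lambda*h(TI)} where \code{h} is the arc-length factor of
#'     one cosine period at slope \code{2*pi*TI}.}
#' }
#'
#' @param TI Tortuosity index (amplitude/wavelength).
#' @param L Axial length of the two-period channel (m).
#' @param mode \code{"fixed-length"} or \code{"equal-arc"}.
#' @param arc_target Target arc length (m) for \code{"equal-arc"} mode;
#'   defaults to \code{L}.
#' @return List with \code{A}, \code{lambda}, \code{TI}, \code{L}
#'   (axial length \code{2*lambda}) and \code{arc} (centerline arc length).
#' @export
ti_preset <- function(TI, L = 314e-6,
                      mode = c("fixed-length", "equal-arc"),
                      arc_target = NULL) {
  mode <- match.arg(mode)
  stopifnot(TI >= 0, L > 0)
  if (mode == "fixed-length") {
    lambda <- L / 2
  } else {
    if (is.null(arc_target)) arc_target <- L
    k <- 2 * pi * TI
    h <- stats::integrate(function(s) sqrt(1 + k^2 * sin(2 * pi * s)^2),
                          0, 1, rel.tol = 1e-10)$value
    lambda <- arc_target / (2 * h)
  }
  A <- TI * lambda
  list(A = A, lambda = lambda, TI = TI, L = 2 * lambda,
       arc = arc_length(A, lambda))
}

## Offset centerline in box coordinates: walls fit in 0 <= y <= 2A + D.
channel_center_y <- function(x, A, lambda, D) {
  A * cos(2 * pi * x / lambda) + A + D / 2
}

## Flood fill over a logical matrix (periodic in x), returning the connected
## component containing `seed` (an index).  4-neighbour connectivity.
flood_component <- function(mask, seed) {
  nx <- nrow(mask); ny <- ncol(mask)
  comp <- matrix(FALSE, nx, ny)
  comp[seed] <- TRUE
  repeat {
    grown <- comp
    grown[-1, ] <- grown[-1, ] | comp[-nx, ]
    grown[-nx, ] <- grown[-nx, ] | comp[-1, ]
    grown[1, ] <- grown[1, ] | comp[nx, ]
    grown[nx, ] <- grown[nx, ] | comp[1, ]
    grown[, -1] <- grown[, -1] | comp[, -ny]
    grown[, -ny] <- grown[, -ny] | comp[, -1]
    grown <- grown & mask
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

#' Build a tortuous-channel lattice domain
#'
#' Discretises the two-period cosine channel on a uniform grid and
#' classifies nodes as fluid or solid.  Node centres sit at
#' \code{x_i = (i - 1/2) dx} (periodic in x) and
#' \code{y_j = (j - 1/2 - margin) dx}, so the box \code{0 <= y <= 2A + D}
#' is padded by \code{margin} solid rows on each side.
#'
#' A node is fluid iff its distance to the centerline is at most the wall
#' half-width.  Two wall conventions are available:
#' \describe{
#'   \item{\code{"normal"}}{Euclidean distance to the centerline curve
#'     (walls are the true parallel offsets of the centerline, so the
#'     channel's perpendicular width is \code{D} everywhere).  Default.}
#'   \item{\code{"vertical"}}{vertical distance \code{|y - g(x)|} (walls are
#'     the vertical offsets \code{g(x) +/- D/2}; the perpendicular width
#'     shrinks to \code{D cos(theta)} on slopes).}
#' }
#'
#' \code{wall_shift} (lattice units) shrinks the classification half-width
#' by \code{wall_shift * dx} to compensate the apparent wall offset of the
#' bounce-back scheme at the run's relaxation time (see
#' \code{\link{bounceback_wall_offset}}), so the effective hydraulic width
#' equals \code{D}.
#'
#' @param A Amplitude (m).
#' @param lambda Wavelength (m).
#' @param D Channel diameter (m).
#' @param nx Number of axial lattice nodes (>= 8); \code{dx = 2*lambda/nx}.
#' @param wall_rule \code{"normal"} (default) or \code{"vertical"}.
#' @param wall_shift Wall-offset correction in lattice units (default 0).
#' @param margin Solid padding rows above/below the box (default 2).
#' @return An object of class \code{channel_geometry}: a list with the
#'   resolved parameters, node coordinates \code{x}, \code{y}, the
#'   fluid/solid \code{mask} (nx x ny, 1 = fluid), the distance-to-centerline
#'   field \code{phi} (m) and the classification half-width \code{half_width}.
#' @examples
#' ch <- build_channel(A = 0, lambda = 157e-6, D = 25e-6, nx = 64)
#' table(ch$mask)
#' @export
build_channel <- function(A, lambda, D, nx,
                          wall_rule = c("normal", "vertical"),
                          wall_shift = 0, margin = 2L) {
  wall_rule <- match.arg(wall_rule)
  stopifnot(A >= 0, lambda > 0, D > 0, nx >= 8, margin >= 1)
  dx <- 2 * lambda / nx
  height <- 2 * A + D
  ny_box <- ceiling(height / dx)
  ny <- ny_box + 2L * margin
  x <- (seq_len(nx) - 0.5) * dx
  y <- (seq_len(ny) - 0.5 - margin) * dx
  half_width <- D / 2 - wall_shift * dx

  if (A == 0 || wall_rule == "vertical") {
    yc <- channel_center_y(x, A, lambda, D)
    phi <- abs(outer(-yc, y, `+`))           # |y_j - yc(x_i)|
  } else {
    ns <- max(8L * nx, 2048L)
    xs <- (seq_len(ns) - 0.5) * (2 * lambda / ns)
    ys <- channel_center_y(xs, A, lambda, D)
    nodes <- expand.grid(x = x, y = y)
    phi <- matrix(cpp_dist_to_curve(nodes$x, nodes$y, xs, ys, 2 * lambda),
                  nx, ny)
  }
  mask <- (phi <= half_width) * 1L
  storage.mode(mask) <- "integer"

  widths <- rowSums(mask)                     # fluid nodes per axial column
  if (any(widths < 4))
    stop("unresolvable geometry: channel thinner than 4 lattice nodes ",
         "(min ", min(widths), " at column ", which.min(widths), ")")
  ## keep only the component connected to the inlet (guards against
  ## stray pixels); it must span the full axial extent
  comp <- flood_component(mask == 1L, which(mask == 1L)[1L])
  if (any(mask == 1L & !comp)) mask[mask == 1L & !comp] <- 0L
  if (any(rowSums(mask) < 1))
    stop("fluid region does not span the channel axially")

  structure(list(
    A = A, lambda = lambda, D = D, L = 2 * lambda,
    TI = A / lambda, nx = nx, ny = ny, dx = dx, margin = margin,
    x = x, y = y, mask = mask, phi = phi,
    half_width = half_width, wall_rule = wall_rule,
    wall_shift = wall_shift,
    fluid_area = sum(mask) * dx^2
  ), class = "channel_geometry")
}

#' Straight-channel lattice for validation runs
#'
#' Builds a plane channel of height \code{D} with \code{ny} transverse fluid
#' rows.  When \code{dt} and \code{nu} are supplied the lattice spacing is
#' sized so that the channel's \emph{effective} hydraulic height (half-way
#' wall planes plus the bounce-back wall offset of the scheme at the
#' resulting relaxation time) equals \code{D}; otherwise \code{dx = D/ny}.
#'
#' @param D Channel height (m).
#' @param nx Axial nodes (periodic).
#' @param ny Transverse fluid rows.
#' @param L Channel length used for the pressure gradient (m); kept
#'   independent of \code{nx*dx}, which is immaterial for axially invariant
#'   flow.
#' @param dt Time step (s), needed for the wall-offset correction.
#' @param nu Kinematic viscosity (m^2/s).
#' @param slip_correct Apply the bounce-back wall-offset correction
#'   (default \code{TRUE} when \code{dt} and \code{nu} are given).
#' @return A \code{channel_geometry} object (with \code{A = 0}).
#' @export
straight_channel <- function(D = 25e-6, nx = 600, ny = 48, L = 314e-6,
                             dt = NULL, nu = NULL,
                             slip_correct = !is.null(dt) && !is.null(nu)) {
  stopifnot(D > 0, nx >= 4, ny >= 4)
  dx <- D / ny
  delta <- 0
  if (slip_correct) {
    stopifnot(!is.null(dt), !is.null(nu))
    for (it in 1:3) {
      tau <- tau_from_viscosity(nu * dt / dx^2)
      delta <- bounceback_wall_offset(tau, ny)
      dx <- D / (ny + 2 * delta)
    }
  }
  margin <- 2L
  ny_tot <- ny + 2L * margin
  x <- (seq_len(nx) - 0.5) * dx
  y <- (seq_len(ny_tot) - 0.5 - margin) * dx
  yc <- dx * ny / 2
  phi <- matrix(abs(rep(y, each = nx) - yc), nx, ny_tot)
  mask <- (phi <= dx * ny / 2) * 1L
  storage.mode(mask) <- "integer"
  structure(list(
    A = 0, lambda = NA_real_, D = D, L = L, TI = 0,
    nx = nx, ny = ny_tot, dx = dx, margin = margin,
    x = x, y = y, mask = mask, phi = phi,
    half_width = dx * ny / 2, wall_rule = "normal",
    wall_shift = delta, fluid_area = sum(mask) * dx^2
  ), class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat("Tortuous-channel lattice domain\n")
  cat(sprintf("  A = %.3g um, lambda = %.3g um, D = %.3g um (TI = %.3g)\n",
              x$A * 1e6, x$lambda * 1e6, x$D * 1e6, x$TI))
  cat(sprintf("  grid %d x %d, dx = %.4g um, wall rule: %s (shift %.3g dx)\n",
              x$nx, x$ny, x$dx * 1e6, x$wall_rule, x$wall_shift))
  cat(sprintf("  fluid nodes: %d (%.1f%%)\n", sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Export the fluid/solid mask as plain text
#'
#' Writes the node classification as a grid of 0/1 characters, one row of
#' the lattice per line (top row first).
#'
#' @param geometry A \code{channel_geometry}.
#' @param path Output file path.
#' @export
write_mask <- function(geometry, path) {
  m <- geometry$mask
  lines <- apply(m[, rev(seq_len(ncol(m))), drop = FALSE], 2,
                 function(col) paste(col, collapse = ""))
  writeLines(lines, path)
  invisible(path)
}
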