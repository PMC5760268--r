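# Unresolved fluid-particle exchange: bilinear interpolation of nodal
# fields at platelet centres and the adjoint spreading of reaction forces
# back onto the lattice.  Using the same (bilinear) kernel for both
# directions makes interpolation and spreading adjoint, which guarantees
# the discrete momentum-exchange identity.

## continuous (1-based) node coordinates of a physical position
node_coords <- function(geometry, position) {
  gx <- position[1] / geometry$dx + 0.5
  gy <- position[2] / geometry$dx + 0.5 + geometry$margin
  c(gx, gy)
}

## stencil of the 4 surrounding nodes with bilinear weights;
## x wraps periodically, y is clamped to the grid
bilinear_stencil <- function(geometry, position) {
  g <- node_coords(geometry, position)
  i0 <- floor(g[1]); j0 <- floor(g[2])
  fx <- g[1] - i0; fy <- g[2] - j0
  ii <- c(i0, i0 + 1, i0, i0 + 1)
  jj <- c(j0, j0, j0 + 1, j0 + 1)
  w <- c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  ii <- ((ii - 1) %% geometry$nx) + 1
  jj <- pmin(pmax(jj, 1), geometry$ny)
  list(i = ii, j = jj, w = w)
}

#' Interpolate a nodal field at a point
#'
#' Bilinear interpolation over the four surrounding lattice nodes; weights
#' falling on solid nodes are redistributed proportionally onto the fluid
#' nodes of the stencil.
#'
#' @param field nx x ny matrix of nodal values.
#' @param geometry A \code{channel_geometry}.
#' @param position Physical position 2-vector (m).
#' @return Interpolated value.
#' @export
interpolate_field <- function(field, geometry, position) {
  st <- bilinear_stencil(geometry, position)
  fluid <- geometry$mask[cbind(st$i, st$j)] == 1L
  w <- st$w * fluid
  tot <- sum(w)
  if (tot <= 0)
    stop("all four stencil nodes are solid: position is inside the wall")
  sum(w * field[cbind(st$i, st$j)]) / tot
}

#' Spread platelet reaction forces onto the lattice
#'
#' Distributes each platelet's fluid-interaction force (the negative of its
#' Stokes drag) onto its four surrounding fluid nodes with bilinear
#' weights, as a lattice force density for the forcing term of the
#' collision step.  The total spread force equals the total reaction force.
#'
#' @param positions n x 2 matrix of platelet positions (m).
#' @param forces n x 2 matrix of reaction forces on the fluid (N).
#' @param geometry A \code{channel_geometry}.
#' @param units A \code{\link{lattice_units}} list.
#' @param b_depth Assumed out-of-plane depth (m) converting point forces to
#'   per-depth densities.
#' @return List of nx x ny matrices \code{x} and \code{y} (lattice force
#'   density), with attribute \code{total} = column sums of \code{forces}.
#' @export
spread_reaction_force <- function(positions, forces, geometry, units,
                                  b_depth) {
  stopifnot(ncol(positions) == 2, ncol(forces) == 2, b_depth > 0)
  nx <- geometry$nx; ny <- geometry$ny
  fx <- matrix(0, nx, ny); fy <- matrix(0, nx, ny)
  conv <- units$force_density / (geometry$dx^2 * b_depth)  # N -> lattice
  for (p in seq_len(nrow(positions))) {
    st <- bilinear_stencil(geometry, positions[p, ])
    fluid <- geometry$mask[cbind(st$i, st$j)] == 1L
    w <- st$w * fluid
    tot <- sum(w)
    if (tot <= 0) next
    w <- w / tot
    idx <- cbind(st$i, st$j)
    fx[idx] <- fx[idx] + w * forces[p, 1] * conv
    fy[idx] <- fy[idx] + w * forces[p, 2] * conv
  }
  structure(list(x = fx, y = fy), total = colSums(forces))
}
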