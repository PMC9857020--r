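# Dielectric, ion-accessibility and source maps on the calculation grid.
# The molecular envelope is the union of atom spheres, optionally inflated
# by the solvent probe radius; mobile ions are additionally excluded from a
# Stern shell measured from the vdW radius.

# apply f(subarray, mask) to the grid nodes within distance R of point p
.sphere_window <- function(g, p, R, values, inside_value) {
  ax <- grid_axis(g, 1); ay <- grid_axis(g, 2); az <- grid_axis(g, 3)
  ix <- which(abs(ax - p[1]) <= R)
  iy <- which(abs(ay - p[2]) <= R)
  iz <- which(abs(az - p[3]) <= R)
  if (!length(ix) || !length(iy) || !length(iz)) return(values)
  d2 <- outer(outer((ax[ix] - p[1])^2, (ay[iy] - p[2])^2, "+"),
              (az[iz] - p[3])^2, "+")
  sub <- values[ix, iy, iz, drop = FALSE]
  sub[d2 <= R^2] <- inside_value
  values[ix, iy, iz] <- sub
  values
}

#' Harmonic-mean permittivity at a finite-difference stencil face
#'
#' The flux through the face between two nodes uses the harmonic mean of the
#' node permittivities, the standard treatment for discontinuous
#' coefficients (e.g. 2 and 80 give 2*2*80/82 = 3.90).
#'
#' @param e1,e2 node permittivities (> 0).
#' @return harmonic mean 2*e1*e2/(e1+e2).
#' @export
face_permittivity <- function(e1, e2) {
  stopifnot(all(e1 > 0), all(e2 > 0))
  2 * e1 * e2 / (e1 + e2)
}

#' Build the node permittivity map
#'
#' Nodes inside any atom sphere of radius `radius + probe_radius * s` get
#' `eps_solute`, all others `eps_solvent`, where `s` is
#' `settings$surface_inflation` (1 by default: the probe-inflated union of
#' spheres approximates the solvent-excluded envelope; 0 gives the bare vdW
#' surface). The solver applies harmonic-mean averaging at stencil faces.
#'
#' @param x a charged [struct3d()] with radii set.
#' @param g a [scalar_grid()] giving the geometry.
#' @param settings a [solver_settings()].
#' @return a `scalar_grid` of permittivities.
#' @export
build_dielectric_map <- function(x, g, settings = solver_settings()) {
  stopifnot(inherits(x, "struct3d"), inherits(g, "scalar_grid"))
  if (anyNA(x$atoms$radius)) stop("atom radii unset; assign charges/radii first")
  v <- array(settings$eps_solvent, dim = g$dims)
  xyz <- coords(x)
  R <- x$atoms$radius + settings$probe_radius * settings$surface_inflation
  for (i in seq_len(nrow(xyz)))
    if (R[i] > 0) v <- .sphere_window(g, xyz[i, ], R[i], v, settings$eps_solute)
  scalar_grid(g$origin, g$spacing, g$dims, v)
}

#' Build the modified screening map
#'
#' \eqn{\bar\kappa^2 = \varepsilon_s \kappa^2} (1/Angstrom^2) at solvent
#' nodes farther than `radius + stern_radius` from every atom; 0 inside the
#' solute and its Stern (ion-exclusion) shell. \eqn{\kappa} comes from
#' [debye_parameter()] applied to `settings$ions`.
#'
#' @inheritParams build_dielectric_map
#' @return a `scalar_grid` of \eqn{\bar\kappa^2} values.
#' @export
build_screening_map <- function(x, g, settings = solver_settings()) {
  stopifnot(inherits(x, "struct3d"), inherits(g, "scalar_grid"))
  kappa <- debye_parameter(settings$ions, settings$eps_solvent, settings$temperature)
  v <- array(settings$eps_solvent * kappa^2, dim = g$dims)
  if (kappa > 0) {
    if (anyNA(x$atoms$radius)) stop("atom radii unset; assign charges/radii first")
    xyz <- coords(x)
    R <- x$atoms$radius + settings$stern_radius
    for (i in seq_len(nrow(xyz)))
      if (R[i] > 0) v <- .sphere_window(g, xyz[i, ], R[i], v, 0)
  }
  scalar_grid(g$origin, g$spacing, g$dims, v)
}

#' Distribute atomic charges to grid nodes
#'
#' Each atom's charge is split over the 8 nodes of its enclosing cell with
#' trilinear weights, conserving total charge to machine precision.
#'
#' @param x a charged [struct3d()]; all atoms must lie inside the grid.
#' @param g a [scalar_grid()].
#' @return a `scalar_grid` whose node values are charges in e (not a
#'   density; the solver divides by the cell volume).
#' @export
spread_charges <- function(x, g) {
  stopifnot(inherits(x, "struct3d"), inherits(g, "scalar_grid"))
  if (anyNA(x$atoms$charge)) stop("atom charges unset; assign charges/radii first")
  pts <- coords(x)
  t <- sweep(pts, 2, g$origin) / g$spacing
  if (any(t < -1e-9) || any(sweep(t, 2, g$dims - 1) > 1e-9))
    stop("atom outside grid in spread_charges")
  t <- pmin(pmax(t, 0), matrix(rep(g$dims - 1, each = nrow(t)), ncol = 3))
  i0 <- pmin(floor(t), matrix(rep(g$dims - 2, each = nrow(t)), ncol = 3))
  f <- t - i0
  nx <- g$dims[1]; ny <- g$dims[2]
  q <- x$atoms$charge
  v <- numeric(prod(g$dims))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx == 1) f[, 1] else 1 - f[, 1]) *
         (if (dy == 1) f[, 2] else 1 - f[, 2]) *
         (if (dz == 1) f[, 3] else 1 - f[, 3])
    lin <- 1 + (i0[, 1] + dx) + nx * ((i0[, 2] + dy) + ny * (i0[, 3] + dz))
    acc <- rowsum(w * q, lin)
    ii <- as.integer(rownames(acc))
    v[ii] <- v[ii] + acc[, 1]
  }
  scalar_grid(g$origin, g$spacing, g$dims, array(v, dim = g$dims))
}

.boundary_indices <- function(dims) {
  mask <- array(FALSE, dim = dims)
  mask[c(1, dims[1]), , ] <- TRUE
  mask[, c(1, dims[2]), ] <- TRUE
  mask[, , c(1, dims[3])] <- TRUE
  which(mask)
}

#' Boundary potential values for the finite-difference solve
#'
#' Three modes are supported. `"zero"` sets all faces to 0. `"coulomb_dh"`
#' (default) sums a screened-Coulomb (Debye-Hueckel) term per atom over the
#' boundary nodes: \eqn{\phi_b = \sum_i q_i C e^{-\kappa (r_i - a_i)} /
#' (\varepsilon_s r_i (1 + \kappa a_i))} with \eqn{a_i} the atom's
#' ion-exclusion radius (vdW + Stern). `"dipole_dh"` applies the same form
#' to the structure's net monopole plus point dipole placed at its center of
#' charge; this is the analogue of the dipolar boundary condition of
#' DelPhi-style solvers.
#'
#' @param g a [scalar_grid()].
#' @param x the charged [struct3d()] providing the source charges.
#' @param settings a [solver_settings()] (uses `boundary`, `eps_solvent`,
#'   `ions`, `temperature`, `stern_radius`).
#' @return a `scalar_grid` with boundary nodes set (interior 0), in kT/e.
#' @export
apply_boundary <- function(g, x, settings = solver_settings()) {
  stopifnot(inherits(g, "scalar_grid"), inherits(x, "struct3d"))
  mode <- settings$boundary
  if (!mode %in% c("zero", "coulomb_dh", "dipole_dh"))
    stop("unknown boundary mode: ", mode)
  v <- array(0, dim = g$dims)
  if (mode == "zero")
    return(scalar_grid(g$origin, g$spacing, g$dims, v))
  if (anyNA(x$atoms$charge)) stop("atom charges unset")
  C <- coulomb_constant(settings$temperature)
  kappa <- debye_parameter(settings$ions, settings$eps_solvent, settings$temperature)
  es <- settings$eps_solvent
  bidx <- .boundary_indices(g$dims)
  sub <- arrayInd(bidx, g$dims)
  bpos <- sweep((sub - 1) * g$spacing, 2, g$origin, "+")
  phi <- numeric(length(bidx))
  dh_term <- function(q, p, a) {
    d <- sqrt((bpos[, 1] - p[1])^2 + (bpos[, 2] - p[2])^2 + (bpos[, 3] - p[3])^2)
    d <- pmax(d, 1e-6)
    # screened Coulomb of a charge with ion-exclusion radius a:
    # decays as exp(-kappa (r - a)) outside the exclusion sphere
    q * C * exp(-kappa * (d - a)) / (es * d * (1 + kappa * a))
  }
  if (mode == "coulomb_dh") {
    xyz <- coords(x)
    a <- ifelse(is.na(x$atoms$radius), 0, x$atoms$radius) + settings$stern_radius
    q <- x$atoms$charge
    for (i in seq_len(nrow(xyz)))
      if (q[i] != 0) phi <- phi + dh_term(q[i], xyz[i, ], a[i])
  } else {
    xyz <- coords(x)
    q <- x$atoms$charge
    Q <- sum(q)
    r0 <- if (sum(abs(q)) > 0) colSums(abs(q) * xyz) / sum(abs(q)) else colMeans(xyz)
    p_dip <- colSums(q * (sweep(xyz, 2, r0)))
    a_eff <- mean(ifelse(is.na(x$atoms$radius), 0, x$atoms$radius)) + settings$stern_radius
    if (Q != 0) phi <- phi + dh_term(Q, r0, a_eff)
    if (sum(abs(p_dip)) > 0) {
      dvec <- sweep(bpos, 2, r0)
      d <- sqrt(rowSums(dvec^2)); d <- pmax(d, 1e-6)
      pr <- as.vector(dvec %*% p_dip) / d
      phi <- phi + C * pr * (1 + kappa * d) * exp(-kappa * d) / (es * d^2)
    }
  }
  v[bidx] <- phi
  scalar_grid(g$origin, g$spacing, g$dims, v)
}
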