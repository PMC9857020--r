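#' Poisson-Boltzmann solver settings
#'
#' Collects the physical and numerical parameters of the finite-difference
#' PB solve. Defaults reproduce a standard protein setup: solute
#' permittivity 2.0, solvent 80.0, 150 mM 1:1 salt at 300 K, 1.4 Angstrom
#' solvent probe, 2.0 Angstrom Stern (ion-exclusion) shell, 70% box fill,
#' screened-Coulomb boundary values, linearized equation.
#'
#' @param eps_solute solute relative permittivity (> 0).
#' @param eps_solvent solvent relative permittivity (> 0).
#' @param ions list of [ion_species()]; `salt_ions(0.15)` by default. Ions
#'   enter only through the ionic strength in the screening parameter
#'   (mean-field), so divalent cations are modelled as
#'   `salt_ions(0.15, z_plus = 2)`.
#' @param temperature kelvin.
#' @param probe_radius solvent probe radius, Angstrom.
#' @param surface_inflation 0 or 1: whether the dielectric envelope inflates
#'   atom spheres by the probe radius.
#' @param stern_radius ion-exclusion shell thickness, Angstrom.
#' @param fill_percent structure extent as a percentage of the box edge
#'   (0 < fill < 100).
#' @param boundary one of `"zero"`, `"coulomb_dh"` (per-atom screened
#'   Coulomb, default), `"dipole_dh"` (monopole + dipole).
#' @param tolerance convergence threshold on the max node update, kT/e.
#' @param max_iterations SOR sweep limit.
#' @param omega SOR over-relaxation factor in (0, 2); applies to the linear
#'   solve. The nonlinear mode runs unaccelerated (omega 1) for robustness.
#' @param nonlinear logical; solve the full sinh form by nonlinear SOR with
#'   a per-node Newton linearization of the sinh term.
#' @param max_dims maximum grid nodes per axis.
#' @return object of class `solver_settings`.
#' @export
solver_settings <- function(eps_solute = 2.0, eps_solvent = 80.0,
                            ions = salt_ions(0.15), temperature = 300,
                            probe_radius = 1.4, surface_inflation = 1,
                            stern_radius = 2.0, fill_percent = 70.0,
                            boundary = c("coulomb_dh", "dipole_dh", "zero"),
                            tolerance = 1e-6, max_iterations = 10000,
                            omega = 1.9, nonlinear = FALSE, max_dims = 97) {
  boundary <- match.arg(boundary)
  stopifnot(eps_solute > 0, eps_solvent > 0, temperature > 0,
            probe_radius >= 0, surface_inflation %in% c(0, 1),
            stern_radius >= 0, tolerance > 0, max_iterations >= 1,
            omega > 0, omega < 2, max_dims >= 3)
  if (fill_percent <= 0 || fill_percent >= 100)
    stop("fill_percent must lie strictly between 0 and 100")
  structure(list(eps_solute = eps_solute, eps_solvent = eps_solvent,
                 ions = ions, temperature = temperature,
                 probe_radius = probe_radius,
                 surface_inflation = surface_inflation,
                 stern_radius = stern_radius, fill_percent = fill_percent,
                 boundary = boundary, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations), omega = omega,
                 nonlinear = nonlinear, max_dims = as.integer(max_dims)),
            class = "solver_settings")
}

.check_same_grid <- function(...) {
  gs <- list(...)
  ref <- gs[[1]]
  for (g in gs[-1]) {
    if (!identical(g$dims, ref$dims) ||
        max(abs(g$origin - ref$origin)) > 1e-9 ||
        abs(g$spacing - ref$spacing) > 1e-12)
      stop("maps are not defined on the same grid")
  }
  invisible(TRUE)
}

#' Solve the Poisson-Boltzmann equation on a grid
#'
#' Finite-difference solution of
#' \deqn{\nabla\cdot[\varepsilon(r)\nabla\phi(r)] - \bar\kappa^2(r)\,
#'       \sinh\phi(r) = -4\pi C \rho(r)}
#' with \eqn{\phi} in kT/e, by red-black successive over-relaxation with
#' harmonic-mean face permittivities. The linearized form (sinh replaced by
#' its argument) is the default; `settings$nonlinear = TRUE` keeps the sinh
#' term and updates each node through a local Newton linearization
#' (nonlinear SOR, run without over-relaxation for robustness).
#'
#' @param source charge grid from [spread_charges()] (e per node).
#' @param eps_map permittivity grid from [build_dielectric_map()].
#' @param screening_map \eqn{\bar\kappa^2} grid from [build_screening_map()].
#' @param boundary boundary-value grid from [apply_boundary()].
#' @param settings a [solver_settings()].
#' @return list with `phi` (a [scalar_grid()], kT/e), `iterations`,
#'   `residual` (final max node update), `history` (max update per sweep).
#' @export
solve_pbe <- function(source, eps_map, screening_map, boundary,
                      settings = solver_settings()) {
  .check_same_grid(source, eps_map, screening_map, boundary)
  g <- source
  fourpic <- 4 * pi * coulomb_constant(settings$temperature)
  omega <- if (settings$nonlinear) 1.0 else settings$omega
  res <- sor_solve_cpp(as.vector(eps_map$values),
                       as.vector(screening_map$values),
                       as.vector(source$values),
                       as.vector(boundary$values), g$dims, g$spacing, fourpic,
                       omega, settings$tolerance, settings$max_iterations,
                       settings$nonlinear)
  if (!res$converged)
    stop(structure(class = c("pbe_convergence_error", "error", "condition"),
                   list(message = sprintf(
                     "PB solver did not converge in %d sweeps (max update %.3g kT/e)",
                     res$iterations, res$residual),
                     call = sys.call(-1), history = res$history)))
  list(phi = scalar_grid(g$origin, g$spacing, g$dims,
                         array(res$phi, dim = g$dims)),
       iterations = res$iterations,
       residual = res$residual,
       history = res$history)
}

#' One-call potential map for a charged structure
#'
#' Convenience composition: build the grid ([build_grid()]), the dielectric
#' and screening maps, spread the charges, apply the boundary condition and
#' solve.
#'
#' @param x a charged [struct3d()].
#' @param settings a [solver_settings()].
#' @param source_struct optional structure supplying the source charges
#'   (defaults to `x`; pass a subset to solve with one molecule's charges in
#'   the full complex's dielectric cavity).
#' @param ... grid geometry overrides passed to [build_grid()]
#'   (`spacing`, `dims`, `min_edge`).
#' @return as [solve_pbe()], plus `grid`, `eps`, `screening` entries.
#' @export
solve_potential <- function(x, settings = solver_settings(),
                            source_struct = x, ...) {
  g <- build_grid(x, settings, ...)
  eps <- build_dielectric_map(x, g, settings)
  scr <- build_screening_map(x, g, settings)
  src <- spread_charges(source_struct, g)
  bnd <- apply_boundary(g, source_struct, settings)
  out <- solve_pbe(src, eps, scr, bnd, settings)
  out$grid <- g; out$eps <- eps; out$screening <- scr
  out
}

#' Electric field from a potential grid
#'
#' \eqn{E = -\nabla\phi} by central differences at interior nodes and
#' one-sided differences on the faces, in kT/(e Angstrom).
#'
#' @param phi a potential [scalar_grid()] (kT/e).
#' @return list of three `scalar_grid`s: `Ex`, `Ey`, `Ez`.
#' @export
grid_gradient <- function(phi) {
  stopifnot(inherits(phi, "scalar_grid"))
  v <- phi$values; h <- phi$spacing; d <- phi$dims
  deriv <- function(ax) {
    n <- d[ax]
    idx <- function(i) switch(ax,
      v[i, , , drop = FALSE], v[, i, , drop = FALSE], v[, , i, drop = FALSE])
    out <- array(0, dim = d)
    ctr <- (idx(3:n) - idx(1:(n - 2))) / (2 * h)
    lo <- (idx(2) - idx(1)) / h
    hi <- (idx(n) - idx(n - 1)) / h
    if (ax == 1) { out[2:(n - 1), , ] <- ctr; out[1, , ] <- lo; out[n, , ] <- hi }
    if (ax == 2) { out[, 2:(n - 1), ] <- ctr; out[, 1, ] <- lo; out[, n, ] <- hi }
    if (ax == 3) { out[, , 2:(n - 1)] <- ctr; out[, , 1] <- lo; out[, , n] <- hi }
    scalar_grid(phi$origin, h, d, -out)
  }
  list(Ex = deriv(1), Ey = deriv(2), Ez = deriv(3))
}

#' Sample the potential at atom positions
#'
#' Trilinear interpolation of the solved potential at each atom position,
#' optionally clamped to [-1, +1] kT/e (the conventional surface-potential
#' colour scale).
#'
#' @param x a [struct3d()].
#' @param phi a potential [scalar_grid()] (kT/e).
#' @param clamp logical; clamp samples to [-1, 1] kT/e.
#' @return numeric vector, one value per atom.
#' @export
surface_potential <- function(x, phi, clamp = FALSE) {
  stopifnot(inherits(x, "struct3d"))
  out <- trilinear_interp(phi, coords(x))
  if (clamp) out <- pmin(pmax(out, -1), 1)
  out
}
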