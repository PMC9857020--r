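# Finite-difference PB solver: trivial limits, analytic agreement,
# linearity, symmetry, convergence behaviour.

uniform_setup <- function(x, settings, dims, min_edge = 32) {
  g <- build_grid(x, settings, dims = dims, min_edge = min_edge)
  list(g = g,
       eps = build_dielectric_map(x, g, settings),
       scr = build_screening_map(x, g, settings),
       src = spread_charges(x, g),
       bnd = apply_boundary(g, x, settings))
}

test_that("zero source with zero boundary gives the zero solution", {
  s <- solver_settings(boundary = "zero", ions = list())
  x <- atoms_df(at("Q", "ION", "A", 1, c(0, 0, 0), charge = 0, radius = 0))
  su <- uniform_setup(x, s, dims = 17, min_edge = 16)
  sol <- solve_pbe(su$src, su$eps, su$scr, su$bnd, s)
  expect_true(all(sol$phi$values == 0))
  expect_equal(sol$residual, 0)
})

test_that("single charge in uniform dielectric reproduces the Coulomb potential", {
  s <- solver_settings(eps_solute = 80, ions = list(), stern_radius = 0,
                       surface_inflation = 0)
  ion <- make_born_ion(1, 1)
  su <- uniform_setup(ion, s, dims = 33)
  sol <- solve_pbe(su$src, su$eps, su$scr, su$bnd, s)
  C <- coulomb_constant(300)
  phi10 <- trilinear_interp(sol$phi, matrix(c(10, 0, 0), 1))
  expect_equal(phi10, C / (80 * 10), tolerance = 0.05)
  expect_equal(C / (80 * 10), 0.6963, tolerance = 1e-3)
})

test_that("Born ion exterior potential matches the Debye-Hueckel closed form", {
  s <- solver_settings(stern_radius = 0, surface_inflation = 0)
  born <- make_born_ion(1, 2)
  su <- uniform_setup(born, s, dims = 49)
  sol <- solve_pbe(su$src, su$eps, su$scr, su$bnd, s)
  g <- su$g
  ax <- grid_axis(g, 1); ay <- grid_axis(g, 2); az <- grid_axis(g, 3)
  r <- sqrt(outer(outer(ax^2, ay^2, "+"), az^2, "+"))
  sel <- r >= 2 + 2 * g$spacing
  ana <- born_ion_potential(pmax(r, 2), 1, 2, s)
  expect_lt(max(abs(sol$phi$values[sel] - ana[sel]) / abs(ana[sel])), 0.05)
})

test_that("grid refinement reduces the Born-ion error monotonically", {
  s <- solver_settings(stern_radius = 0, surface_inflation = 0)
  born <- make_born_ion(1, 2)
  err <- sapply(c(33, 65), function(nd) {
    su <- uniform_setup(born, s, dims = nd)
    sol <- solve_pbe(su$src, su$eps, su$scr, su$bnd, s)
    g <- su$g
    ax <- grid_axis(g, 1)
    r <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
    sel <- r >= 2 + 2 * (32 / 32)  # fixed comparison region r >= 4 A
    ana <- born_ion_potential(pmax(r, 2), 1, 2, s)
    max(abs(sol$phi$values[sel] - ana[sel]) / abs(ana[sel]))
  })
  expect_lt(err[2], err[1])
})

test_that("the linear solve is linear in the charges and salt-free equals Poisson", {
  s <- solver_settings(stern_radius = 0, surface_inflation = 0)
  born <- make_born_ion(1, 2)
  su <- uniform_setup(born, s, dims = 25)
  sol1 <- solve_pbe(su$src, su$eps, su$scr, su$bnd, s)
  for (c_scale in c(2, -1)) {
    bornc <- make_born_ion(c_scale, 2)
    suc <- uniform_setup(bornc, s, dims = 25)
    solc <- solve_pbe(suc$src, suc$eps, suc$scr, suc$bnd, s)
    expect_equal(solc$phi$values, c_scale * sol1$phi$values,
                 tolerance = 1e-4, label = sprintf("scale %g", c_scale))
  }
  # kappa = 0 equals the pure Poisson solution
  s0 <- solver_settings(ions = list(), stern_radius = 0, surface_inflation = 0)
  su0 <- uniform_setup(born, s0, dims = 25)
  zero_scr <- scalar_grid(su0$g$origin, su0$g$spacing, su0$g$dims, 0)
  solA <- solve_pbe(su0$src, su0$eps, su0$scr, su0$bnd, s0)
  solB <- solve_pbe(su0$src, su0$eps, zero_scr, su0$bnd, s0)
  expect_equal(solA$phi$values, solB$phi$values, tolerance = 1e-12)
})

test_that("a centered charge yields a permutation-symmetric potential", {
  s <- solver_settings(eps_solute = 80, ions = list(), stern_radius = 0,
                       surface_inflation = 0)
  ion <- make_born_ion(1, 1)
  su <- uniform_setup(ion, s, dims = 25)
  sol <- solve_pbe(su$src, su$eps, su$scr, su$bnd, s)
  v <- sol$phi$values
  expect_equal(v, aperm(v, c(2, 1, 3)), tolerance = 1e-5)
  expect_equal(v, aperm(v, c(3, 2, 1)), tolerance = 1e-5)
  expect_equal(v, v[rev(seq_len(dim(v)[1])), , ], tolerance = 1e-5)
})

test_that("the nonlinear mode converges and stays near the linear solution at low potential", {
  sl <- solver_settings(stern_radius = 0, surface_inflation = 0)
  snl <- solver_settings(stern_radius = 0, surface_inflation = 0, nonlinear = TRUE)
  born <- make_born_ion(0.2, 2)  # weak charge: |phi| << 1 kT/e outside
  su <- uniform_setup(born, sl, dims = 25)
  lin <- solve_pbe(su$src, su$eps, su$scr, su$bnd, sl)
  nl <- solve_pbe(su$src, su$eps, su$scr, su$bnd, snl)
  sel <- abs(lin$phi$values) > 1e-4
  expect_lt(max(abs(nl$phi$values[sel] - lin$phi$values[sel]) /
                abs(lin$phi$values[sel])), 0.01)
  # at strong charge the sinh term increases effective screening:
  # nonlinear |phi| <= linear |phi| in the solvent
  born4 <- make_born_ion(4, 2)
  su4 <- uniform_setup(born4, sl, dims = 25)
  lin4 <- solve_pbe(su4$src, su4$eps, su4$scr, su4$bnd, sl)
  nl4 <- solve_pbe(su4$src, su4$eps, su4$scr, su4$bnd, snl)
  far <- su4$scr$values > 0
  expect_true(all(nl4$phi$values[far] <= lin4$phi$values[far] + 1e-6))
})

test_that("non-convergence raises an error carrying the residual history", {
  s <- solver_settings(max_iterations = 3, stern_radius = 0, surface_inflation = 0)
  born <- make_born_ion(1, 2)
  su <- uniform_setup(born, s, dims = 25)
  err <- tryCatch(solve_pbe(su$src, su$eps, su$scr, su$bnd, s), error = identity)
  expect_s3_class(err, "pbe_convergence_error")
  expect_equal(length(err$history), 3)
})

test_that("surface potential sampling matches node values and the trilinear oracle", {
  g <- scalar_grid(c(0, 0, 0), 1, c(7, 7, 7), array(rnorm(343), c(7, 7, 7)))
  x0 <- atoms_df(at("Q", "ION", "A", 1, c(3, 3, 3)))
  expect_equal(surface_potential(x0, g), g$values[4, 4, 4])
  set.seed(5)
  pts <- matrix(runif(30, 0.2, 5.8), ncol = 3)
  mine <- trilinear_interp(g, pts)
  ora <- apply(pts, 1, function(p) oracle_trilinear(g, p))
  expect_equal(mine, ora, tolerance = 1e-12)
  zero <- scalar_grid(c(0, 0, 0), 1, c(7, 7, 7), 0)
  expect_equal(surface_potential(x0, zero), 0)
  # clamping to the +/-1 kT/e reporting scale
  big <- scalar_grid(c(0, 0, 0), 1, c(7, 7, 7), 5)
  expect_equal(surface_potential(x0, big, clamp = TRUE), 1)
  outside <- atoms_df(at("Q", "ION", "A", 1, c(30, 0, 0)))
  expect_error(surface_potential(outside, g), "outside grid")
})
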