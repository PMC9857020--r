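# Grid geometry, dielectric/screening/source maps, boundary conditions, DX I/O.

test_that("Debye parameter matches the closed form and its scaling laws", {
  # 150 mM 1:1, eps 80, 300 K: screening length ~7.95 A
  k <- debye_parameter(salt_ions(0.15), 80, 300)
  expect_equal(1 / k, 7.95, tolerance = 0.01)
  expect_equal(debye_parameter(list(), 80, 300), 0)
  # +2/-2 salt at equal concentration has 4x the ionic strength -> 2x kappa
  k22 <- debye_parameter(list(ion_species(0.15, 2), ion_species(0.15, -2)), 80, 300)
  expect_equal(k22 / k, 2, tolerance = 1e-12)
  # electroneutral divalent-cation salt (+2 with 2x -1 anions): I = 3x -> sqrt(3)x
  kdiv <- debye_parameter(salt_ions(0.15, z_plus = 2), 80, 300)
  expect_equal(kdiv / k, sqrt(3), tolerance = 1e-12)
  expect_error(debye_parameter(salt_ions(0.15), -1), "positive")
})

test_that("grid geometry honours fill percentage, floor and explicit overrides", {
  # two zero-radius atoms spanning 35 A at 70% fill -> 50 A box
  s <- atoms_df(at("Q", "ION", "A", 1, c(0, 0, 0), radius = 0),
                at("Q", "ION", "B", 1, c(35, 0, 0), radius = 0))
  g <- build_grid(s, solver_settings(), dims = 51)
  expect_equal(g$spacing * (g$dims[1] - 1), 50, tolerance = 1e-9)
  expect_equal(g$origin, c(17.5 - 25, -25, -25), tolerance = 1e-9)
  # single atom: 20 A floor applies
  g2 <- build_grid(make_born_ion(1, 2), solver_settings(), dims = 21)
  expect_equal(g2$spacing * (g2$dims[1] - 1), 20, tolerance = 1e-9)
  # fill outside (0, 100) rejected
  expect_error(solver_settings(fill_percent = 101), "fill_percent")
  bad <- solver_settings(); bad$fill_percent <- 101
  expect_error(build_grid(make_born_ion(), bad), "fill_percent")
  # spacing request is honoured up to the dims cap
  g3 <- build_grid(make_born_ion(1, 2), solver_settings(), spacing = 0.5)
  expect_lte(g3$spacing, 0.5)
})

test_that("dielectric map separates solute and solvent with harmonic faces", {
  s <- make_born_ion(1, 2)
  st <- solver_settings(surface_inflation = 0)
  g <- build_grid(s, st, dims = 21)
  eps <- build_dielectric_map(s, g, st)
  ctr <- (g$dims + 1) / 2
  expect_equal(eps$values[ctr[1], ctr[2], ctr[3]], 2.0)  # node at atom center
  expect_equal(eps$values[1, 1, 1], 80.0)                # far corner is solvent
  # zero-radius atoms leave the map uniform solvent
  s0 <- atoms_df(at("Q", "ION", "A", 1, c(0, 0, 0), radius = 0))
  eps0 <- build_dielectric_map(s0, build_grid(s0, st, dims = 11), st)
  expect_true(all(eps0$values == 80))
  # face value between solute and solvent nodes
  expect_equal(face_permittivity(2, 80), 2 * 2 * 80 / 82)
  expect_equal(face_permittivity(2, 80), 3.902439, tolerance = 1e-6)
})

test_that("screening map is zero inside the Stern shell and bulk elsewhere", {
  s <- make_born_ion(1, 2)
  st <- solver_settings(stern_radius = 2)
  g <- build_grid(s, st, dims = 33, min_edge = 32)
  scr <- build_screening_map(s, g, st)
  kap <- debye_parameter(st$ions, st$eps_solvent, st$temperature)
  ctr <- (g$dims + 1) / 2
  expect_equal(scr$values[ctr[1], ctr[2], ctr[3]], 0)  # inside solute
  # node just inside radius + stern = 4 A
  expect_equal(scr$values[ctr[1] + 3, ctr[2], ctr[3]], 0)
  # bulk node carries eps_s * kappa^2
  expect_equal(scr$values[1, 1, 1], 80 * kap^2, tolerance = 1e-12)
  # no salt: identically zero
  s0 <- solver_settings(ions = list())
  scr0 <- build_screening_map(s, g, s0)
  expect_true(all(scr0$values == 0))
})

test_that("charge spreading is exact on nodes, symmetric at cell centers, conservative", {
  g <- scalar_grid(c(0, 0, 0), 1, c(9, 9, 9))
  on_node <- atoms_df(at("Q", "ION", "A", 1, c(4, 4, 4), charge = 1))
  src <- spread_charges(on_node, g)
  expect_equal(src$values[5, 5, 5], 1.0)
  expect_equal(sum(src$values), 1.0)
  expect_equal(sum(src$values != 0), 1)
  center <- atoms_df(at("Q", "ION", "A", 1, c(4.5, 4.5, 4.5), charge = 1))
  src2 <- spread_charges(center, g)
  expect_equal(sort(unique(round(src2$values[src2$values > 0], 12))), 0.125)
  expect_equal(sum(src2$values > 0), 8)
  # conservation at arbitrary positions, mixed signs
  set.seed(42)
  n <- 20
  rnd <- struct3d(data.frame(serial = 1:n, name = "Q", resname = "ION",
                             chain = "A", resid = 1:n,
                             x = runif(n, 1, 7), y = runif(n, 1, 7), z = runif(n, 1, 7),
                             charge = rnorm(n), radius = 1))
  src3 <- spread_charges(rnd, g)
  expect_equal(sum(src3$values), sum(rnd$atoms$charge), tolerance = 1e-13)
  outside <- atoms_df(at("Q", "ION", "A", 1, c(30, 0, 0), charge = 1))
  expect_error(spread_charges(outside, g), "outside grid")
})

test_that("boundary conditions reproduce closed forms and multipole limits", {
  st0 <- solver_settings(ions = list(), stern_radius = 0, boundary = "coulomb_dh")
  # +1 e at the grid center, kappa = 0: boundary face center is 25 A away
  q <- atoms_df(at("Q", "ION", "A", 1, c(0, 0, 0), charge = 1, radius = 2))
  g <- scalar_grid(c(-25, -25, -25), 50 / 16, c(17, 17, 17))
  b <- apply_boundary(g, q, st0)
  C <- coulomb_constant(300)
  expect_equal(b$values[1, 9, 9], C / (80 * 25), tolerance = 1e-9)
  expect_equal(b$values[1, 9, 9], 0.2785, tolerance = 1e-3)
  expect_equal(b$values[9, 9, 9], 0)  # interior untouched
  # neutral, dipole-free structure: dipolar boundary identically 0
  st_dip <- solver_settings(boundary = "dipole_dh")
  pair <- atoms_df(at("Q", "ION", "A", 1, c(0, 0, 0), charge = 1, radius = 1),
                   at("Q", "ION", "A", 2, c(0, 0, 0.0), charge = -1, radius = 1))
  b2 <- apply_boundary(g, pair, st_dip)
  expect_true(all(b2$values == 0))
  # coulomb_dh and dipole_dh agree asymptotically for a compact monopole
  st_c <- solver_settings(ions = list(), stern_radius = 0, boundary = "coulomb_dh")
  st_d <- solver_settings(ions = list(), stern_radius = 0, boundary = "dipole_dh")
  mono <- atoms_df(at("Q1", "ION", "A", 1, c(0.7, -0.3, 0.4), charge = 0.5, radius = 2),
                   at("Q2", "ION", "A", 2, c(-0.9, 0.8, -0.2), charge = 0.5, radius = 2))
  reldiff <- sapply(c(30, 60, 120), function(edge) {
    gg <- scalar_grid(rep(-edge / 2, 3), edge / 16, c(17, 17, 17))
    bc <- apply_boundary(gg, mono, st_c)$values
    bd <- apply_boundary(gg, mono, st_d)$values
    sel <- bc != 0
    max(abs(bc[sel] - bd[sel]) / abs(bc[sel]))
  })
  expect_true(all(diff(reldiff) < 0))
  expect_lt(reldiff[3], 1e-3)
  # unknown mode rejected
  bad <- solver_settings(); bad$boundary <- "mirror"
  expect_error(apply_boundary(g, q, bad), "unknown boundary mode")
})

test_that("OpenDX files round trip and reject unsupported layouts", {
  set.seed(7)
  g <- scalar_grid(c(-1, 0, 2.5), 0.75, c(3, 4, 5), array(rnorm(60), c(3, 4, 5)))
  f <- tempfile(fileext = ".dx")
  write_dx(g, f)
  g2 <- read_dx(f)
  expect_equal(g2$origin, g$origin, tolerance = 1e-9)
  expect_equal(g2$spacing, g$spacing, tolerance = 1e-9)
  expect_equal(g2$dims, g$dims)
  expect_equal(g2$values, g$values, tolerance = 1e-5)
  # data laid out 3 per line parses to nx*ny*nz values
  expect_equal(length(g2$values), 60)
  # non-uniform spacing rejected
  lines <- readLines(f)
  lines[grep("^delta", lines)[1]] <-
    "delta 9.990000e-01 0.000000e+00 0.000000e+00"
  f2 <- tempfile(fileext = ".dx")
  writeLines(lines, f2)
  expect_error(read_dx(f2), "non-uniform")
  # malformed header rejected
  f3 <- tempfile(fileext = ".dx")
  writeLines(lines[-2], f3)
  expect_error(read_dx(f3), "malformed|missing")
})
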