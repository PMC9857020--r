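# Structure containers, PQR/PDB parsing and template charge assignment.

write_tmp <- function(lines) {
  f <- tempfile(fileext = ".pqr")
  writeLines(lines, f)
  f
}

test_that("PQR reading populates charge and radius and preserves order", {
  f <- write_tmp(c(
    "ATOM      1 N    GLY A    1       1.000   2.000   3.000   1.0000  1.5000",
    "ATOM      2 CA   GLY A    1       2.000   2.000   3.000  -0.5000  1.7000",
    "ATOM      3 C    GLY A    1       3.000   2.000   3.000  -0.5000  1.7000"))
  s <- read_pqr(f)
  expect_s3_class(s, "struct3d")
  expect_equal(nrow(s$atoms), 3)
  expect_equal(s$atoms$charge, c(1.0, -0.5, -0.5))
  expect_equal(s$atoms$radius[1], 1.5)
  expect_equal(s$atoms$name, c("N", "CA", "C"))
  expect_equal(total_charge(s), 0.0)
})

test_that("malformed and empty PQR files produce informative errors", {
  expect_error(read_pqr(write_tmp("REMARK nothing here")), "no atoms")
  bad <- write_tmp(c(
    "ATOM      1 N    GLY A    1       1.000   2.000   3.000   1.0000  1.5000",
    "ATOM      2 CA   GLY A    1       2.000   not_a_number 3.0 -0.5 1.7"))
  expect_error(read_pqr(bad), "line 2")
  short <- write_tmp("ATOM 1 N GLY A 1 1.0 2.0 3.0")  # missing charge/radius
  expect_error(read_pqr(short), "line 1")
})

test_that("PQR write/read round trip preserves charges and radii", {
  s <- make_charged_interface_pair(2, 3.5)
  f <- tempfile(fileext = ".pqr")
  write_pqr(s, f)
  s2 <- read_pqr(f)
  expect_equal(s2$atoms$charge, s$atoms$charge, tolerance = 1e-8)
  expect_equal(s2$atoms$radius, s$atoms$radius, tolerance = 1e-8)
  expect_equal(s2$atoms$name, s$atoms$name)
  expect_equal(coords(s2), coords(s), tolerance = 1e-3)
})

test_that("PDB reading takes the first model with a warning and flags unset charges", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  GLY A   1       9.000   9.000   9.000  1.00  0.00",
    "ENDMDL", "END"), f)
  expect_warning(s <- read_pdb(f), "first")
  expect_equal(unname(coords(s)[1, ]), c(1, 2, 3))
  expect_true(is.na(s$atoms$charge[1]))
  f2 <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER junk", "REMARK none"), f2)
  expect_error(read_pdb(f2), "no atoms")
})

test_that("multi-model ensembles load with frame ranges and count checks", {
  base <- make_charged_interface_pair(2, 3.5)
  ens <- make_contact_trajectory(base, c("1" = 1, "2" = 0), n_frames = 10, seed = 1)
  f <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, f)
  e2 <- read_ensemble(f, topology = base)
  expect_equal(n_frames(e2), 10)
  expect_equal(e2$frames[[3]], ens$frames[[3]], tolerance = 1e-3)
  e3 <- read_ensemble(f, topology = base, frame_range = "last 50%")
  expect_equal(n_frames(e3), 5)
  expect_equal(e3$frames[[1]], ens$frames[[6]], tolerance = 1e-3)
  # atom-count mismatch
  expect_error(read_ensemble(f, topology = make_born_ion()), "mismatch")
  # frame selection on in-memory ensembles
  expect_equal(n_frames(select_frames(ens, 2:4)), 3)
  expect_error(select_frames(ens, 99), "out of bounds")
})

test_that("template assignment yields integer residue charges and flags unknowns", {
  tmpl <- charge_template()
  for (res in c("GLY", "ALA", "SER", "THR", "ASN", "GLN", "TYR", "TRP", "CYS",
                "MET", "PHE", "VAL", "LEU", "ILE", "PRO", "HIS")) {
    net <- sum(tmpl$charge[tmpl$resname == res & !tmpl$name %in% c("OXT", "H1", "H2", "H3")])
    expect_equal(net, 0, tolerance = 1e-12, label = paste("net charge of", res))
  }
  for (res in c("ASP", "GLU")) {
    net <- sum(tmpl$charge[tmpl$resname == res & !tmpl$name %in% c("OXT", "H1", "H2", "H3")])
    expect_equal(net, -1, tolerance = 1e-12, label = paste("net charge of", res))
  }
  for (res in c("LYS", "ARG")) {
    net <- sum(tmpl$charge[tmpl$resname == res & !tmpl$name %in% c("OXT", "H1", "H2", "H3")])
    expect_equal(net, 1, tolerance = 1e-12, label = paste("net charge of", res))
  }
  # protonated histidine is +1
  tp <- charge_template("protonated")
  expect_equal(sum(tp$charge[tp$resname == "HIS" & !tp$name %in% c("OXT", "H1", "H2", "H3")]),
               1, tolerance = 1e-12)

  # assignment on complete residues built from the template geometry-free
  mk_res <- function(res) {
    rows <- tmpl[tmpl$resname == res & !tmpl$name %in% c("OXT", "H1", "H2", "H3"), ]
    atoms_df_args <- lapply(seq_len(nrow(rows)), function(i)
      at(rows$name[i], res, "A", 1, c(i, 0, 0)))
    do.call(atoms_df, atoms_df_args)
  }
  glu <- assign_charges_radii(mk_res("GLU"))
  expect_equal(total_charge(glu), -1, tolerance = 1e-12)
  lys <- assign_charges_radii(mk_res("LYS"))
  expect_equal(total_charge(lys), 1, tolerance = 1e-12)

  # idempotent and order-independent
  again <- assign_charges_radii(glu)
  expect_equal(again$atoms$charge, glu$atoms$charge)
  perm <- struct3d(glu$atoms[rev(seq_len(nrow(glu$atoms))), ])
  perm_assigned <- assign_charges_radii(perm)
  expect_equal(perm_assigned$atoms$charge,
               rev(glu$atoms$charge))

  # unknown residue names the offender; permissive downgrades to a warning
  bad <- atoms_df(at("XX1", "XYZ", "A", 1, c(0, 0, 0)))
  expect_error(assign_charges_radii(bad), "XYZ")
  expect_warning(ok <- assign_charges_radii(bad, permissive = TRUE), "XYZ")
  expect_equal(ok$atoms$charge, 0)
})

test_that("struct3d validates identity uniqueness and finiteness", {
  expect_error(atoms_df(at("CA", "GLY", "A", 1, c(0, 0, 0)),
                        at("CA", "GLY", "A", 1, c(1, 0, 0))), "duplicate")
  expect_error(atoms_df(at("CA", "GLY", "A", 1, c(NaN, 0, 0))), "finite")
  s <- make_dumbbell()
  expect_error(chain_subset(s, "Z"), "no atoms")
  expect_equal(centroid(chain_subset(s, "B")), c(20, 0, 0))
})
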