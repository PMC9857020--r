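# Synthetic fixtures: analytically solvable charge configurations, toy
# charged interfaces with standard residue/atom naming, and ensembles with
# planted per-frame contact probabilities. All stochastic generators take an
# explicit seed and drive every random choice from one R random stream
# (Mersenne-Twister), so fixtures are reproducible bit-for-bit.

.atom_row <- function(serial, name, resname, chain, resid, pos, charge, radius) {
  data.frame(serial = serial, name = name, resname = resname, chain = chain,
             resid = resid, x = pos[1], y = pos[2], z = pos[3],
             charge = charge, radius = radius, stringsAsFactors = FALSE)
}

#' Born ion fixture
#'
#' A single charged sphere at the origin: the canonical analytic test case
#' for a Poisson-Boltzmann solver, paired with [born_ion_potential()].
#'
#' @param charge charge in e.
#' @param radius sphere radius in Angstrom (> 0).
#' @return a [struct3d()] with one atom.
#' @export
make_born_ion <- function(charge = 1, radius = 2) {
  stopifnot(radius > 0)
  struct3d(.atom_row(1L, "Q", "ION", "A", 1L, c(0, 0, 0), charge, radius))
}

#' Closed-form exterior potential of a Born ion
#'
#' Debye-Hueckel solution for a charged sphere of radius `a` centred at the
#' origin, with mobile ions excluded inside `b = a + stern_radius`:
#' \deqn{\phi(r) = \frac{qC}{\varepsilon_s}\left[\frac1r -
#'   \frac{\kappa}{1+\kappa b}\right], \quad a \le r \le b}
#' \deqn{\phi(r) = \frac{qC\, e^{-\kappa (r-b)}}{\varepsilon_s r (1+\kappa b)},
#'   \quad r \ge b}
#' With `stern_radius = 0` this reduces to the textbook form
#' \eqn{qC e^{-\kappa(r-a)} / (\varepsilon_s r (1+\kappa a))}. The exterior
#' potential is independent of the solute permittivity (spherical symmetry).
#'
#' @param r radial distance(s), Angstrom (must be >= `radius`).
#' @param charge charge in e.
#' @param radius sphere radius, Angstrom.
#' @param settings a [solver_settings()] supplying solvent permittivity,
#'   ions, temperature and Stern radius.
#' @return potential in kT/e at each `r`.
#' @export
born_ion_potential <- function(r, charge, radius, settings = solver_settings()) {
  stopifnot(all(r >= radius - 1e-9))
  C <- coulomb_constant(settings$temperature)
  es <- settings$eps_solvent
  kappa <- debye_parameter(settings$ions, es, settings$temperature)
  b <- radius + settings$stern_radius
  shell <- charge * C / es * (1 / r - kappa / (1 + kappa * b))
  outer_ <- charge * C * exp(-kappa * (r - b)) / (es * r * (1 + kappa * b))
  ifelse(r < b, shell, outer_)
}

#' Two-charge dumbbell fixture
#'
#' Two single-atom chains `A` and `B` on the x axis at the given center
#' separation: the minimal fixture for force calculations (opposite charges
#' attract, like charges repel, a zero charge feels no force).
#'
#' @param q1,q2 charges in e.
#' @param separation center distance, Angstrom (> 0).
#' @param radius atom radius, Angstrom.
#' @return a [struct3d()] with two atoms in chains A and B.
#' @export
make_dumbbell <- function(q1 = 1, q2 = -1, separation = 20, radius = 1.5) {
  stopifnot(separation > 0)
  struct3d(rbind(
    .atom_row(1L, "Q", "ION", "A", 1L, c(0, 0, 0), q1, radius),
    .atom_row(2L, "Q", "ION", "B", 1L, c(separation, 0, 0), q2, radius)))
}

# rigid GLU side-chain carboxylate group, local frame: CD at origin, OE1 on +x
.glu_group <- function(resid, chain, origin, serial0) {
  rbind(
    .atom_row(serial0 + 0L, "CD", "GLU", chain, resid, origin + c(0, 0, 0), 0.62, 1.70),
    .atom_row(serial0 + 1L, "OE1", "GLU", chain, resid, origin + c(1.25, 0, 0), -0.67, 1.52),
    .atom_row(serial0 + 2L, "OE2", "GLU", chain, resid, origin + c(-0.62, 1.08, 0), -0.67, 1.52))
}

# rigid LYS ammonium group, local frame: NZ at origin, CE on +x; HZ1 points
# along -x (toward the paired carboxylate: the hydrogen-bonded salt-bridge
# geometry), HZ2/HZ3 complete the tetrahedron
.lys_group <- function(resid, chain, origin, serial0) {
  rbind(
    .atom_row(serial0 + 0L, "CE", "LYS", chain, resid, origin + c(1.50, 0, 0), 0.25, 1.70),
    .atom_row(serial0 + 1L, "NZ", "LYS", chain, resid, origin + c(0, 0, 0), -0.24, 1.55),
    .atom_row(serial0 + 2L, "HZ1", "LYS", chain, resid, origin + c(-1.04, 0, 0), 0.33, 1.00),
    .atom_row(serial0 + 3L, "HZ2", "LYS", chain, resid, origin + c(0.35, 0.96, 0), 0.33, 1.00),
    .atom_row(serial0 + 4L, "HZ3", "LYS", chain, resid, origin + c(0.35, -0.48, 0.83), 0.33, 1.00))
}

#' Paired charged-interface fixture
#'
#' Two rigid pseudo-chains facing each other across an interface: chain A
#' carries GLU carboxylate groups, chain B LYS ammonium groups, with the
#' i-th NZ-OE1 distance set to `spacing[i]` (recycled). Standard residue and
#' atom naming means [detect_salt_bridges()] and [detect_hbonds()] apply
#' unmodified.
#'
#' @param n_pairs number of acid/base pairs (>= 1).
#' @param spacing NZ-OE1 distance(s) in Angstrom, recycled to `n_pairs`.
#' @param pitch lateral distance between consecutive pairs, Angstrom.
#' @return a [struct3d()] with chains A (GLU) and B (LYS).
#' @export
make_charged_interface_pair <- function(n_pairs = 3, spacing = 3.5, pitch = 10) {
  stopifnot(n_pairs >= 1, all(spacing > 0))
  spacing <- rep_len(spacing, n_pairs)
  rows <- list()
  for (i in seq_len(n_pairs)) {
    y <- (i - 1) * pitch
    rows[[length(rows) + 1]] <-
      .glu_group(i, "A", c(0, y, 0), serial0 = (i - 1L) * 8L + 1L)
    # NZ sits at x = spacing[i] + 1.25 so that d(NZ, OE1) = spacing[i]
    rows[[length(rows) + 1]] <-
      .lys_group(i, "B", c(1.25 + spacing[i], y, 0), serial0 = (i - 1L) * 8L + 4L)
  }
  struct3d(do.call(rbind, rows))
}

#' Planted-contact trajectory
#'
#' Builds an ensemble in which specified residue pairs are in contact with
#' specified independent per-frame probabilities: in a "contact" frame the
#' mobile (chain B) residue sits at its base-structure position (built
#' inside the cutoff); in a "no contact" frame it is translated along +x to
#' twice the relevant cutoff. This tests criteria and counting, not physics.
#' Identical seeds give identical ensembles.
#'
#' @param base a [struct3d()] such as [make_charged_interface_pair()] output,
#'   with mobile residues on chain B facing partners on chain A.
#' @param contact_probabilities named numeric vector: names are chain B
#'   resids (as characters), values in [0, 1]. Alternatively an unnamed
#'   vector matching chain B's residues in resid order.
#' @param n_frames number of frames (>= 1).
#' @param seed integer RNG seed (mandatory).
#' @param cutoff the relevant contact cutoff in Angstrom (default 4.0, the
#'   salt-bridge criterion); the "out" displacement is `2 * cutoff`.
#' @param exact logical; with `exact = TRUE` each pair is in contact in
#'   exactly `round(p * n_frames)` frames (a seeded random subset) instead
#'   of independent Bernoulli draws, e.g. to plant a contact in exactly 947
#'   of 1000 frames.
#' @return an [ensemble3d()].
#' @export
make_contact_trajectory <- function(base, contact_probabilities, n_frames = 1000,
                                    seed, cutoff = 4.0, exact = FALSE) {
  stopifnot(inherits(base, "struct3d"), n_frames >= 1)
  if (missing(seed)) stop("seed is mandatory for stochastic fixtures")
  p <- contact_probabilities
  if (any(p < 0 | p > 1)) stop("contact probabilities must lie in [0, 1]")
  bres <- sort(unique(base$atoms$resid[base$atoms$chain == "B"]))
  if (is.null(names(p))) {
    if (length(p) != length(bres))
      stop("unnamed probabilities must match the number of chain B residues")
    names(p) <- as.character(bres)
  }
  if (!all(names(p) %in% as.character(bres)))
    stop("contact probabilities reference unknown chain B residues: ",
         paste(setdiff(names(p), as.character(bres)), collapse = ","))
  xyz0 <- coords(base)
  set.seed(seed)
  # one draw matrix, pair-major, from the single seeded stream; an entry
  # below p means "in contact this frame"
  if (exact) {
    draws <- matrix(1, nrow = length(p), ncol = n_frames,
                    dimnames = list(names(p), NULL))
    for (k in seq_along(p)) {
      n_in <- round(p[k] * n_frames)
      if (n_in > 0) draws[k, sample.int(n_frames, n_in)] <- 0
    }
  } else {
    draws <- matrix(runif(n_frames * length(p)), nrow = length(p),
                    dimnames = list(names(p), NULL))
  }
  frames <- vector("list", n_frames)
  rows_by_res <- lapply(names(p), function(r)
    which(base$atoms$chain == "B" & base$atoms$resid == as.integer(r)))
  for (f in seq_len(n_frames)) {
    xyz <- xyz0
    for (k in seq_along(p)) {
      if (draws[k, f] >= p[k])  # no contact: displace beyond cutoff
        xyz[rows_by_res[[k]], 1] <- xyz[rows_by_res[[k]], 1] + 2 * cutoff
    }
    frames[[f]] <- xyz
  }
  ensemble3d(base, frames)
}

# uniform random rotation matrix from the seeded stream
.random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Random two-chain contact fixture
#'
#' A randomized structure for oracle testing of the contact detectors: two
#' chains of `n_residues / 2` residues each, residue types drawn from
#' {GLU, ASP, LYS, ARG, SER, ASN}, each residue a small rigid group (with
#' polar hydrogens on donors) at a random position and orientation inside a
#' box sized so that cross-chain distances straddle the contact cutoffs.
#'
#' @param n_residues total residue count (split over chains A and B).
#' @param seed integer RNG seed.
#' @param box_edge edge of the placement box, Angstrom.
#' @return a [struct3d()].
#' @export
make_random_contact_fixture <- function(n_residues = 30, seed, box_edge = 18) {
  if (missing(seed)) stop("seed is mandatory for stochastic fixtures")
  stopifnot(n_residues >= 2)
  set.seed(seed)
  types <- c("GLU", "ASP", "LYS", "ARG", "SER", "ASN")
  local_groups <- list(
    GLU = list(names = c("CD", "OE1", "OE2"),
               pos = rbind(c(0, 0, 0), c(1.25, 0, 0), c(-0.62, 1.08, 0)),
               charge = c(0.62, -0.67, -0.67)),
    ASP = list(names = c("CG", "OD1", "OD2"),
               pos = rbind(c(0, 0, 0), c(1.25, 0, 0), c(-0.62, 1.08, 0)),
               charge = c(0.62, -0.67, -0.67)),
    LYS = list(names = c("CE", "NZ", "HZ1", "HZ2", "HZ3"),
               pos = rbind(c(1.5, 0, 0), c(0, 0, 0), c(-0.5, 0.87, 0),
                           c(-0.5, -0.44, 0.76), c(-0.5, -0.44, -0.76)),
               charge = c(0.25, -0.24, 0.33, 0.33, 0.33)),
    ARG = list(names = c("NE", "HE", "CZ", "NH1", "HH11", "HH12",
                         "NH2", "HH21", "HH22"),
               pos = rbind(c(0, 0, 0), c(-0.51, 0.86, 0), c(1.33, 0, 0),
                           c(2.0, 1.09, 0), c(1.6, 1.98, 0), c(3.0, 1.12, 0),
                           c(2.0, -1.09, 0), c(1.6, -1.98, 0), c(3.0, -1.12, 0)),
               charge = c(-0.70, 0.44, 0.64, -0.80, 0.46, 0.46, -0.80, 0.46, 0.46)),
    SER = list(names = c("CB", "OG", "HG"),
               pos = rbind(c(0, 0, 0), c(1.41, 0, 0), c(1.74, 0.89, 0)),
               charge = c(0.05, -0.48, 0.43)),
    ASN = list(names = c("CG", "OD1", "ND2", "HD21", "HD22"),
               pos = rbind(c(0, 0, 0), c(1.23, 0, 0), c(-0.68, 1.13, 0),
                           c(-1.68, 1.16, 0), c(-0.21, 2.0, 0)),
               charge = c(0.55, -0.55, -0.62, 0.31, 0.31))
  )
  n_a <- n_residues %/% 2; n_b <- n_residues - n_a
  rows <- list(); serial <- 1L
  place <- function(chain, n) {
    for (i in seq_len(n)) {
      ty <- sample(types, 1)
      grp <- local_groups[[ty]]
      rot <- .random_rotation()
      center <- runif(3, 0, box_edge) +
        if (chain == "B") c(box_edge * 0.3, 0, 0) else c(0, 0, 0)
      pos <- t(rot %*% t(grp$pos)) + matrix(center, nrow(grp$pos), 3, byrow = TRUE)
      for (j in seq_along(grp$names)) {
        rows[[length(rows) + 1]] <<- .atom_row(
          serial, grp$names[j], ty, chain, i, pos[j, ],
          grp$charge[j], .element_radius(grp$names[j]))
        serial <<- serial + 1L
      }
    }
  }
  place("A", n_a)
  place("B", n_b)
  struct3d(do.call(rbind, rows))
}
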