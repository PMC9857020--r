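#' Geometric criteria for interface contacts
#'
#' Defaults follow common trajectory-analysis practice for protein-protein
#' interfaces: hydrogen bonds at donor-acceptor distance <= 3.2 Angstrom
#' with <= 20 degrees deviation from linearity, salt bridges at <= 4.0
#' Angstrom between acidic side-chain oxygens and basic side-chain
#' nitrogens, and interfacial residues within 15 Angstrom of the opposing
#' chain. All distance comparisons are inclusive (<=).
#'
#' @param hbond_distance donor-acceptor cutoff, Angstrom.
#' @param hbond_angle angular cutoff, degrees. Interpreted per
#'   `angle_convention`.
#' @param saltbridge_distance O-N cutoff, Angstrom.
#' @param interface_cutoff interfacial-residue cutoff, Angstrom.
#' @param angle_convention `"donor_vector"` (default): angle between the
#'   D->H and D->A vectors must be <= `hbond_angle`; `"dha"`: the deviation
#'   of the D-H...A angle from 180 degrees must be <= `hbond_angle`.
#' @return object of class `contact_criteria`.
#' @export
contact_criteria <- function(hbond_distance = 3.2, hbond_angle = 20,
                             saltbridge_distance = 4.0, interface_cutoff = 15,
                             angle_convention = c("donor_vector", "dha")) {
  angle_convention <- match.arg(angle_convention)
  stopifnot(hbond_distance > 0, hbond_angle > 0,
            saltbridge_distance > 0, interface_cutoff > 0)
  structure(list(hbond_distance = hbond_distance, hbond_angle = hbond_angle,
                 saltbridge_distance = saltbridge_distance,
                 interface_cutoff = interface_cutoff,
                 angle_convention = angle_convention),
            class = "contact_criteria")
}

#' Hydrogen-bond donor chemistry table
#'
#' Rows of (resname, donor heavy atom, attached hydrogen). `resname = "*"`
#' matches any residue (the backbone amide). Covers the standard side-chain
#' donors; histidine rows apply to whichever tautomer hydrogens are present.
#'
#' @return data.frame with columns `resname`, `donor`, `hydrogen`.
#' @export
hbond_donors <- function() {
  d <- rbind(
    c("*", "N", "H"),
    c("SER", "OG", "HG"), c("THR", "OG1", "HG1"), c("TYR", "OH", "HH"),
    c("CYS", "SG", "HG"),
    c("ASN", "ND2", "HD21"), c("ASN", "ND2", "HD22"),
    c("GLN", "NE2", "HE21"), c("GLN", "NE2", "HE22"),
    c("LYS", "NZ", "HZ1"), c("LYS", "NZ", "HZ2"), c("LYS", "NZ", "HZ3"),
    c("ARG", "NE", "HE"),
    c("ARG", "NH1", "HH11"), c("ARG", "NH1", "HH12"),
    c("ARG", "NH2", "HH21"), c("ARG", "NH2", "HH22"),
    c("TRP", "NE1", "HE1"),
    c("HIS", "ND1", "HD1"), c("HIS", "NE2", "HE2")
  )
  setNames(as.data.frame(d, stringsAsFactors = FALSE),
           c("resname", "donor", "hydrogen"))
}

#' Hydrogen-bond acceptor chemistry table
#'
#' Backbone carbonyl oxygen plus standard side-chain acceptors
#' (carboxylates, amide oxygens, hydroxyl oxygens, histidine ring
#' nitrogens); thioether sulfur is excluded.
#'
#' @return data.frame with columns `resname`, `acceptor`.
#' @export
hbond_acceptors <- function() {
  a <- rbind(
    c("*", "O"), c("*", "OXT"),
    c("ASP", "OD1"), c("ASP", "OD2"), c("GLU", "OE1"), c("GLU", "OE2"),
    c("ASN", "OD1"), c("GLN", "OE1"),
    c("SER", "OG"), c("THR", "OG1"), c("TYR", "OH"),
    c("HIS", "ND1"), c("HIS", "NE2")
  )
  setNames(as.data.frame(a, stringsAsFactors = FALSE),
           c("resname", "acceptor"))
}

# acidic side-chain oxygens and basic side-chain nitrogens for salt bridges
.sb_acidic <- function() data.frame(
  resname = c("ASP", "ASP", "GLU", "GLU", "*"),
  atom = c("OD1", "OD2", "OE1", "OE2", "OXT"), stringsAsFactors = FALSE)

.sb_basic <- function(include_his = FALSE) {
  b <- data.frame(resname = c("LYS", "ARG", "ARG", "ARG"),
                  atom = c("NZ", "NE", "NH1", "NH2"), stringsAsFactors = FALSE)
  if (include_his)
    b <- rbind(b, data.frame(resname = c("HIS", "HIS"),
                             atom = c("ND1", "NE2"), stringsAsFactors = FALSE))
  b
}

.match_atoms <- function(atoms, table, atom_col) {
  hits <- lapply(seq_len(nrow(table)), function(i) {
    sel <- atoms$name == table[[atom_col]][i] &
      (table$resname[i] == "*" | atoms$resname == table$resname[i])
    atoms[sel, , drop = FALSE]
  })
  out <- do.call(rbind, hits)
  out[!duplicated(paste(out$chain, out$resid, out$name)), , drop = FALSE]
}

.cross_dist <- function(pa, pb) {
  # pairwise distance matrix between rows of two coordinate matrices
  sqrt(outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb))
}

#' Select interfacial residues of a two-chain complex
#'
#' A residue is interfacial iff any of its atoms lies within
#' `criteria$interface_cutoff` (inclusive) of any atom of the opposite side.
#'
#' @param x a [struct3d()].
#' @param chains_a,chains_b chain identifier vectors for the two sides.
#' @param criteria a [contact_criteria()].
#' @return list with data.frames `A` and `B` (columns `chain`, `resid`,
#'   `resname`), one row per interfacial residue.
#' @export
select_interfacial_residues <- function(x, chains_a, chains_b,
                                        criteria = contact_criteria()) {
  sa <- chain_subset(x, chains_a)$atoms
  sb <- chain_subset(x, chains_b)$atoms
  d <- .cross_dist(as.matrix(sa[c("x", "y", "z")]), as.matrix(sb[c("x", "y", "z")]))
  cutoff <- criteria$interface_cutoff
  near_a <- apply(d, 1, min) <= cutoff
  near_b <- apply(d, 2, min) <= cutoff
  pick <- function(at, keep) {
    r <- unique(at[keep, c("chain", "resid", "resname")])
    r <- r[order(r$chain, r$resid), , drop = FALSE]
    rownames(r) <- NULL
    r
  }
  list(A = pick(sa, near_a), B = pick(sb, near_b))
}

.hb_side <- function(atoms, donors, acceptors, heavy_only) {
  dlist <- list()
  for (i in seq_len(nrow(donors))) {
    sel <- atoms$name == donors$donor[i] &
      (donors$resname[i] == "*" | atoms$resname == donors$resname[i])
    dd <- atoms[sel, , drop = FALSE]
    if (!nrow(dd)) next
    hmatch <- match(paste(dd$chain, dd$resid, donors$hydrogen[i]),
                    paste(atoms$chain, atoms$resid, atoms$name))
    dd$hx <- atoms$x[hmatch]; dd$hy <- atoms$y[hmatch]; dd$hz <- atoms$z[hmatch]
    dd$hydrogen <- ifelse(is.na(hmatch), NA_character_, donors$hydrogen[i])
    dlist[[length(dlist) + 1]] <- dd
  }
  don <- if (length(dlist)) do.call(rbind, dlist) else atoms[0, ]
  if (nrow(don)) {
    has_h <- !is.na(don$hydrogen)
    # a donor heavy atom qualifies if any of its template hydrogens exists
    donor_key <- paste(don$chain, don$resid, don$name)
    ok_key <- unique(donor_key[has_h])
    if (!heavy_only) {
      missing <- !(donor_key %in% ok_key)
      if (any(missing))
        stop("donors without hydrogens (add hydrogens or use heavy_only = TRUE): ",
             paste(unique(paste0(don$resname[missing], don$resid[missing], ":",
                                 don$name[missing])), collapse = ", "))
      don <- don[has_h, , drop = FALSE]
    } else {
      don <- don[!duplicated(donor_key), , drop = FALSE]
    }
  }
  acc <- .match_atoms(atoms, acceptors, "acceptor")
  list(don = don, acc = acc)
}

#' Detect cross-chain hydrogen bonds in one structure/frame
#'
#' A donor-acceptor pair is a hydrogen bond when the D...A distance is
#' within `criteria$hbond_distance` and the geometry deviates from linearity
#' by at most `criteria$hbond_angle` degrees (see
#' [contact_criteria()] for the two angle conventions). With
#' `heavy_only = TRUE` the angle test is skipped (distance-only criterion
#' for hydrogen-free structures; reports are labelled accordingly upstream).
#'
#' @param x a [struct3d()] (one frame).
#' @param chains_a,chains_b the two sides of the interface.
#' @param criteria a [contact_criteria()].
#' @param heavy_only logical; fall back to the distance-only criterion.
#' @param donors,acceptors chemistry tables, see [hbond_donors()].
#' @return data.frame, one row per bond: donor side (`chain_d`, `resid_d`,
#'   `resname_d`, `donor`, `hydrogen`), acceptor side (`chain_a`, `resid_a`,
#'   `resname_a`, `acceptor`), `distance` (Angstrom) and `angle` (degrees,
#'   NA when `heavy_only`).
#' @export
detect_hbonds <- function(x, chains_a, chains_b,
                          criteria = contact_criteria(), heavy_only = FALSE,
                          donors = hbond_donors(), acceptors = hbond_acceptors()) {
  stopifnot(inherits(x, "struct3d"))
  atoms_a <- chain_subset(x, chains_a)$atoms
  atoms_b <- chain_subset(x, chains_b)$atoms
  side_a <- .hb_side(atoms_a, donors, acceptors, heavy_only)
  side_b <- .hb_side(atoms_b, donors, acceptors, heavy_only)
  one_dir <- function(don, acc) {
    if (!nrow(don) || !nrow(acc)) return(NULL)
    dmat <- .cross_dist(as.matrix(don[c("x", "y", "z")]),
                        as.matrix(acc[c("x", "y", "z")]))
    hit <- which(dmat <= criteria$hbond_distance, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    di <- hit[, 1]; ai <- hit[, 2]
    ang <- rep(NA_real_, nrow(hit))
    if (!heavy_only) {
      vda <- cbind(acc$x[ai] - don$x[di], acc$y[ai] - don$y[di], acc$z[ai] - don$z[di])
      if (criteria$angle_convention == "donor_vector") {
        vdh <- cbind(don$hx[di] - don$x[di], don$hy[di] - don$y[di], don$hz[di] - don$z[di])
        cosang <- rowSums(vda * vdh) /
          (sqrt(rowSums(vda^2)) * sqrt(rowSums(vdh^2)))
      } else {
        vhd <- cbind(don$x[di] - don$hx[di], don$y[di] - don$hy[di], don$z[di] - don$hz[di])
        vha <- cbind(acc$x[ai] - don$hx[di], acc$y[ai] - don$hy[di], acc$z[ai] - don$hz[di])
        # deviation from linearity: 180 - angle(D-H...A)
        cosdha <- rowSums(vhd * vha) /
          (sqrt(rowSums(vhd^2)) * sqrt(rowSums(vha^2)))
        cosang <- -cosdha
      }
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    }
    out <- data.frame(
      chain_d = don$chain[di], resid_d = don$resid[di], resname_d = don$resname[di],
      donor = don$name[di], hydrogen = don$hydrogen[di],
      chain_a = acc$chain[ai], resid_a = acc$resid[ai], resname_a = acc$resname[ai],
      acceptor = acc$name[ai],
      distance = dmat[hit], angle = ang, stringsAsFactors = FALSE)
    if (!heavy_only) out <- out[out$angle <= criteria$hbond_angle, , drop = FALSE]
    # several hydrogens of one donor can satisfy the criterion; keep the
    # most linear one per (donor atom, acceptor atom) pair
    key <- paste(out$chain_d, out$resid_d, out$donor, out$chain_a, out$resid_a, out$acceptor)
    out <- out[order(key, out$angle), , drop = FALSE]
    out[!duplicated(paste(out$chain_d, out$resid_d, out$donor,
                          out$chain_a, out$resid_a, out$acceptor)), , drop = FALSE]
  }
  res <- rbind(one_dir(side_a$don, side_b$acc), one_dir(side_b$don, side_a$acc))
  if (is.null(res)) res <- data.frame(
    chain_d = character(0), resid_d = integer(0), resname_d = character(0),
    donor = character(0), hydrogen = character(0),
    chain_a = character(0), resid_a = integer(0), resname_a = character(0),
    acceptor = character(0), distance = numeric(0), angle = numeric(0),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Detect cross-chain salt bridges in one structure/frame
#'
#' A residue pair forms a salt bridge when the minimum distance between any
#' acidic side-chain oxygen (ASP OD1/OD2, GLU OE1/OE2, C-terminal OXT) and
#' any basic side-chain nitrogen (LYS NZ, ARG NE/NH1/NH2, and protonated
#' histidine ring nitrogens when `include_his = TRUE`) is within
#' `criteria$saltbridge_distance` (inclusive).
#'
#' @param x a [struct3d()] (one frame).
#' @param chains_a,chains_b the two sides of the interface.
#' @param criteria a [contact_criteria()].
#' @param include_his treat HIS ring nitrogens as basic (protonated state).
#' @return data.frame, one row per residue pair: acid side (`chain_acid`,
#'   `resid_acid`, `resname_acid`, `atom_acid`), base side (`chain_base`,
#'   `resid_base`, `resname_base`, `atom_base`) and `distance` (the minimal
#'   O-N distance, with the atoms achieving it).
#' @export
detect_salt_bridges <- function(x, chains_a, chains_b,
                                criteria = contact_criteria(),
                                include_his = FALSE) {
  stopifnot(inherits(x, "struct3d"))
  atoms_a <- chain_subset(x, chains_a)$atoms
  atoms_b <- chain_subset(x, chains_b)$atoms
  acid_tab <- .sb_acidic(); base_tab <- .sb_basic(include_his)
  one_dir <- function(acid_atoms, base_atoms) {
    ac <- .match_atoms(acid_atoms, acid_tab, "atom")
    ba <- .match_atoms(base_atoms, base_tab, "atom")
    if (!nrow(ac) || !nrow(ba)) return(NULL)
    dmat <- .cross_dist(as.matrix(ac[c("x", "y", "z")]),
                        as.matrix(ba[c("x", "y", "z")]))
    hit <- which(dmat <= criteria$saltbridge_distance, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    out <- data.frame(
      chain_acid = ac$chain[hit[, 1]], resid_acid = ac$resid[hit[, 1]],
      resname_acid = ac$resname[hit[, 1]], atom_acid = ac$name[hit[, 1]],
      chain_base = ba$chain[hit[, 2]], resid_base = ba$resid[hit[, 2]],
      resname_base = ba$resname[hit[, 2]], atom_base = ba$name[hit[, 2]],
      distance = dmat[hit], stringsAsFactors = FALSE)
    # residue-pair level: keep the closest O-N atom pair
    key <- paste(out$chain_acid, out$resid_acid, out$chain_base, out$resid_base)
    out <- out[order(key, out$distance), , drop = FALSE]
    out[!duplicated(paste(out$chain_acid, out$resid_acid,
                          out$chain_base, out$resid_base)), , drop = FALSE]
  }
  res <- rbind(one_dir(atoms_a, atoms_b), one_dir(atoms_b, atoms_a))
  if (is.null(res)) res <- data.frame(
    chain_acid = character(0), resid_acid = integer(0), resname_acid = character(0),
    atom_acid = character(0), chain_base = character(0), resid_base = integer(0),
    resname_base = character(0), atom_base = character(0), distance = numeric(0),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
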