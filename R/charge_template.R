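# Residue charge/radius template used to promote plain-PDB input to the
# charged representation the solver needs. The table is a deliberately
# simple, self-contained charge set: per-residue net charges are exact
# integers for the standard titratable states (ASP/GLU -1, LYS/ARG +1, HIS
# neutral by default), with partial charges concentrated on the polar
# backbone and on the charged/polar side-chain groups. It is not a full
# molecular-mechanics force field; see the methods vignette.

.element_radius <- function(name) {
  el <- substr(gsub("^[0-9]+", "", name), 1, 1)
  r <- c(H = 1.00, C = 1.70, N = 1.55, O = 1.52, S = 1.80)[el]
  ifelse(is.na(r), 1.70, r)
}

.template_rows <- function(resname, names, charges) {
  stopifnot(length(names) == length(charges))
  data.frame(resname = rep(resname, length(names)), name = names,
             charge = charges, stringsAsFactors = FALSE)
}

#' Residue charge and radius template table
#'
#' Mapping (resname, atom name) -> (partial charge e, vdW radius Angstrom)
#' for the 20 standard amino acids plus N-/C-terminal patch atoms. Net
#' side-chain + backbone charge is 0 for neutral residues, -1 for ASP/GLU,
#' +1 for LYS/ARG; histidine is provided in a neutral (`HIS`) and a
#' protonated (`HIS+`) state. Radii follow a per-element Bondi-like set
#' (H 1.0, C 1.7, N 1.55, O 1.52, S 1.8).
#'
#' @param histidine_state `"neutral"` (default, single delta-protonated
#'   tautomer) or `"protonated"` (+1).
#' @return data.frame with columns `resname`, `name`, `charge`, `radius`.
#' @export
charge_template <- function(histidine_state = c("neutral", "protonated")) {
  histidine_state <- match.arg(histidine_state)
  bb <- function(res) .template_rows(res, c("N", "H", "CA", "C", "O"),
                                     c(-0.47, 0.31, 0.16, 0.51, -0.51))
  side <- list(
    GLY = .template_rows("GLY", character(0), numeric(0)),
    ALA = .template_rows("ALA", "CB", 0),
    VAL = .template_rows("VAL", c("CB", "CG1", "CG2"), c(0, 0, 0)),
    LEU = .template_rows("LEU", c("CB", "CG", "CD1", "CD2"), rep(0, 4)),
    ILE = .template_rows("ILE", c("CB", "CG1", "CG2", "CD1"), rep(0, 4)),
    MET = .template_rows("MET", c("CB", "CG", "SD", "CE"), c(0, 0.06, -0.12, 0.06)),
    PHE = .template_rows("PHE", c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"), rep(0, 7)),
    TYR = .template_rows("TYR", c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH", "HH"),
                         c(0, 0, 0, 0, 0, 0, 0.11, -0.54, 0.43)),
    TRP = .template_rows("TRP", c("CB", "CG", "CD1", "CD2", "NE1", "HE1", "CE2",
                                  "CE3", "CZ2", "CZ3", "CH2"),
                         c(0, 0, 0, 0, -0.43, 0.43, 0, 0, 0, 0, 0)),
    SER = .template_rows("SER", c("CB", "OG", "HG"), c(0.05, -0.48, 0.43)),
    THR = .template_rows("THR", c("CB", "OG1", "HG1", "CG2"), c(0.05, -0.48, 0.43, 0)),
    CYS = .template_rows("CYS", c("CB", "SG", "HG"), c(0.11, -0.54, 0.43)),
    ASN = .template_rows("ASN", c("CB", "CG", "OD1", "ND2", "HD21", "HD22"),
                         c(0, 0.55, -0.55, -0.62, 0.31, 0.31)),
    GLN = .template_rows("GLN", c("CB", "CG", "CD", "OE1", "NE2", "HE21", "HE22"),
                         c(0, 0, 0.55, -0.55, -0.62, 0.31, 0.31)),
    ASP = .template_rows("ASP", c("CB", "CG", "OD1", "OD2"),
                         c(-0.28, 0.62, -0.67, -0.67)),
    GLU = .template_rows("GLU", c("CB", "CG", "CD", "OE1", "OE2"),
                         c(0, -0.28, 0.62, -0.67, -0.67)),
    LYS = .template_rows("LYS", c("CB", "CG", "CD", "CE", "NZ", "HZ1", "HZ2", "HZ3"),
                         c(0, 0, 0, 0.25, -0.24, 0.33, 0.33, 0.33)),
    ARG = .template_rows("ARG", c("CB", "CG", "CD", "NE", "HE", "CZ",
                                  "NH1", "HH11", "HH12", "NH2", "HH21", "HH22"),
                         c(0, 0, 0.38, -0.70, 0.44, 0.64,
                           -0.80, 0.46, 0.46, -0.80, 0.46, 0.46)),
    PRO = .template_rows("PRO", c("CB", "CG", "CD"), c(0, 0, 0))
  )
  his_neutral <- .template_rows("HIS", c("CB", "CG", "ND1", "HD1", "CD2", "CE1", "NE2"),
                                c(0, 0, -0.36, 0.36, 0, 0.36, -0.36))
  his_prot <- .template_rows("HIS", c("CB", "CG", "ND1", "HD1", "CD2", "CE1", "NE2", "HE2"),
                             c(0.25, 0.25, -0.36, 0.36, 0, 0.50, -0.36, 0.36))
  side$HIS <- if (histidine_state == "neutral") his_neutral else his_prot
  resnames <- names(side)
  tab <- do.call(rbind, c(
    lapply(resnames, function(r) {
      b <- bb(r)
      if (r == "PRO") b <- b[b$name != "H", ]  # proline backbone N carries no H
      rbind(b, side[[r]])
    })
  ))
  # terminal patches: OXT closes the C-terminal carboxylate at -1 e;
  # H1/H2/H3 replace the single backbone H at a charged N-terminus
  # (net -0.31 + 1.31 = +1 e for the residue).
  term <- do.call(rbind, lapply(resnames, function(r)
    .template_rows(r, c("OXT", "H1", "H2", "H3"), c(-1.00, 0.44, 0.44, 0.43))))
  tab <- rbind(tab, term)
  # proline backbone correction: no H, so N absorbs its charge
  tab$charge[tab$resname == "PRO" & tab$name == "N"] <- -0.16
  tab$radius <- .element_radius(tab$name)
  rownames(tab) <- NULL
  tab
}

#' Assign partial charges and vdW radii from the residue template
#'
#' Every atom whose (resname, atom name) appears in the template gains the
#' template charge and radius; a complete residue then carries its integer
#' formal charge. Unknown residues or atom names raise an error listing the
#' offending (resname, name) pairs, unless `permissive = TRUE`, in which
#' case they are assigned charge 0 and an element-based radius with a
#' warning. The operation is idempotent and independent of atom order.
#'
#' @param x a [struct3d()].
#' @param table template table from [charge_template()] (or a compatible
#'   data.frame with columns resname/name/charge/radius).
#' @param permissive logical; downgrade unknown atoms to a warning.
#' @return a [struct3d()] with `charge` and `radius` populated.
#' @export
assign_charges_radii <- function(x, table = charge_template(), permissive = FALSE) {
  stopifnot(inherits(x, "struct3d"))
  a <- x$atoms
  key <- paste(a$resname, a$name)
  tkey <- paste(table$resname, table$name)
  idx <- match(key, tkey)
  unknown <- is.na(idx)
  if (any(unknown)) {
    offending <- unique(paste0("(", a$resname[unknown], ", ", a$name[unknown], ")"))
    msg <- paste("atoms without template entry:", paste(offending, collapse = " "))
    if (!permissive) stop(msg)
    warning(msg, "; assigned charge 0")
  }
  a$charge <- ifelse(unknown, 0, table$charge[idx])
  a$radius <- ifelse(unknown, .element_radius(a$name), table$radius[idx])
  struct3d(a)
}
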