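# File I/O for structures and ensembles. Parsing of PDB/PQR/DCD is delegated
# to bio3d; these wrappers convert to/from the package's struct3d container
# and add the validation and error reporting the pipeline relies on.

.bio3d_to_atoms <- function(pdb) {
  a <- pdb$atom
  data.frame(
    serial = a$eleno, name = a$elety, resname = a$resid,
    chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    resid = a$resno,
    x = a$x, y = a$y, z = a$z,
    charge = if ("o" %in% names(a)) a$o else NA_real_,
    radius = if ("b" %in% names(a)) a$b else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Read a PQR file
#'
#' Reads the whitespace-delimited PQR dialect used by DelPhi/APBS-family
#' tools: `ATOM`/`HETATM` records with fields serial, atom name, residue
#' name, optional chain, residue number, x, y, z, charge (e), radius
#' (Angstrom). This dialect is token- rather than column-oriented, so it is
#' parsed directly (fixed-column PDB readers mis-split wide or shifted
#' fields).
#'
#' @param path PQR file path.
#' @return a [struct3d()] with charges and radii populated.
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM|HETATM)", lines)
  if (!length(rec)) stop("no atoms in PQR file: ", path)
  parse_line <- function(i) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (!length(tok) %in% c(10, 11))
      stop(sprintf("malformed PQR line %d: expected 10 or 11 whitespace-separated fields, got %d",
                   i, length(tok)))
    num <- suppressWarnings(as.numeric(utils::tail(tok, 5)))
    if (anyNA(num))
      stop(sprintf("malformed PQR line %d: coordinate/charge/radius fields are not numeric",
                   i))
    has_chain <- length(tok) == 11
    resid <- suppressWarnings(as.integer(tok[if (has_chain) 6 else 5]))
    if (is.na(resid))
      stop(sprintf("malformed PQR line %d: residue number is not an integer", i))
    data.frame(serial = suppressWarnings(as.integer(tok[2])),
               name = tok[3], resname = tok[4],
               chain = if (has_chain) tok[5] else "A",
               resid = resid,
               x = num[1], y = num[2], z = num[3],
               charge = num[4], radius = num[5], stringsAsFactors = FALSE)
  }
  struct3d(do.call(rbind, lapply(rec, parse_line)))
}

#' Write a PQR file
#'
#' Columns are both fixed-width and whitespace-separated, readable by
#' DelPhi/APBS-style tools and by [read_pqr()]. Charges are written with 4
#' decimals and radii with 4 decimals; a read-back therefore reproduces them
#' to that precision.
#'
#' @param x a [struct3d()] with charges and radii set.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(x, path) {
  stopifnot(inherits(x, "struct3d"))
  a <- x$atoms
  if (anyNA(a$charge) || anyNA(a$radius))
    stop("cannot write PQR: charges/radii unset (run assign_charges_radii first)")
  lines <- sprintf("ATOM  %5d %-4s %-4s %1s %4d    %8.3f %8.3f %8.3f %8.4f %7.4f",
                   a$serial, a$name, a$resname, a$chain, a$resid,
                   a$x, a$y, a$z, a$charge, a$radius)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a PDB file (single model)
#'
#' Charges and radii are left unset (`NA`); use [assign_charges_radii()] to
#' populate them from the packaged residue template table. If the file holds
#' several MODEL records only the first is returned, with a warning.
#'
#' @param path PDB file path.
#' @return a [struct3d()] with `charge`/`radius` columns `NA`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!any(grepl("^(ATOM|HETATM)", readLines(path, warn = FALSE))))
    stop("no atoms in PDB file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e)))
  nmod <- nrow(pdb$xyz)
  if (!is.null(nmod) && nmod > 1)
    warning(sprintf("multi-model PDB: using first of %d models (use read_ensemble for all frames)",
                    nmod))
  atoms <- .bio3d_to_atoms(pdb)
  atoms$charge <- NA_real_
  atoms$radius <- NA_real_
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  if (any(!is.finite(xyz))) stop("non-numeric coordinate field in ", path)
  atoms[c("x", "y", "z")] <- xyz
  struct3d(atoms)
}

#' Read a conformational ensemble
#'
#' Accepts a multi-model PDB (each MODEL becomes a frame) or a DCD
#' trajectory plus a separate topology file (PDB or PQR). A `frame_range`
#' may be given to keep only part of the trajectory, e.g. `"last 50%"` for
#' the stable tail of a run.
#'
#' @param path multi-model PDB path, or DCD path when `topology` is given.
#' @param topology optional topology: a [struct3d()] or a PDB/PQR path.
#'   Required for DCD input; for multi-model PDB it overrides the identities
#'   parsed from the file (atom counts must agree) and supplies
#'   charges/radii.
#' @param frame_range optional frame selection passed to [select_frames()].
#' @return an [ensemble3d()].
#' @export
read_ensemble <- function(path, topology = NULL, frame_range = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  topo <- NULL
  if (!is.null(topology)) {
    topo <- if (inherits(topology, "struct3d")) topology
            else if (grepl("\\.pqr$", topology, ignore.case = TRUE)) read_pqr(topology)
            else read_pdb(topology)
  }
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    if (is.null(topo)) stop("DCD input requires a topology")
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    if (is.null(topo)) {
      atoms <- .bio3d_to_atoms(pdb)
      atoms$charge <- NA_real_; atoms$radius <- NA_real_
      atoms[c("x", "y", "z")] <- matrix(xyz[1, ], ncol = 3, byrow = TRUE)
      topo <- struct3d(atoms)
    }
  }
  n <- nrow(topo$atoms)
  if (ncol(xyz) != 3 * n)
    stop(sprintf("atom-count mismatch: frames have %d atoms, topology has %d",
                 ncol(xyz) / 3, n))
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  ens <- ensemble3d(topo, frames)
  if (!is.null(frame_range)) ens <- select_frames(ens, frame_range)
  ens
}

#' Write an ensemble as a multi-model PDB
#'
#' The portable plain-text trajectory format used by the package's fixtures:
#' one MODEL/ENDMDL block per frame.
#'
#' @param x an [ensemble3d()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(x, path) {
  stopifnot(inherits(x, "ensemble3d"))
  a <- x$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x$frames)) {
    f <- x$frames[[i]]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                       a$serial, a$name, a$resname, a$chain, a$resid,
                       f[, 1], f[, 2], f[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
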