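#' Atomic structure container
#'
#' A `struct3d` holds an ordered table of atoms with coordinates (Angstrom),
#' partial charges (e) and radii (Angstrom). Charges/radii may be `NA` for
#' plain-PDB input until [assign_charges_radii()] is applied.
#'
#' @param atoms data.frame with columns `serial` (integer), `name`,
#'   `resname`, `chain` (character), `resid` (integer), `x`, `y`, `z`
#'   (numeric, Angstrom), `charge` (e, may be NA), `radius` (Angstrom, may
#'   be NA).
#' @return object of class `struct3d`.
#' @export
struct3d <- function(atoms) {
  req <- c("serial", "name", "resname", "chain", "resid",
           "x", "y", "z", "charge", "radius")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0) stop("no atoms")
  atoms <- as.data.frame(atoms)[req]
  atoms$serial <- as.integer(atoms$serial)
  atoms$resid <- as.integer(atoms$resid)
  for (cc in c("name", "resname", "chain")) atoms[[cc]] <- as.character(atoms[[cc]])
  for (cc in c("x", "y", "z", "charge", "radius")) atoms[[cc]] <- as.numeric(atoms[[cc]])
  if (any(!is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(!is.na(atoms$radius) & atoms$radius < 0))
    stop("negative atom radius")
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, resid, name) atom identities: ",
         paste(unique(key[duplicated(key)])[1:min(3, sum(duplicated(key)))],
               collapse = "; "))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "struct3d")
}

#' @export
print.struct3d <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("struct3d: %d atoms, %d residues, chains %s\n",
              nrow(a), length(unique(paste(a$chain, a$resid))),
              paste(sort(unique(a$chain)), collapse = ",")))
  tq <- total_charge(x)
  cat(sprintf("  total charge: %s e, charges %s\n",
              if (is.na(tq)) "NA" else format(tq, digits = 4),
              if (anyNA(a$charge)) "unset for some atoms" else "set"))
  invisible(x)
}

#' Coordinates of a structure as an n x 3 matrix
#' @param x a `struct3d`.
#' @return numeric matrix (Angstrom).
#' @export
coords <- function(x) {
  stopifnot(inherits(x, "struct3d"))
  as.matrix(x$atoms[c("x", "y", "z")])
}

#' Total charge of a structure
#' @param x a `struct3d`.
#' @return sum of atomic partial charges (e); `NA` if any charge unset.
#' @export
total_charge <- function(x) {
  stopifnot(inherits(x, "struct3d"))
  if (anyNA(x$atoms$charge)) return(NA_real_)
  sum(x$atoms$charge)
}

#' Geometric center (unweighted centroid) of a structure
#'
#' Atomic masses are not carried by PQR input, so the "center of mass" used
#' for separation axes is the unweighted centroid of atom positions.
#'
#' @param x a `struct3d`.
#' @return length-3 numeric vector (Angstrom).
#' @export
centroid <- function(x) unname(colMeans(coords(x)))

#' Subset a structure by chain identifiers
#' @param x a `struct3d`.
#' @param chains character vector of chain ids to keep.
#' @return a `struct3d` with only the selected chains.
#' @export
chain_subset <- function(x, chains) {
  stopifnot(inherits(x, "struct3d"))
  keep <- x$atoms$chain %in% chains
  if (!any(keep))
    stop("no atoms in chains: ", paste(chains, collapse = ","))
  struct3d(x$atoms[keep, , drop = FALSE])
}

#' Rigidly translate a structure
#' @param x a `struct3d`.
#' @param shift length-3 numeric vector (Angstrom).
#' @return translated `struct3d`.
#' @export
translate_struct <- function(x, shift) {
  stopifnot(inherits(x, "struct3d"), length(shift) == 3, all(is.finite(shift)))
  a <- x$atoms
  a$x <- a$x + shift[1]; a$y <- a$y + shift[2]; a$z <- a$z + shift[3]
  struct3d(a)
}

#' Concatenate two structures
#'
#' Chains must be disjoint; atom serials are renumbered sequentially.
#'
#' @param a,b `struct3d` objects.
#' @return combined `struct3d`.
#' @export
combine_structs <- function(a, b) {
  stopifnot(inherits(a, "struct3d"), inherits(b, "struct3d"))
  if (length(intersect(unique(a$atoms$chain), unique(b$atoms$chain))))
    stop("structures share chain identifiers")
  atoms <- rbind(a$atoms, b$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  struct3d(atoms)
}

#' Conformational ensemble (topology + frames)
#'
#' @param topology a `struct3d` giving atom identities (frame 1 coordinates
#'   are not required to match any frame).
#' @param frames list of n_atoms x 3 coordinate matrices, one per frame.
#' @return object of class `ensemble3d`.
#' @export
ensemble3d <- function(topology, frames) {
  stopifnot(inherits(topology, "struct3d"), is.list(frames))
  if (length(frames) < 1) stop("ensemble must have at least 1 frame")
  n <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || ncol(f) != 3 || nrow(f) != n)
      stop(sprintf("frame %d has %d coordinates; topology has %d atoms",
                   i, if (is.matrix(f)) nrow(f) else -1L, n))
    if (any(!is.finite(f))) stop(sprintf("frame %d has non-finite coordinates", i))
    dimnames(frames[[i]]) <- NULL
  }
  structure(list(topology = topology, frames = frames), class = "ensemble3d")
}

#' @export
print.ensemble3d <- function(x, ...) {
  cat(sprintf("ensemble3d: %d frames x %d atoms\n",
              length(x$frames), nrow(x$topology$atoms)))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param x an `ensemble3d`.
#' @return integer frame count.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "ensemble3d"))
  length(x$frames)
}

#' Structure of a single ensemble frame
#' @param x an `ensemble3d`.
#' @param i frame index.
#' @return `struct3d` with the topology's identities and frame `i` coordinates.
#' @export
frame_struct <- function(x, i) {
  stopifnot(inherits(x, "ensemble3d"), i >= 1, i <= length(x$frames))
  a <- x$topology$atoms
  a[c("x", "y", "z")] <- x$frames[[i]]
  struct3d(a)
}

#' Select a frame range from an ensemble
#'
#' Supports the convention of analysing only the stable tail of a
#' trajectory (e.g. the last half of the frames, mirroring "last 5 ns of a
#' 10 ns run").
#'
#' @param x an `ensemble3d`.
#' @param range either an integer vector of frame indices, or a string
#'   `"last p%"` / `"first p%"` (e.g. `"last 50%"`).
#' @return an `ensemble3d` with only the selected frames (order preserved).
#' @export
select_frames <- function(x, range) {
  stopifnot(inherits(x, "ensemble3d"))
  nf <- length(x$frames)
  if (is.character(range)) {
    m <- regmatches(range, regexec("^(last|first) *([0-9.]+)%$", range))[[1]]
    if (length(m) != 3) stop("unrecognised frame range: ", range)
    k <- max(1L, round(nf * as.numeric(m[3]) / 100))
    idx <- if (m[2] == "last") (nf - k + 1L):nf else 1L:k
  } else {
    idx <- as.integer(range)
    if (any(idx < 1 | idx > nf)) stop("frame index out of bounds")
  }
  ensemble3d(x$topology, x$frames[idx])
}
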