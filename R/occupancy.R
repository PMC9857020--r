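# Per-frame contact series and occupancy tables with reporting tiers.
# Occupancy = 100 * (frames with the contact) / (frames analysed); pairs
# below the minimum occupancy (default 10%, inclusive: ">= 10% kept") are
# dropped from reports; tiers mark pairs above 40% and above 80%.

.pair_records <- function(contacts, kind) {
  if (kind == "hbond") {
    data.frame(
      pair_id = paste0(contacts$chain_d, ":", contacts$resid_d, ":",
                       contacts$resname_d, ":", contacts$donor, "->",
                       contacts$chain_a, ":", contacts$resid_a, ":",
                       contacts$resname_a, ":", contacts$acceptor),
      chain_1 = contacts$chain_d, resid_1 = contacts$resid_d,
      resname_1 = contacts$resname_d, atom_1 = contacts$donor,
      chain_2 = contacts$chain_a, resid_2 = contacts$resid_a,
      resname_2 = contacts$resname_a, atom_2 = contacts$acceptor,
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      pair_id = paste0(contacts$chain_acid, ":", contacts$resid_acid, ":",
                       contacts$resname_acid, "--",
                       contacts$chain_base, ":", contacts$resid_base, ":",
                       contacts$resname_base),
      chain_1 = contacts$chain_acid, resid_1 = contacts$resid_acid,
      resname_1 = contacts$resname_acid, atom_1 = contacts$atom_acid,
      chain_2 = contacts$chain_base, resid_2 = contacts$resid_base,
      resname_2 = contacts$resname_base, atom_2 = contacts$atom_base,
      stringsAsFactors = FALSE)
  }
}

.tier_label <- function(occ) ifelse(occ > 80, ">80", ifelse(occ > 40, ">40", ">=10"))

#' Contact occupancy over a conformational ensemble
#'
#' Runs [detect_hbonds()] or [detect_salt_bridges()] on every frame,
#' records per-pair presence, and reports occupancy percentages. Hydrogen
#' bonds are keyed by (donor atom, acceptor atom); salt bridges by residue
#' pair (the representative atom names come from the first frame in which
#' the pair appears). Pairs below `min_occupancy` are excluded from the
#' table (inclusive: exactly `min_occupancy` is kept); tiers label pairs
#' above 40% and above 80%. Interfacial-residue preselection at
#' `criteria$interface_cutoff` is applied on the first frame purely as a
#' performance prefilter; it cannot change the result because the contact
#' cutoffs are far smaller than the interface cutoff.
#'
#' @param ensemble an [ensemble3d()] (already trimmed to the frames to
#'   analyse, e.g. with [select_frames()]).
#' @param chains_a,chains_b the two sides of the interface.
#' @param kind `"hbond"` or `"saltbridge"`.
#' @param criteria a [contact_criteria()].
#' @param min_occupancy reporting threshold in percent (default 10).
#' @param ... passed to the per-frame detector (`heavy_only`, `include_his`,
#'   chemistry tables).
#' @return an `occupancy_table`: list with `pairs` (data.frame: `pair_id`,
#'   identity columns, `n_present`, `n_frames`, `occupancy`, `tier`),
#'   `residues` (per-residue aggregate, see [aggregate_by_residue()]),
#'   `series` (logical pairs x frames presence matrix for retained pairs),
#'   `kind`, `n_frames`.
#' @export
compute_occupancy <- function(ensemble, chains_a, chains_b,
                              kind = c("hbond", "saltbridge"),
                              criteria = contact_criteria(),
                              min_occupancy = 10, ...) {
  kind <- match.arg(kind)
  stopifnot(inherits(ensemble, "ensemble3d"))
  nf <- n_frames(ensemble)
  if (nf < 1) stop("ensemble has no frames")
  detector <- if (kind == "hbond") detect_hbonds else detect_salt_bridges
  # interface prefilter on frame 1
  f1 <- frame_struct(ensemble, 1)
  iface <- select_interfacial_residues(f1, chains_a, chains_b, criteria)
  keep_res <- c(paste(iface$A$chain, iface$A$resid), paste(iface$B$chain, iface$B$resid))
  topo <- ensemble$topology$atoms
  keep_atoms <- paste(topo$chain, topo$resid) %in% keep_res
  presence <- list(); meta <- list()
  for (i in if (nrow(iface$A) && nrow(iface$B)) seq_len(nf) else integer(0)) {
    fs <- frame_struct(ensemble, i)
    fs <- struct3d(fs$atoms[keep_atoms, , drop = FALSE])
    contacts <- detector(fs, chains_a, chains_b, criteria, ...)
    if (!nrow(contacts)) next
    rec <- .pair_records(contacts, kind)
    for (j in seq_len(nrow(rec))) {
      id <- rec$pair_id[j]
      if (is.null(presence[[id]])) {
        presence[[id]] <- logical(nf)
        meta[[id]] <- rec[j, , drop = FALSE]
      }
      presence[[id]][i] <- TRUE
    }
  }
  if (length(presence)) {
    series <- do.call(rbind, presence)
    rownames(series) <- names(presence)
    pairs <- do.call(rbind, meta)
    pairs$n_present <- rowSums(series)
    pairs$n_frames <- nf
    pairs$occupancy <- 100 * pairs$n_present / nf
    keep <- pairs$occupancy >= min_occupancy
    pairs <- pairs[keep, , drop = FALSE]
    series <- series[keep, , drop = FALSE]
    pairs$tier <- .tier_label(pairs$occupancy)
    ord <- order(-pairs$occupancy, pairs$chain_1, pairs$resid_1, pairs$atom_1,
                 pairs$chain_2, pairs$resid_2, pairs$atom_2)
    pairs <- pairs[ord, , drop = FALSE]
    series <- series[ord, , drop = FALSE]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(pair_id = character(0), chain_1 = character(0),
                        resid_1 = integer(0), resname_1 = character(0),
                        atom_1 = character(0), chain_2 = character(0),
                        resid_2 = integer(0), resname_2 = character(0),
                        atom_2 = character(0), n_present = integer(0),
                        n_frames = integer(0), occupancy = numeric(0),
                        tier = character(0), stringsAsFactors = FALSE)
    series <- matrix(FALSE, 0, nf)
  }
  out <- structure(list(pairs = pairs, series = series, kind = kind,
                        n_frames = nf), class = "occupancy_table")
  out$residues <- aggregate_by_residue(out)
  out
}

#' @export
print.occupancy_table <- function(x, ...) {
  cat(sprintf("occupancy_table (%s): %d retained pairs over %d frames\n",
              x$kind, nrow(x$pairs), x$n_frames))
  if (nrow(x$pairs))
    print(utils::head(x$pairs[c("pair_id", "occupancy", "tier")], 10))
  invisible(x)
}

#' Per-residue occupancy aggregate
#'
#' For each residue appearing in a retained pair: union occupancy = 100 *
#' (frames in which the residue participates in at least one retained
#' contact) / frames, and a multi-partner flag set when the residue appears
#' in two or more retained pairs (the convention used to star residues with
#' more than one salt-bridge interaction).
#'
#' @param x an `occupancy_table` from [compute_occupancy()].
#' @return data.frame with columns `chain`, `resid`, `resname`,
#'   `union_occupancy`, `n_pairs`, `multi_partner`.
#' @export
aggregate_by_residue <- function(x) {
  stopifnot(inherits(x, "occupancy_table"))
  p <- x$pairs
  if (!nrow(p))
    return(data.frame(chain = character(0), resid = integer(0),
                      resname = character(0), union_occupancy = numeric(0),
                      n_pairs = integer(0), multi_partner = logical(0),
                      stringsAsFactors = FALSE))
  res_rows <- rbind(
    data.frame(chain = p$chain_1, resid = p$resid_1, resname = p$resname_1,
               row = seq_len(nrow(p)), stringsAsFactors = FALSE),
    data.frame(chain = p$chain_2, resid = p$resid_2, resname = p$resname_2,
               row = seq_len(nrow(p)), stringsAsFactors = FALSE))
  key <- paste(res_rows$chain, res_rows$resid)
  out <- lapply(split(res_rows, key), function(rr) {
    rows <- unique(rr$row)
    union_frames <- apply(x$series[rows, , drop = FALSE], 2, any)
    data.frame(chain = rr$chain[1], resid = rr$resid[1], resname = rr$resname[1],
               union_occupancy = 100 * sum(union_frames) / x$n_frames,
               n_pairs = length(rows), multi_partner = length(rows) >= 2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chain, out$resid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write contact occupancy reports
#'
#' Writes `<path>.tsv` (pair rows sorted by occupancy descending, ties
#' broken lexicographically by chain, resid and atom names) and
#' `<path>.json` (the same rows plus frame-count numerators/denominators and
#' the per-residue aggregate).
#'
#' @param x an `occupancy_table`.
#' @param path output path prefix (without extension).
#' @return character vector of the two written paths, invisibly.
#' @export
write_contact_report <- function(x, path) {
  stopifnot(inherits(x, "occupancy_table"))
  tsv <- paste0(path, ".tsv"); js <- paste0(path, ".json")
  cols <- c("pair_id", "chain_1", "resid_1", "resname_1", "atom_1",
            "chain_2", "resid_2", "resname_2", "atom_2",
            "occupancy", "tier")
  tab <- x$pairs[cols]
  tab$occupancy <- sprintf("%.4f", tab$occupancy)
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(kind = x$kind, n_frames = x$n_frames,
         pairs = x$pairs, residues = x$residues),
    js, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(tsv, js))
}
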