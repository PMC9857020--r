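# Independent brute-force oracles: plain nested loops with the chemistry and
# geometry written out from scratch, used only to cross-check the package's
# vectorised detectors and interpolators.

oracle_trilinear <- function(grid, p) {
  h <- grid$spacing; o <- grid$origin; v <- grid$values
  t <- (p - o) / h
  i <- pmin(floor(t), grid$dims - 2)
  f <- t - i
  out <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
         (if (dz) f[3] else 1 - f[3])
    out <- out + w * v[i[1] + dx + 1, i[2] + dy + 1, i[3] + dz + 1]
  }
  out
}

# donor heavy atom -> hydrogens, written out independently of the package table
.oracle_donors <- list(
  c("*",   "N",   "H"),
  c("SER", "OG",  "HG"),   c("THR", "OG1", "HG1"), c("TYR", "OH", "HH"),
  c("CYS", "SG",  "HG"),
  c("ASN", "ND2", "HD21"), c("ASN", "ND2", "HD22"),
  c("GLN", "NE2", "HE21"), c("GLN", "NE2", "HE22"),
  c("LYS", "NZ",  "HZ1"),  c("LYS", "NZ",  "HZ2"), c("LYS", "NZ", "HZ3"),
  c("ARG", "NE",  "HE"),
  c("ARG", "NH1", "HH11"), c("ARG", "NH1", "HH12"),
  c("ARG", "NH2", "HH21"), c("ARG", "NH2", "HH22"),
  c("TRP", "NE1", "HE1"),
  c("HIS", "ND1", "HD1"),  c("HIS", "NE2", "HE2"))

.oracle_acceptors <- list(
  c("*", "O"), c("*", "OXT"),
  c("ASP", "OD1"), c("ASP", "OD2"), c("GLU", "OE1"), c("GLU", "OE2"),
  c("ASN", "OD1"), c("GLN", "OE1"),
  c("SER", "OG"), c("THR", "OG1"), c("TYR", "OH"),
  c("HIS", "ND1"), c("HIS", "NE2"))

# returns a sorted character vector of "chainD:residD:donor->chainA:residA:acceptor"
oracle_hbonds <- function(x, chains_a, chains_b, dist_cut = 3.2, ang_cut = 20) {
  a <- x$atoms
  pos <- function(i) c(a$x[i], a$y[i], a$z[i])
  found <- character(0)
  for (i in seq_len(nrow(a))) {
    for (rule in .oracle_donors) {
      if (a$name[i] != rule[2]) next
      if (rule[1] != "*" && a$resname[i] != rule[1]) next
      hidx <- which(a$chain == a$chain[i] & a$resid == a$resid[i] & a$name == rule[3])
      if (!length(hidx)) next
      for (j in seq_len(nrow(a))) {
        cross <- (a$chain[i] %in% chains_a && a$chain[j] %in% chains_b) ||
                 (a$chain[i] %in% chains_b && a$chain[j] %in% chains_a)
        if (!cross) next
        is_acc <- FALSE
        for (ar in .oracle_acceptors)
          if (a$name[j] == ar[2] && (ar[1] == "*" || a$resname[j] == ar[1]))
            is_acc <- TRUE
        if (!is_acc) next
        vda <- pos(j) - pos(i)
        d <- sqrt(sum(vda^2))
        if (d > dist_cut) next
        vdh <- pos(hidx[1]) - pos(i)
        ang <- acos(min(max(sum(vda * vdh) /
                 (sqrt(sum(vda^2)) * sqrt(sum(vdh^2))), -1), 1)) * 180 / pi
        if (ang <= ang_cut)
          found <- c(found, paste0(a$chain[i], ":", a$resid[i], ":", a$name[i],
                                   "->", a$chain[j], ":", a$resid[j], ":", a$name[j]))
      }
    }
  }
  sort(unique(found))
}

# salt-bridge residue pairs: "chainAcid:residAcid--chainBase:residBase"
oracle_saltbridges <- function(x, chains_a, chains_b, cut = 4.0) {
  a <- x$atoms
  acid <- (a$resname == "ASP" & a$name %in% c("OD1", "OD2")) |
          (a$resname == "GLU" & a$name %in% c("OE1", "OE2")) |
          a$name == "OXT"
  base <- (a$resname == "LYS" & a$name == "NZ") |
          (a$resname == "ARG" & a$name %in% c("NE", "NH1", "NH2"))
  found <- character(0)
  for (i in which(acid)) for (j in which(base)) {
    cross <- (a$chain[i] %in% chains_a && a$chain[j] %in% chains_b) ||
             (a$chain[i] %in% chains_b && a$chain[j] %in% chains_a)
    if (!cross) next
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
    if (d <= cut)
      found <- c(found, paste0(a$chain[i], ":", a$resid[i], "--",
                               a$chain[j], ":", a$resid[j]))
  }
  sort(unique(found))
}

# canonical keys from the package detectors, for set comparison with oracles
pkg_hbond_keys <- function(hb) {
  if (nrow(hb) == 0) return(character(0))
  sort(unique(paste0(hb$chain_d, ":", hb$resid_d, ":", hb$donor,
                     "->", hb$chain_a, ":", hb$resid_a, ":", hb$acceptor)))
}
pkg_sb_keys <- function(sb) {
  if (nrow(sb) == 0) return(character(0))
  sort(unique(paste0(sb$chain_acid, ":", sb$resid_acid, "--",
                     sb$chain_base, ":", sb$resid_base)))
}

# small hand-built structure helper for contact geometry tests
atoms_df <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(serial = i, name = r$name, resname = r$resname, chain = r$chain,
               resid = r$resid, x = r$pos[1], y = r$pos[2], z = r$pos[3],
               charge = if (is.null(r$charge)) 0 else r$charge,
               radius = if (is.null(r$radius)) 1.5 else r$radius,
               stringsAsFactors = FALSE)
  }))
  struct3d(df)
}
at <- function(name, resname, chain, resid, pos, charge = 0, radius = 1.5)
  list(name = name, resname = resname, chain = chain, resid = resid,
       pos = pos, charge = charge, radius = radius)
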