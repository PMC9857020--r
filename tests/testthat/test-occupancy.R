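# Occupancy computation, the 10/40/80% reporting tiers, per-residue
# aggregation and report writing.

base3 <- make_charged_interface_pair(3, 3.5)

test_that("occupancy arithmetic and tiers follow the frame counts", {
  ens <- make_contact_trajectory(base3, c("1" = 1.0, "2" = 0.5, "3" = 0.0),
                                 n_frames = 100, seed = 2)
  occ <- compute_occupancy(ens, "A", "B", "saltbridge")
  p <- occ$pairs
  expect_equal(p$occupancy[p$resid_1 == 1], 100)
  expect_equal(p$tier[p$resid_1 == 1], ">80")
  # p = 0 pair never appears
  expect_false(any(p$resid_1 == 3))
  expect_true(all(p$occupancy >= 10 & p$occupancy <= 100))
  expect_error(compute_occupancy(ensemble3d(base3, list()), "A", "B"),
               "at least 1|no frames")
})

test_that("a contact present in 947 of 1000 frames reports exactly 94.7%", {
  base1 <- make_charged_interface_pair(1, 3.5)
  ens <- make_contact_trajectory(base1, c("1" = 0.947), n_frames = 1000,
                                 seed = 5, exact = TRUE)
  occ <- compute_occupancy(ens, "A", "B", "saltbridge")
  expect_equal(occ$pairs$n_present, 947)
  expect_equal(occ$pairs$occupancy, 94.7)
  expect_equal(occ$pairs$tier, ">80")
  # 99/1000 sits below the >= 10% retention rule and is dropped
  ens2 <- make_contact_trajectory(base1, c("1" = 0.099), n_frames = 1000,
                                  seed = 5, exact = TRUE)
  occ2 <- compute_occupancy(ens2, "A", "B", "saltbridge")
  expect_equal(nrow(occ2$pairs), 0)
  # 100/1000 = exactly 10% is kept (inclusive filter)
  ens3 <- make_contact_trajectory(base1, c("1" = 0.100), n_frames = 1000,
                                  seed = 5, exact = TRUE)
  occ3 <- compute_occupancy(ens3, "A", "B", "saltbridge")
  expect_equal(occ3$pairs$occupancy, 10)
  expect_equal(occ3$pairs$tier, ">=10")
})

test_that("occupancy is invariant under frame reordering", {
  ens <- make_contact_trajectory(base3, c("1" = 0.6, "2" = 0.3, "3" = 0.9),
                                 n_frames = 200, seed = 9)
  occ <- compute_occupancy(ens, "A", "B", "saltbridge")
  set.seed(1)
  perm <- sample(n_frames(ens))
  occ_perm <- compute_occupancy(select_frames(ens, perm), "A", "B", "saltbridge")
  expect_equal(occ_perm$pairs[order(occ_perm$pairs$pair_id),
                              c("pair_id", "occupancy", "tier")],
               occ$pairs[order(occ$pairs$pair_id),
                         c("pair_id", "occupancy", "tier")],
               ignore_attr = TRUE)
})

test_that("per-residue union occupancy bounds pair occupancy and flags multi-partner", {
  # hand-built series: one residue in two pairs with disjoint frame sets
  ens <- make_contact_trajectory(base3, c("1" = 0.5, "2" = 0.5, "3" = 0.5),
                                 n_frames = 50, seed = 4)
  occ <- compute_occupancy(ens, "A", "B", "saltbridge")
  res <- occ$residues
  for (i in seq_len(nrow(occ$pairs))) {
    for (side in 1:2) {
      rr <- res[res$chain == occ$pairs[[paste0("chain_", side)]][i] &
                res$resid == occ$pairs[[paste0("resid_", side)]][i], ]
      expect_gte(rr$union_occupancy, occ$pairs$occupancy[i])
    }
  }
  expect_true(all(!res$multi_partner))  # one partner each in this fixture

  # synthetic occupancy table with controlled frame sets
  mk_table <- function(seriesA, seriesB) {
    pairs <- data.frame(
      pair_id = c("p1", "p2"),
      chain_1 = "A", resid_1 = 1L, resname_1 = "GLU", atom_1 = "OE1",
      chain_2 = "B", resid_2 = c(1L, 2L), resname_2 = "LYS", atom_2 = "NZ",
      n_present = c(sum(seriesA), sum(seriesB)), n_frames = length(seriesA),
      occupancy = 100 * c(mean(seriesA), mean(seriesB)),
      tier = ">=10", stringsAsFactors = FALSE)
    structure(list(pairs = pairs, series = rbind(p1 = seriesA, p2 = seriesB),
                   kind = "saltbridge", n_frames = length(seriesA)),
              class = "occupancy_table")
  }
  # disjoint 30% + 30% -> union 60%, flagged
  disjoint <- mk_table(rep(c(TRUE, FALSE), c(3, 7)),
                       rep(c(FALSE, TRUE, FALSE), c(3, 3, 4)))
  agg <- aggregate_by_residue(disjoint)
  a1 <- agg[agg$chain == "A" & agg$resid == 1, ]
  expect_equal(a1$union_occupancy, 60)
  expect_true(a1$multi_partner)
  # fully co-occurring 50% + 50% -> union 50%, still flagged
  co <- mk_table(rep(c(TRUE, FALSE), each = 5), rep(c(TRUE, FALSE), each = 5))
  agg2 <- aggregate_by_residue(co)
  a2 <- agg2[agg2$chain == "A" & agg2$resid == 1, ]
  expect_equal(a2$union_occupancy, 50)
  expect_true(a2$multi_partner)
})

test_that("contact reports are sorted, tie-broken deterministically and mirrored in JSON", {
  ens <- make_contact_trajectory(base3, c("1" = 0.8, "2" = 0.3, "3" = 0.8),
                                 n_frames = 10, seed = 3, exact = TRUE)
  occ <- compute_occupancy(ens, "A", "B", "saltbridge")
  out <- tempfile()
  write_contact_report(occ, out)
  tsv <- read.delim(paste0(out, ".tsv"))
  expect_equal(nrow(tsv), 3)
  expect_true(all(diff(tsv$occupancy) <= 0))  # descending
  ties <- tsv[tsv$occupancy == 80, ]
  expect_equal(ties$resid_1, sort(ties$resid_1))  # lexicographic tie-break
  js <- jsonlite::read_json(paste0(out, ".json"), simplifyVector = TRUE)
  expect_equal(js$n_frames, 10)
  expect_equal(js$pairs$n_present, occ$pairs$n_present)
  expect_equal(js$pairs$occupancy, tsv$occupancy, tolerance = 1e-9)
  # empty table: header-only TSV, empty JSON pair list
  ens0 <- make_contact_trajectory(base3, c("1" = 0, "2" = 0, "3" = 0),
                                  n_frames = 5, seed = 1)
  occ0 <- compute_occupancy(ens0, "A", "B", "saltbridge")
  out0 <- tempfile()
  write_contact_report(occ0, out0)
  expect_equal(length(readLines(paste0(out0, ".tsv"))), 1)
  js0 <- jsonlite::read_json(paste0(out0, ".json"), simplifyVector = TRUE)
  expect_equal(length(js0$pairs), 0)
})

test_that("hydrogen-bond occupancy uses donor/acceptor atom pair identity", {
  base1 <- make_charged_interface_pair(1, 2.9)
  ens <- make_contact_trajectory(base1, c("1" = 0.7), n_frames = 100, seed = 8,
                                 cutoff = 3.2, exact = TRUE)
  occ <- compute_occupancy(ens, "A", "B", "hbond")
  expect_equal(nrow(occ$pairs), 1)
  expect_equal(occ$pairs$occupancy, 70)
  expect_equal(occ$pairs$atom_1, "NZ")   # donor side first
  expect_equal(occ$pairs$atom_2, "OE1")
})
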