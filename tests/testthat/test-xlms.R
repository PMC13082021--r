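# Engine-table filtering, consensus, network statistics and
# distance-restraint mapping.

toy_table <- function() data.frame(
  protein_a = c("Q", "P", "P", "P", "P", "R", "R", "S", "S", "T"),
  residue_a = c(7, 3, 3, 10, 11, 2, 3, 4, 5, 6),
  protein_b = c("P", "P", "P", "Q", "Q", "S", "S", "T", "T", "T"),
  residue_b = c(5, 90, 90, 1, 2, 1, 2, 3, 4, 9),
  score = c(20, 12.1, 30, 15, 16, 17, 18, 19, 21, 22),
  csm_fdr = c(0.005, 0.002, 0.004, 0.003, 0.02, 0.06, 0.004, 0.001, 0.5, 0.009),
  stringsAsFactors = FALSE)

test_that("engine loading filters, canonicalizes and de-duplicates", {
  tab <- toy_table()
  expect_equal(sum(tab$csm_fdr <= 0.01), 7)  # 3 of 10 rows above cutoff
  rec <- load_engine_table(tab, "A", fdr_cutoff = 0.01)
  expect_equal(nrow(rec), 6)  # 7 pass the filter, one duplicate collapses
  # duplicate residue pair keeps the best score
  dup <- rec[rec$protein_a == "P" & rec$residue_a == 3 &
               rec$protein_b == "P" & rec$residue_b == 90, ]
  expect_equal(nrow(dup), 1)
  expect_equal(dup$score, 30)
  # canonical endpoint order: (Q,7)-(P,5) flipped to (P,5)-(Q,7)
  expect_true(all(rec$protein_a <= rec$protein_b))
  expect_true(any(rec$protein_a == "P" & rec$residue_a == 5 &
                    rec$protein_b == "Q" & rec$residue_b == 7))
  expect_error(load_engine_table(tab[, -3], "A"), "protein_b")
  bad <- tab
  bad$residue_a[1] <- "x"
  expect_warning(load_engine_table(bad, "A"), "malformed")
  # file round trip
  f <- tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  expect_equal(nrow(load_engine_table(f, "A", 0.01)), 6)
})

test_that("consensus is commutative, idempotent and monotone", {
  a <- load_engine_table(toy_table(), "A", 0.01)
  expect_identical(link_key_df(xl_consensus(a, a)), link_key_df(a))
  b <- a
  b$protein_a <- paste0("Z", b$protein_a)  # disjoint identifiers
  expect_equal(nrow(xl_consensus(a, b)), 0)
  half <- a[1:3, ]
  ab <- xl_consensus(a, half)
  ba <- xl_consensus(half, a)
  expect_identical(sort(link_key_df(ab)), sort(link_key_df(ba)))
  expect_true(all(link_key_df(ab) %in% link_key_df(a)))
  # supersets never shrink the consensus
  expect_gte(nrow(xl_consensus(a, a)), nrow(ab))
})

test_that("planted-truth consensus has near-perfect precision", {
  sm <- gen_structure(3, 60)
  hits <- 0; total <- 0
  for (seed in c(21, 22)) {
    xl <- gen_crosslinks(xl_sim_model(n_true = 500, n_decoy = 60,
                                      engine_detect_prob = c(0.9, 0.8),
                                      decoy_rate = c(0.02, 0.02),
                                      seed = seed), sm)
    cons <- xl_consensus(load_engine_table(xl$engine_a, "A", 0.01),
                         load_engine_table(xl$engine_b, "B", 0.05))
    truth_keys <- link_key_df(xl$truth[xl$truth$is_true, ])
    hits <- hits + sum(link_key_df(cons) %in% truth_keys)
    total <- total + nrow(cons)
  }
  expect_gte(hits / total, 0.99)
})

test_that("network statistics count links, proteins and heterotypic PPIs", {
  links <- data.frame(protein_a = c("P", "P"), residue_a = c(3, 5),
                      protein_b = c("P", "Q"), residue_b = c(90, 7),
                      stringsAsFactors = FALSE)
  ns <- network_stats(links)
  expect_equal(unname(ns$stats), c(2, 2, 1))
  expect_equal(igraph::vcount(ns$network), 2)
  empty <- links[0, ]
  expect_equal(unname(network_stats(empty)$stats), c(0, 0, 0))
  # order and duplication invariance
  shuffled <- rbind(links[2:1, ], links[1, ])
  expect_equal(network_stats(shuffled)$stats, ns$stats)
  # homotypic pairs counted only on request
  expect_equal(unname(network_stats(links, include_homotypic = TRUE)$stats[3]), 2)
})

test_that("restraint mapping matches brute force and flags violations", {
  sm <- gen_structure(1, 100, rise = 0.38)
  same <- data.frame(protein_a = "P1", residue_a = 5, protein_b = "P1",
                     residue_b = 5, stringsAsFactors = FALSE)
  # same residue on a single chain cannot be mapped to two atoms
  expect_false(map_links(same, sm)$mapped)
  ends <- data.frame(protein_a = "P1", residue_a = 1, protein_b = "P1",
                     residue_b = 100, stringsAsFactors = FALSE)
  md <- map_links(ends, sm)
  expect_equal(md$distance, 99 * 3.8)  # 376.2 A
  sat <- restraint_satisfaction(md, cutoff = 35)
  expect_equal(sat$fraction, 0)
  expect_equal(formals(restraint_satisfaction)$cutoff, 35)
  # zero mapped links: explicit NA sentinel
  none <- data.frame(protein_a = "ZZ", residue_a = 1, protein_b = "ZZ",
                     residue_b = 2, stringsAsFactors = FALSE)
  expect_true(is.na(restraint_satisfaction(map_links(none, sm))$fraction))
  # simulation: package result equals the brute-force oracle exactly
  sm3 <- gen_structure(3, 40)
  xl <- gen_crosslinks(xl_sim_model(n_true = 150, n_decoy = 80,
                                    engine_detect_prob = c(1, 1),
                                    decoy_rate = c(1, 1), seed = 31), sm3)
  links <- load_engine_table(xl$engine_a, "A", 1)
  got <- restraint_satisfaction(map_links(links, sm3), 35)
  want <- oracle_satisfaction(links, sm3, 35)
  expect_equal(got$n_mapped, want$n_mapped)
  expect_equal(got$fraction, want$fraction)
  # planted mixture: truth links all satisfied, decoys all violated
  truth <- xl$truth
  tl <- map_links(truth[truth$is_true, ], sm3)
  dl <- map_links(truth[!truth$is_true, ], sm3)
  expect_equal(restraint_satisfaction(tl, 35)$fraction, 1)
  expect_equal(restraint_satisfaction(dl, 35)$fraction, 0)
})

test_that("homodimeric ambiguity resolves to the minimum chain distance", {
  sm <- structure_map(data.frame(
    protein = "HOM", chain = c("A", "A", "B", "B"),
    residue = c(1, 50, 1, 50),
    x = c(0, 0, 100, 100), y = 0, z = c(0, 190, 0, 190)))
  self <- data.frame(protein_a = "HOM", residue_a = 1, protein_b = "HOM",
                     residue_b = 50, stringsAsFactors = FALSE)
  # within one chain 190 A; across chains sqrt(100^2 + 190^2); min wins
  expect_equal(map_links(self, sm)$distance, 190)
})

test_that("tubulin partner extraction and topology calls follow the rules", {
  links <- data.frame(
    protein_a = c("TUBA", "TUBA", "MLF1", "CFAP", "OTH1"),
    residue_a = c(10, 370, 4, 8, 2),
    protein_b = c("TUBB", "MLF1", "TUBB", "TUBA", "OTH2"),
    residue_b = c(20, 1, 60, 370, 3), stringsAsFactors = FALSE)
  tub <- c("TUBA", "TUBB")
  expect_equal(tubulin_partners(links, tub), c("CFAP", "MLF1"))
  only_tt <- links[1, ]
  expect_length(tubulin_partners(only_tt, tub), 0)
  ann <- data.frame(protein = c("TUBA", "TUBB"), residue = c(370, 60),
                    topology = c("lumen", "exterior"), stringsAsFactors = FALSE)
  calls <- topology_call(links, ann, tub)
  expect_equal(calls$topology[calls$partner == "CFAP"], "lumen")
  expect_equal(calls$topology[calls$partner == "MLF1"], "mixed")
})
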