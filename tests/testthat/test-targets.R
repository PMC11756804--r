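lm_fixture <- function() {
  lnc_de <- toy_de(c("L1", "L2"), c(2, -2))
  mir_de <- toy_de(c("m1", "m2", "m3"), c(-2, 2, -1.5),
                   direction = c("down", "up", "ns"))
  list(core = c("L1", "L2"), lnc_de = lnc_de, mir_de = mir_de)
}

test_that("lncRNA-miRNA boundary semantics follow the stated operators", {
  fx <- lm_fixture()
  pred <- data.frame(
    lncrna_id = c("L1", "L1", "L1", "L1", "L1"),
    mirna_id = c("m1", "m1", "m1", "m1", "m2"),
    target_score = c(60, 59.9, 75, 75, 80),
    conservation = c(0.51, 0.8, 0.5, 0.8, 0.8),
    stringsAsFactors = FALSE)
  ## rows 2-4 are duplicates of (L1, m1); best scores are kept (75, 0.8)
  expect_warning(
    out <- lnc_mir_pairs(fx$core, pred, fx$mir_de, fx$lnc_de),
    "duplicate")
  expect_equal(nrow(out$pairs), 1)        # (L1, m1); (L1, m2) same-dir
  expect_equal(out$pairs$target_score, 75)
  expect_equal(out$pairs$conservation, 0.8)
  expect_equal(unname(out$tally[["same_direction"]]), 1)

  ## exact threshold row alone: score 60 inclusive, conservation strict
  one <- pred[1, ]
  expect_equal(nrow(lnc_mir_pairs(fx$core, one, fx$mir_de,
                                  fx$lnc_de)$pairs), 1)
  one$conservation <- 0.5
  out <- lnc_mir_pairs(fx$core, one, fx$mir_de, fx$lnc_de)
  expect_equal(nrow(out$pairs), 0)
  expect_equal(unname(out$tally[["low_conservation"]]), 1)
})

test_that("exclusion reasons are attributed in filter order and sum up", {
  fx <- lm_fixture()
  pred <- data.frame(
    lncrna_id = c("L9", "L1", "L1", "L1", "L1"),
    mirna_id = c("m1", "m1", "m3", "m2", "mX"),
    target_score = c(80, 40, 80, 80, 80),
    conservation = c(0.8, 0.8, 0.8, 0.8, 0.8),
    stringsAsFactors = FALSE)
  out <- lnc_mir_pairs(fx$core, pred, fx$mir_de, fx$lnc_de)
  expect_equal(unname(out$tally[c("not_core", "low_score",
                                  "mirna_not_de", "same_direction",
                                  "retained")]),
               c(1, 1, 2, 1, 0))
  expect_equal(sum(out$tally), nrow(pred))
  expect_setequal(out$lnc_without_mirna, c("L1", "L2"))
  ## a non-DE "core" lncRNA violates the precondition
  expect_error(lnc_mir_pairs(c("L1", "LZ"), pred, fx$mir_de, fx$lnc_de),
               "LZ")
})

test_that("per-miRNA direction rule removes offending miRNAs globally", {
  lnc_de <- toy_de(c("L1", "L2"), c(2, -2))
  mir_de <- toy_de("m1", -2)
  ## m1 is opposite to L1 but same-direction with L2
  pred <- data.frame(lncrna_id = c("L1", "L2"), mirna_id = "m1",
                     target_score = 80, conservation = 0.8,
                     stringsAsFactors = FALSE)
  per_pair <- lnc_mir_pairs(c("L1", "L2"), pred, mir_de, lnc_de)
  expect_equal(per_pair$pairs$lncrna_id, "L1")
  cfg <- pipeline_config(direction_rule = "per_mirna")
  per_mir <- lnc_mir_pairs(c("L1", "L2"), pred, mir_de, lnc_de, cfg)
  expect_equal(nrow(per_mir$pairs), 0)
})

test_that("miRNA-mRNA filtering requires both tools and strict miRanda rules", {
  mir_de <- toy_de("m1", -2)
  mrna_de <- toy_de(c("G1", "G2", "G3"), c(2, 2, -2))
  ts <- data.frame(mirna_id = "m1", mrna_id = c("G1", "G2", "G3"),
                   context_score = c(-0.4, -0.8, -0.8),
                   stringsAsFactors = FALSE)
  mr <- data.frame(mirna_id = "m1", mrna_id = c("G1", "G3"),
                   miranda_score = c(141, 180),
                   miranda_energy = c(-20.5, -30),
                   stringsAsFactors = FALSE)
  out <- mir_mrna_pairs("m1", ts, mr, mrna_de, mir_de)
  ## G1: boundary context -0.4 (inclusive), 141 > 140, -20.5 < -20: kept
  ## G2: single tool; G3: same direction as m1
  expect_equal(out$pairs$mrna_id, "G1")
  expect_equal(unname(out$tally[c("single_tool", "same_direction",
                                  "retained")]), c(1, 1, 1))

  mr$miranda_score[1] <- 140            # strict: now fails
  out <- mir_mrna_pairs("m1", ts, mr, mrna_de, mir_de)
  expect_equal(unname(out$tally[["miranda_score"]]), 1)
  mr$miranda_score[1] <- 150
  mr$miranda_energy[1] <- -20           # strict: fails
  out <- mir_mrna_pairs("m1", ts, mr, mrna_de, mir_de)
  expect_equal(unname(out$tally[["energy"]]), 1)
})

test_that("retained pair sets are invariant to row order and duplicates", {
  cfg <- pipeline_config()
  sc <- simulate_counts(n_features = c(lncRNA = 100, miRNA = 60,
                                       mRNA = 120),
                        n_triplet = c(3, 5, 8), seed = 61)
  st <- simulate_side_tables(sc$truth, decoy_fraction = 0.6, seed = 62)
  lnc_de <- toy_de(sc$truth$de$lncRNA$feature_id,
                   sc$truth$de$lncRNA$log2fc)
  mir_de <- toy_de(sc$truth$de$miRNA$feature_id,
                   sc$truth$de$miRNA$log2fc)
  core <- unique(st$truth$triplets$lncrna_id)
  a <- lnc_mir_pairs(core, st$mirdb, mir_de, lnc_de, cfg)
  perm <- sample(nrow(st$mirdb))
  b <- lnc_mir_pairs(core, st$mirdb[perm, ], mir_de, lnc_de, cfg)
  key <- function(p) sort(paste(p$lncrna_id, p$mirna_id))
  expect_equal(key(a$pairs), key(b$pairs))
  dup <- rbind(st$mirdb, st$mirdb[1:3, ])
  expect_warning(cc <- lnc_mir_pairs(core, dup, mir_de, lnc_de, cfg),
                 "duplicate")
  expect_equal(key(cc$pairs), key(a$pairs))
})

test_that("both filters agree with a brute-force conjunct oracle", {
  cfg <- pipeline_config()
  for (seed in c(71, 72)) {
    sc <- simulate_counts(n_features = c(lncRNA = 100, miRNA = 60,
                                         mRNA = 120),
                          n_triplet = c(3, 5, 8), seed = seed)
    st <- simulate_side_tables(sc$truth, decoy_fraction = 0.7,
                               seed = seed + 1)
    lnc_de <- toy_de(sc$truth$de$lncRNA$feature_id,
                     sc$truth$de$lncRNA$log2fc)
    mir_de <- toy_de(sc$truth$de$miRNA$feature_id,
                     sc$truth$de$miRNA$log2fc)
    mrna_de <- toy_de(sc$truth$de$mRNA$feature_id,
                      sc$truth$de$mRNA$log2fc)
    core <- unique(st$truth$triplets$lncrna_id)

    got <- lnc_mir_pairs(core, st$mirdb, mir_de, lnc_de, cfg)$pairs
    ora <- bf_lnc_mir_filter(core, st$mirdb, mir_de, lnc_de, cfg)
    expect_setequal(paste(got$lncrna_id, got$mirna_id),
                    paste(ora$lncrna_id, ora$mirna_id))

    mirnas <- unique(got$mirna_id)
    got2 <- mir_mrna_pairs(mirnas, st$targetscan, st$miranda, mrna_de,
                           mir_de, cfg)$pairs
    ora2 <- bf_mir_mrna_filter(mirnas, st$targetscan, st$miranda,
                               mrna_de, mir_de, cfg)
    expect_setequal(paste(got2$mirna_id, got2$mrna_id),
                    paste(ora2$mirna_id, ora2$mrna_id))
  }
})
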