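small_counts <- function(...) {
  simulate_counts(n_features = c(lncRNA = 120, miRNA = 60, mRNA = 120),
                  ...)
}

test_that("the generator is deterministic and validates its inputs", {
  a <- small_counts(seed = 5)
  b <- small_counts(seed = 5)
  expect_identical(a, b)
  c <- small_counts(seed = 6)
  expect_false(identical(a$counts$lncRNA, c$counts$lncRNA))

  expect_error(small_counts(n_per_group = 1), "n_per_group")
  expect_error(small_counts(dispersion = 0), "dispersion")
  expect_error(small_counts(de_fraction = 1.2), "de_fraction")
  expect_error(small_counts(de_fraction = 0.1, effect = 0), "effect")
})

test_that("de_fraction = 0 plants nothing and forbids triplets", {
  sc <- small_counts(de_fraction = 0, seed = 1)
  expect_equal(nrow(sc$truth$de$lncRNA), 0)
  expect_equal(nrow(sc$truth$de$mRNA), 0)
  expect_null(sc$truth$triplets)
  expect_error(small_counts(de_fraction = 0, n_triplet = c(2, 2, 2),
                            seed = 1), "n_triplet")
})

test_that("counts are non-negative integers and non-DE features share group means", {
  ## large groups + tiny dispersion make the shared-mean check sharp
  sc <- simulate_counts(n_features = c(lncRNA = 150, miRNA = 10,
                                       mRNA = 10),
                        n_per_group = 40, dispersion = 0.01,
                        de_fraction = c(0.2, 0, 0), effect = 2,
                        seed = 9)
  m <- sc$counts$lncRNA
  expect_true(all(m >= 0))
  expect_true(all(m == floor(m)))
  is_test <- sc$groups == "test"
  ratio <- rowMeans(m[, is_test]) / rowMeans(m[, !is_test])
  planted <- rownames(m) %in% sc$truth$de$lncRNA$feature_id
  expect_equal(mean(ratio[!planted]), 1, tolerance = 0.05)
  expect_true(all(abs(log2(ratio[planted])) > 1))
})

test_that("planted triplets satisfy the sponge sign invariants", {
  sc <- small_counts(n_triplet = c(4, 6, 10), seed = 21)
  tr <- sc$truth$triplets
  expect_gt(nrow(tr), 0)
  expect_true(all(tr$lnc_direction != tr$mir_direction))
  expect_true(all(tr$mir_direction != tr$mrna_direction))
  expect_true(all(tr$lnc_direction == tr$mrna_direction))
  ## members exist in the count matrices and in the planted DE sets
  expect_true(all(tr$lncrna_id %in% rownames(sc$counts$lncRNA)))
  expect_true(all(tr$mirna_id %in% rownames(sc$counts$miRNA)))
  expect_true(all(tr$mrna_id %in% rownames(sc$counts$mRNA)))
  expect_true(all(tr$lncrna_id %in% sc$truth$de$lncRNA$feature_id))
  expect_true(all(tr$mirna_id %in% sc$truth$de$miRNA$feature_id))
  ## recorded directions match the planted effect signs
  de <- sc$truth$de$lncRNA
  expect_equal(ifelse(de$log2fc[match(tr$lncrna_id, de$feature_id)] > 0,
                      "up", "down"),
               tr$lnc_direction)
})

test_that("planted prediction rows pass every threshold and decoys fail as labelled", {
  cfg <- pipeline_config()
  sc <- small_counts(n_triplet = c(4, 6, 10), seed = 33)
  st <- simulate_side_tables(sc$truth, decoy_fraction = 0.5, seed = 34)
  tr <- st$truth

  pk <- function(d, a, b) paste(d[[a]], d[[b]])
  ## every planted pair is supported by a passing row
  mirdb_key <- pk(st$mirdb, "lncrna_id", "mirna_id")
  for (i in seq_len(nrow(tr$pairs_lm))) {
    j <- match(pk(tr$pairs_lm, "lncrna_id", "mirna_id")[i], mirdb_key)
    expect_false(is.na(j))
    expect_gte(st$mirdb$target_score[j], cfg$mirdb_score)
    expect_gt(st$mirdb$conservation[j], cfg$mirdb_conservation)
  }
  ts_key <- pk(st$targetscan, "mirna_id", "mrna_id")
  mr_key <- pk(st$miranda, "mirna_id", "mrna_id")
  for (i in seq_len(nrow(tr$pairs_mg))) {
    k <- pk(tr$pairs_mg, "mirna_id", "mrna_id")[i]
    j1 <- match(k, ts_key); j2 <- match(k, mr_key)
    expect_false(is.na(j1) || is.na(j2))
    expect_lte(st$targetscan$context_score[j1], cfg$context_max)
    expect_gt(st$miranda$miranda_score[j2], cfg$miranda_min)
    expect_lt(st$miranda$miranda_energy[j2], cfg$energy_max)
  }

  ## decoy classes are attributable: each fails its designated rule
  de_dir <- function(layer) {
    d <- sc$truth$de[[layer]]
    stats::setNames(ifelse(d$log2fc > 0, "up", "down"), d$feature_id)
  }
  mdir <- de_dir("miRNA"); gdir <- de_dir("mRNA"); ldir <- de_dir("lncRNA")
  dec <- tr$decoys
  expect_true(all(c("score_fail", "direction_fail", "non_de") %in%
                    dec$class))
  for (i in seq_len(nrow(dec))) {
    if (dec$table[i] == "mirdb") {
      j <- match(paste(dec$a[i], dec$b[i]), mirdb_key)
      score_ok <- st$mirdb$target_score[j] >= cfg$mirdb_score &&
        st$mirdb$conservation[j] > cfg$mirdb_conservation
      if (dec$class[i] == "score_fail") expect_false(score_ok)
      if (dec$class[i] == "direction_fail") {
        expect_true(score_ok)
        expect_equal(unname(ldir[dec$a[i]]), unname(mdir[dec$b[i]]))
      }
      if (dec$class[i] == "non_de")
        expect_false(dec$b[i] %in% names(mdir))
    } else {
      k <- paste(dec$a[i], dec$b[i])
      j1 <- match(k, ts_key); j2 <- match(k, mr_key)
      score_ok <- !is.na(j1) && !is.na(j2) &&
        st$targetscan$context_score[j1] <= cfg$context_max &&
        st$miranda$miranda_score[j2] > cfg$miranda_min &&
        st$miranda$miranda_energy[j2] < cfg$energy_max
      if (dec$class[i] == "score_fail") expect_false(score_ok)
      if (dec$class[i] == "direction_fail") {
        expect_true(score_ok)
        expect_equal(unname(mdir[dec$a[i]]), unname(gdir[dec$b[i]]))
      }
      if (dec$class[i] == "non_de")
        expect_false(dec$b[i] %in% names(gdir))
    }
  }

  ## planted triplet lncRNAs argmax to the cytoplasm
  loc <- predict_compartment(st$localization)
  t_lncs <- unique(tr$triplets$lncrna_id)
  expect_true(all(loc$predicted[match(t_lncs, loc$lncrna_id)] ==
                    "cytoplasm"))
})

test_that("FPKM derivation matches its definition", {
  m <- matrix(c(100, 200, 50, 100), ncol = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  f <- fpkm(m, lengths = c(1000, 500))   # libraries: 300 and 150 reads
  expect_equal(f["a", "s1"], 100 / (1 * 300 / 1e6))
  expect_equal(f["b", "s2"], 100 / (0.5 * 150 / 1e6))
})

test_that("a simulated study writes as plain text and re-reads", {
  cfg <- pipeline_config()
  sim <- simulate_study(cfg,
                        n_features = c(lncRNA = 150, miRNA = 60,
                                       mRNA = 150),
                        n_triplet = c(3, 4, 6), decoy_fraction = 0.2,
                        n_decoy_transcripts = 40, seed = 12)
  dir <- withr::local_tempdir()
  write_study(sim, dir)
  mirdb <- read_table(file.path(dir, "mirdb.tsv"), "mirdb")
  expect_equal(mirdb, sim$mirdb, tolerance = 1e-8, ignore_attr = TRUE)
  tx <- read_table(file.path(dir, "transcripts.tsv"), "transcript")
  expect_equal(nrow(tx), nrow(sim$transcripts))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 12)
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_equal(sets, sim$gene_sets)
})
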