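test_that("screening applies each rule at its stated boundary", {
  pass <- toy_transcript("ok")            # u, 500 nt, 2 exons, FPKM 0.5
  out <- screen_lncrnas(pass)
  expect_equal(nrow(out$retained), 1)

  cases <- rbind(
    toy_transcript("bad_class", class_code = "="),
    toy_transcript("bad_len", length_nt = 150),
    toy_transcript("edge_len", length_nt = 200),     # inclusive: kept
    toy_transcript("bad_exon", exon_count = 1),
    toy_transcript("bad_fpkm", fpkm = 0.05),
    toy_transcript("edge_fpkm", fpkm = 0.1),         # inclusive: kept
    toy_transcript("bad_cpc", cpc = 0.5),            # strict: dropped
    toy_transcript("bad_cnci", cnci = 0),
    toy_transcript("bad_cpat", cpat = 0.5),
    toy_transcript("bad_pfam", pfam = 0),
    toy_transcript("no_score", cpc = NA))
  out <- screen_lncrnas(cases)
  expect_setequal(out$retained$transcript_id, c("edge_len", "edge_fpkm"))
  expect_equal(unname(out$tally[c("class_code", "length", "exons",
                                  "fpkm", "missing_score", "cpc",
                                  "cnci", "cpat", "pfam")]),
               c(1, 1, 1, 1, 1, 1, 1, 1, 1))
})

test_that("the rejection tally is mutually exclusive in filter order", {
  ## fails both class code and length; must be counted at class code only
  both <- toy_transcript("b1", class_code = "=", length_nt = 100)
  out <- screen_lncrnas(both)
  expect_equal(unname(out$tally[["class_code"]]), 1)
  expect_equal(unname(out$tally[["length"]]), 0)
})

test_that("tally sums to the input size on simulated annotation tables", {
  cfg <- pipeline_config()
  sim <- simulate_study(cfg,
                        n_features = c(lncRNA = 200, miRNA = 60,
                                       mRNA = 150),
                        n_triplet = c(3, 4, 6), n_decoy_transcripts = 90,
                        seed = 44)
  out <- screen_lncrnas(sim$transcripts, cfg)
  expect_equal(sum(out$tally), nrow(sim$transcripts))
  ## decoy transcripts planted to fail the class rule all land there
  dec <- sim$truth$transcript_decoys
  expect_gte(unname(out$tally[["class_code"]]),
             sum(dec$fails == "class_code"))
  expect_gte(unname(out$tally[["missing_score"]]),
             sum(dec$fails == "missing_score"))
  ## classification of the retained set is an exhaustive partition
  cls <- classify_lncrnas(out$retained)
  expect_equal(sum(cls), nrow(out$retained))
})

test_that("class codes map to the four lncRNA classes", {
  tx <- do.call(rbind, lapply(c("u", "i", "x", "o", "e"), function(cc)
    toy_transcript(paste0("t_", cc), class_code = cc)))
  cls <- classify_lncrnas(tx)
  expect_equal(cls, c(sense = 2L, antisense = 1L, intronic = 1L,
                      intergenic = 1L))
  expect_equal(sum(classify_lncrnas(tx[0, ])), 0L)
  expect_error(classify_lncrnas(toy_transcript("z", class_code = "=")),
               "unexpected class code")
})

test_that("cis association uses the 100 kb edge-to-edge gap rule", {
  lnc <- data.frame(transcript_id = "L1", chrom = "chr1",
                    start = 1000, end = 2000)
  mk_m <- function(id, chrom, start, end)
    data.frame(transcript_id = id, chrom = chrom, start = start,
               end = end)
  mrna <- rbind(mk_m("near", "chr1", 50000, 51000),      # gap 48000
                mk_m("edge", "chr1", 102000, 103000),    # gap 100000
                mk_m("far", "chr1", 102001, 103000),     # gap 100001
                mk_m("overlap", "chr1", 1500, 2500),     # gap 0
                mk_m("other", "chr2", 1000, 2000))
  expr_l <- matrix(rnorm(5), 1, dimnames = list("L1", NULL))
  expr_m <- matrix(rnorm(25), 5,
                   dimnames = list(mrna$transcript_id, NULL))
  res <- associate_mrnas(lnc, mrna, expr_l, expr_m)
  cis_ids <- res$mrna_id[res$cis]
  expect_setequal(cis_ids, c("near", "edge", "overlap"))
  expect_equal(res$gap[res$mrna_id == "near"], 48000)
  expect_equal(res$gap[res$mrna_id == "overlap"], 0)
})

test_that("trans association reproduces the exact correlation t-test", {
  set.seed(13)
  n <- 10
  lnc <- data.frame(transcript_id = "L1", chrom = "chrX",
                    start = 1, end = 100)
  mrna <- data.frame(transcript_id = sprintf("G%02d", 1:30),
                     chrom = "chrY", start = 1, end = 100)
  e_l <- matrix(rnorm(n), 1, dimnames = list("L1", NULL))
  base <- as.numeric(e_l)
  e_m <- t(sapply(1:30, function(i)
    base * rnorm(1, 0.9, 0.6) + rnorm(n, sd = runif(1, 0.05, 2))))
  rownames(e_m) <- mrna$transcript_id
  res <- associate_mrnas(lnc, mrna, e_l, e_m)
  ## oracle: cor.test per pair, strict thresholds
  keep <- character(0)
  for (i in 1:30) {
    ct <- cor.test(base, e_m[i, ])
    if (abs(ct$estimate) > 0.9 && ct$p.value < 0.01)
      keep <- c(keep, mrna$transcript_id[i])
    j <- which(res$mrna_id == mrna$transcript_id[i])
    if (length(j) == 1) {
      expect_equal(res$r[j], unname(ct$estimate), tolerance = 1e-12)
      expect_equal(res$p[j], ct$p.value, tolerance = 1e-9)
    }
  }
  expect_setequal(res$mrna_id[res$trans], keep)
})

test_that("identical expression gives r = 1 and a trans call", {
  lnc <- data.frame(transcript_id = "L1", chrom = "chr1",
                    start = 1, end = 10)
  mrna <- data.frame(transcript_id = "G1", chrom = "chr9",
                     start = 1e7, end = 1e7 + 10)
  v <- matrix(rnorm(10), 1)
  rownames(v) <- "L1"
  w <- v; rownames(w) <- "G1"
  res <- associate_mrnas(lnc, mrna, v, w)
  expect_true(res$trans[1])
  expect_equal(res$r[1], 1)
  expect_equal(res$p[1], 0)
})

test_that("constant expression vectors are skipped for trans and flagged", {
  lnc <- data.frame(transcript_id = "L1", chrom = "chr1",
                    start = 1, end = 10)
  mrna <- data.frame(transcript_id = "G1", chrom = "chr1",
                     start = 50, end = 60)
  v <- matrix(rep(3, 6), 1, dimnames = list("L1", NULL))
  w <- matrix(rnorm(6), 1, dimnames = list("G1", NULL))
  res <- associate_mrnas(lnc, mrna, v, w)
  expect_true("L1" %in% attr(res, "trans_skipped"))
  expect_true(res$cis[1])       # still a cis pair
  expect_false(res$trans[1])
  ## strand never enters the cis rule
  expect_error(associate_mrnas(lnc, mrna, v[, 1:2, drop = FALSE],
                               w[, 1:2, drop = FALSE]), "3 shared")
})

test_that("interval gaps agree with the GenomicRanges reference", {
  set.seed(14)
  for (i in 1:25) {
    s1 <- sample(1e5, 1); e1 <- s1 + sample(5000, 1)
    s2 <- sample(1e5, 1); e2 <- s2 + sample(5000, 1)
    gr1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s1, e1))
    gr2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s2, e2))
    ref <- GenomicRanges::distance(gr1, gr2)
    got <- cernet:::interval_gap(s1, e1, s2, e2)
    ## distance() counts the positions strictly between the intervals;
    ## the edge-to-edge gap is one more for disjoint intervals
    overlap <- s1 <= e2 && s2 <= e1
    expect_equal(got, if (overlap) 0 else ref + 1)
  }
})
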