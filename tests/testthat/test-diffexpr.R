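test_that("size factors match hand-computed median-of-ratios values", {
  ## identical columns -> unit factors
  m <- matrix(c(5, 10, 20, 5, 10, 20), ncol = 2)
  expect_equal(size_factors(m), c(1, 1))
  ## column B = 2 x column A: geometric-mean centering gives sqrt(2) scale
  m <- matrix(c(10, 30, 5, 20, 60, 10), ncol = 2)
  expect_equal(size_factors(m), c(1 / sqrt(2), sqrt(2)))
  ## single feature, counts (4, 9): geometric mean 6
  m <- matrix(c(4, 9), ncol = 2)
  expect_equal(size_factors(m), c(4 / 6, 9 / 6))
})

test_that("size factors agree with the DESeq2 reference implementation", {
  set.seed(11)
  m <- matrix(rnbinom(600, mu = 50, size = 5), ncol = 6) +
    matrix(rep(c(0, 3), each = 300), ncol = 6)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(size_factors(m), unname(ref), tolerance = 1e-10)
})

test_that("degenerate count matrices are handled explicitly", {
  m <- matrix(c(0, 5, 3, 0), ncol = 2)  # no feature positive everywhere
  expect_error(size_factors(m), "poscounts")
  sf <- size_factors(m, fallback = "poscounts")
  expect_true(all(sf > 0))
  expect_error(size_factors(matrix(c(0, 0, 1, 2), ncol = 2)),
               "all-zero")
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.03), 0.03)
  set.seed(7)
  for (i in 1:5) {
    p <- runif(40)^sample(1:3, 1)
    expect_equal(bh_adjust(p), bf_bh(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH output dominates p and is monotone in p-rank", {
  set.seed(8)
  p <- runif(100)
  f <- bh_adjust(p)
  expect_true(all(f >= p))
  o <- order(p)
  expect_true(all(diff(f[o]) >= -1e-12))
})

test_that("fold changes use a 0.5 pseudo-count on group means", {
  ## 50 stable features pin the size factors at 1; the focal feature has
  ## group means 10 and 40
  set.seed(1)
  base <- matrix(rep(rpois(50, 100), 10), ncol = 10)
  m <- rbind(base, c(rep(40, 5), rep(10, 5)))
  rownames(m) <- c(sprintf("s%02d", 1:50), "focal")
  groups <- rep(c("test", "control"), each = 5)
  de <- nb_test(m, groups, ref = "control", layer = "lncRNA")
  expect_equal(de$log2fc[de$feature_id == "focal"],
               log2(40.5 / 10.5), tolerance = 1e-12)
  ## identical groups -> exactly zero fold change everywhere
  de0 <- nb_test(cbind(base, base[, 1:2]),
                 c(rep("a", 5), rep("b", 7)), ref = "a")
  expect_true(all(de0$log2fc == 0))
})

test_that("all-zero features are kept but flagged non-significant", {
  set.seed(2)
  m <- matrix(rpois(200, 30), ncol = 10)
  m[3, ] <- 0
  rownames(m) <- sprintf("f%02d", 1:20)
  de <- nb_test(m, rep(c("t", "c"), each = 5), ref = "c")
  expect_equal(de$p_value[3], 1)
  expect_equal(de$fdr[3], 1)
  expect_equal(de$direction[3], "ns")
  expect_equal(de$flag[3], "all_zero")
  expect_equal(de$log2fc[3], 0)
})

test_that("swapping group labels negates log2fc and keeps p-values", {
  set.seed(3)
  m <- matrix(rnbinom(500, mu = 60, size = 8), ncol = 10)
  rownames(m) <- sprintf("f%02d", 1:50)
  g <- rep(c("A", "B"), each = 5)
  d1 <- nb_test(m, g, ref = "A")
  d2 <- nb_test(m, g, ref = "B")
  expect_equal(d1$log2fc, -d2$log2fc, tolerance = 1e-10)
  expect_equal(d1$p_value, d2$p_value, tolerance = 1e-10)
})

test_that("planted log2 fold changes of 2 are recovered within 0.15", {
  sc <- simulate_counts(n_features = c(lncRNA = 1200, miRNA = 10,
                                       mRNA = 10),
                        dispersion = 0.1, de_fraction = c(0.1, 0, 0),
                        effect = 2, seed = 31)
  de <- nb_test(sc$counts$lncRNA, sc$groups, ref = "control",
                layer = "lncRNA")
  planted <- sc$truth$de$lncRNA
  est <- de$log2fc[match(planted$feature_id, de$feature_id)]
  expect_equal(mean(abs(est)), 2, tolerance = 0.15 / 2)
  expect_true(all(sign(est) == sign(planted$log2fc)))
})

test_that("direction calls respect the layer-specific boundary semantics", {
  cfg <- pipeline_config()
  rec <- data.frame(feature_id = c("a", "b", "c", "d"),
                    log2fc = c(1, -1, 0.99, 1),
                    p_value = c(1e-4, 1e-4, 1e-4, 0.2),
                    fdr = c(1e-3, 1e-3, 1e-3, 0.2))
  ## lncRNA: |log2fc| >= 1 inclusive, FDR < 0.01 and P < 0.05
  out <- classify_direction(rec, "lncRNA", cfg)
  expect_equal(out$records$direction, c("up", "down", "ns", "ns"))
  expect_equal(out$n_up, 1L)
  expect_equal(out$n_down, 1L)
  ## miRNA: |log2fc| > 1 strict, adjusted p < 0.05
  rec2 <- data.frame(feature_id = c("a", "b"), log2fc = c(1, 1.01),
                     p_value = 1e-4, fdr = 0.04)
  expect_equal(classify_direction(rec2, "miRNA", cfg)$records$direction,
               c("ns", "up"))
  ## mRNA: |log2fc| > 2 strict, FDR < 0.01
  rec3 <- data.frame(feature_id = c("a", "b"), log2fc = c(2, -2.2),
                     p_value = 1e-4, fdr = 1e-3)
  expect_equal(classify_direction(rec3, "mRNA", cfg)$records$direction,
               c("ns", "down"))
  ## degenerate empty input
  empty <- classify_direction(rec[0, ], "mRNA", cfg)
  expect_equal(empty$n_up + empty$n_down, 0L)
})

test_that("relative expression follows 2^-ddCt", {
  expect_equal(ddct(20, 20, 20, 20), 1)
  expect_equal(ddct(19, 20, 20, 20), 2)  # ddCt = -1
  expect_equal(ddct(20, 18, 24, 18), 16) # ddCt = 2 - 6 = -4
  expect_error(ddct(NA, 1, 1, 1), "finite")
})
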