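.layers <- c("lncRNA", "miRNA", "mRNA")

resample <- function(x, n) x[sample.int(length(x), n)]

expand_layer <- function(x, what) {
  if (length(x) == 1L && is.null(names(x)))
    return(stats::setNames(rep(x, 3L), .layers))
  if (!is.null(names(x))) {
    if (!all(.layers %in% names(x)))
      stop(what, " must name all of ", paste(.layers, collapse = ", "),
           call. = FALSE)
    return(x[.layers])
  }
  if (length(x) == 3L) return(stats::setNames(x, .layers))
  stop(what, " must be length 1, length 3, or named per layer",
       call. = FALSE)
}

#' Simulate two-group NB count matrices with planted signal
#'
#' Emits negative-binomial counts (`var = mu + dispersion * mu^2`) for the
#' three RNA layers of a test-vs-control design (test group first), with a
#' planted fraction of differentially expressed features per layer and,
#' optionally, planted ceRNA triplets whose members change direction
#' consistently (lncRNA and miRNA opposite; miRNA and mRNA opposite).
#' Baseline means are log-normal; per-sample library-size factors are
#' log-uniform in \[0.7, 1.4\]; feature lengths (lncRNA and mRNA layers)
#' are log-uniform in \[200, 10000\] nt, for deriving FPKM downstream.
#' Non-DE features share their group means exactly. Planted triplet
#' lncRNAs are emitted at high abundance relative to their length (they
#' model the highly expressed cytoplasmic sponges the prioritization stage
#' is designed to keep), so the expression-rank stage retains them.
#' The same seed always reproduces the same output.
#'
#' @param n_features features per layer (scalar or named per-layer vector).
#' @param n_per_group samples per group (>= 2).
#' @param meanlog,sdlog log-normal parameters of the baseline means.
#' @param dispersion NB dispersion alpha (> 0), shared across features.
#' @param de_fraction fraction of DE features per layer (in \[0, 1\]).
#' @param effect planted |log2FC| per layer; must be nonzero wherever
#'   `de_fraction > 0`.
#' @param n_triplet planted ceRNA members per layer (named or length-3:
#'   lncRNAs, miRNAs, mRNAs); `0` plants no triplets. Members are drawn
#'   from the planted DE sets, so each must be at most the layer's DE
#'   count.
#' @param seed integer RNG seed.
#' @return list with `counts` (named list of three integer matrices,
#'   features x samples), `groups` (character vector, `"test"` /
#'   `"control"`), `samples`, and `truth` — a `SyntheticTruth` list:
#'   per-layer planted DE tables (`feature_id`, `log2fc`), the planted
#'   triplet table and its two pair tables, per-layer feature lengths,
#'   planted localization (triplet lncRNAs are cytoplasmic), and the seed.
#' @export
simulate_counts <- function(n_features = c(lncRNA = 2000, miRNA = 600,
                                           mRNA = 2500),
                            n_per_group = 5, meanlog = 5, sdlog = 1.5,
                            dispersion = 0.1,
                            de_fraction = c(lncRNA = 0.08, miRNA = 0.2,
                                            mRNA = 0.15),
                            effect = c(lncRNA = 2, miRNA = 2, mRNA = 3),
                            n_triplet = 0,
                            seed = 1L) {
  n_features <- expand_layer(n_features, "n_features")
  de_fraction <- expand_layer(de_fraction, "de_fraction")
  effect <- expand_layer(effect, "effect")
  n_triplet <- expand_layer(n_triplet, "n_triplet")
  if (n_per_group < 2L) stop("n_per_group must be >= 2", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  if (any(de_fraction < 0 | de_fraction > 1))
    stop("de_fraction must lie in [0, 1]", call. = FALSE)
  if (any(de_fraction > 0 & effect == 0))
    stop("effect = 0 is incompatible with de_fraction > 0", call. = FALSE)

  set.seed(seed)
  ns <- 2L * n_per_group
  samples <- sprintf("T%02d", seq_len(ns))
  groups <- rep(c("test", "control"), each = n_per_group)

  prefix <- c(lncRNA = "L", miRNA = "m", mRNA = "G")
  ids <- mu0 <- lens <- lfc <- de_idx <- list()
  for (ly in .layers) {
    n <- n_features[[ly]]
    ids[[ly]] <- sprintf("%s%04d", prefix[[ly]], seq_len(n))
    mu0[[ly]] <- stats::rlnorm(n, meanlog, sdlog)
    lens[[ly]] <- if (ly == "miRNA") rep(22, n)
                  else exp(stats::runif(n, log(200), log(10000)))
    n_de <- round(de_fraction[[ly]] * n)
    de_idx[[ly]] <- if (n_de > 0L) sample.int(n, n_de) else integer(0)
    v <- numeric(n)
    if (n_de > 0L)
      v[de_idx[[ly]]] <- sample(c(1, -1), n_de, replace = TRUE) *
        effect[[ly]]
    lfc[[ly]] <- v
  }

  triplets <- pairs_lm <- pairs_mg <- NULL
  if (any(n_triplet > 0)) {
    if (any(n_triplet > vapply(de_idx, length, integer(1))))
      stop("n_triplet exceeds the planted DE count of a layer",
           call. = FALSE)
    if (any(n_triplet < 1))
      stop("triplets need members in all three layers", call. = FALSE)
    nt_l <- n_triplet[["lncRNA"]]; nt_m <- n_triplet[["miRNA"]]
    nt_g <- n_triplet[["mRNA"]]
    t_lnc <- de_idx$lncRNA[seq_len(nt_l)]
    t_mir <- de_idx$miRNA[seq_len(nt_m)]
    t_mrna <- de_idx$mRNA[seq_len(nt_g)]
    s_l <- sample(c(1, -1), nt_l, replace = TRUE, prob = c(0.7, 0.3))
    own_l <- rep(seq_len(nt_l), length.out = nt_m)  # host lncRNA per miRNA
    s_m <- -s_l[own_l]
    own_m <- rep(seq_len(nt_m), length.out = nt_g)  # host miRNA per mRNA
    s_g <- -s_m[own_m]

    ## pairs: each member is linked to its host, plus extra random
    ## direction-compatible links
    pl <- data.frame(lnc = own_l, mir = seq_len(nt_m))
    for (i in seq_len(nt_l)) {
      compat <- setdiff(which(s_m == -s_l[i]), pl$mir[pl$lnc == i])
      n_extra <- min(length(compat), sample(0:2, 1L))
      if (n_extra > 0L)
        pl <- rbind(pl, data.frame(
          lnc = i, mir = resample(compat, n_extra)))
    }
    pg <- data.frame(mir = own_m, mrna = seq_len(nt_g))
    for (j in seq_len(nt_m)) {
      compat <- setdiff(which(s_g == -s_m[j]), pg$mrna[pg$mir == j])
      n_extra <- min(length(compat), sample(0:3, 1L))
      if (n_extra > 0L)
        pg <- rbind(pg, data.frame(
          mir = j, mrna = resample(compat, n_extra)))
    }

    lfc$lncRNA[t_lnc] <- s_l * effect[["lncRNA"]]
    lfc$miRNA[t_mir] <- s_m * effect[["miRNA"]]
    lfc$mRNA[t_mrna] <- s_g * effect[["mRNA"]]

    ## planted sponges are well expressed: triplet lncRNAs dominate the
    ## FPKM ranking regardless of their planted sign (the boost scales
    ## with the effect so up-regulated background never overtakes them),
    ## and triplet miRNAs/mRNAs sit above the quantification floor
    ratio <- mu0$lncRNA / (lens$lncRNA / 1000)
    boost <- 4 * (1 + 2^effect[["lncRNA"]]) * max(ratio)
    mu0$lncRNA[t_lnc] <- boost * lens$lncRNA[t_lnc] / 1000
    mu0$miRNA[t_mir] <- pmax(mu0$miRNA[t_mir], exp(meanlog + 1))
    mu0$mRNA[t_mrna] <- pmax(mu0$mRNA[t_mrna], exp(meanlog + 1))

    dir_of <- function(s) ifelse(s > 0, "up", "down")
    pairs_lm <- data.frame(
      lncrna_id = ids$lncRNA[t_lnc[pl$lnc]],
      mirna_id = ids$miRNA[t_mir[pl$mir]],
      lnc_direction = dir_of(s_l[pl$lnc]),
      mir_direction = dir_of(s_m[pl$mir]),
      stringsAsFactors = FALSE)
    pairs_mg <- data.frame(
      mirna_id = ids$miRNA[t_mir[pg$mir]],
      mrna_id = ids$mRNA[t_mrna[pg$mrna]],
      mir_direction = dir_of(s_m[pg$mir]),
      mrna_direction = dir_of(s_g[pg$mrna]),
      stringsAsFactors = FALSE)
    triplets <- merge(pairs_lm, pairs_mg,
                      by = c("mirna_id", "mir_direction"))
    triplets <- triplets[order(triplets$lncrna_id, triplets$mirna_id,
                               triplets$mrna_id),
                         c("lncrna_id", "lnc_direction", "mirna_id",
                           "mir_direction", "mrna_id", "mrna_direction")]
    rownames(triplets) <- NULL
  }

  counts <- list()
  sfs <- list()
  test_col <- groups == "test"
  for (ly in .layers) {
    n <- n_features[[ly]]
    sf <- exp(stats::runif(ns, log(0.7), log(1.4)))
    mu <- outer(mu0[[ly]], rep(1, ns))
    mu[, test_col] <- mu[, test_col] * 2^lfc[[ly]]
    mu <- sweep(mu, 2L, sf, "*")
    cm <- matrix(stats::rnbinom(n * ns, mu = mu, size = 1 / dispersion),
                 nrow = n, dimnames = list(ids[[ly]], samples))
    counts[[ly]] <- cm
    sfs[[ly]] <- sf
  }

  de_tab <- lapply(.layers, function(ly) {
    ii <- sort(de_idx[[ly]])
    data.frame(feature_id = ids[[ly]][ii], log2fc = lfc[[ly]][ii],
               stringsAsFactors = FALSE)
  })
  names(de_tab) <- .layers

  localization <- if (!is.null(triplets)) {
    data.frame(lncrna_id = sort(unique(triplets$lncrna_id)),
               compartment = "cytoplasm", stringsAsFactors = FALSE)
  } else {
    data.frame(lncrna_id = character(0), compartment = character(0),
               stringsAsFactors = FALSE)
  }

  truth <- list(de = de_tab, triplets = triplets, pairs_lm = pairs_lm,
                pairs_mg = pairs_mg, lengths = lens, ids = ids,
                localization = localization, size_factors = sfs,
                baseline_mu = mu0, seed = seed)
  list(counts = counts, groups = groups, samples = samples, truth = truth)
}

#' FPKM from counts and feature lengths
#'
#' `fpkm_ij = count_ij / (length_i/1000 * libsize_j/1e6)` with per-sample
#' library size `libsize_j = sum_i count_ij`.
#'
#' @param counts matrix, features x samples.
#' @param lengths feature lengths in nt, recycled along rows.
#' @return matrix of the same shape.
#' @export
fpkm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  lib <- colSums(counts) / 1e6
  sweep(counts / (lengths / 1000), 2L, lib, "/")
}

pick_unused <- function(n, a_pool, b_pool, used) {
  ## sample up to n unused (a, b) combinations
  out <- data.frame(a = character(0), b = character(0),
                    stringsAsFactors = FALSE)
  guard <- 0L
  while (nrow(out) < n && guard < 50L * n + 50L) {
    guard <- guard + 1L
    a <- sample(a_pool, 1L)
    b <- sample(b_pool, 1L)
    key <- paste(a, b, sep = "\r")
    if (key %in% used) next
    used <- c(used, key)
    out <- rbind(out, data.frame(a = a, b = b, stringsAsFactors = FALSE))
  }
  out
}

#' Simulate the side tables supporting a planted truth
#'
#' Generates the miRDB-style, TargetScan-style and miRanda-style
#' prediction tables, the localization score table, the PPI edge table and
#' the gene sets that match a [simulate_counts()] truth. Every planted
#' triplet is supported by prediction rows that clear all thresholds
#' (target score in \[70, 99\], conservation in \[0.6, 0.95\]; context++
#' in \[-0.9, -0.45\]; miRanda score in \[150, 190\] with energy in
#' \[-35, -21\] kcal/mol), and the planted triplet lncRNAs score highest
#' for the cytoplasm. Decoy rows are planted in three labelled classes per
#' prediction table so each filter's rejection is attributable:
#' `score_fail` (direction-consistent but fails at least one score
#' threshold, including single-tool support on the mRNA side),
#' `direction_fail` (all scores pass but the partner changes in the same
#' direction), and `non_de` (all scores pass but the partner is not
#' differentially expressed).
#'
#' @param truth `SyntheticTruth` from [simulate_counts()] (with planted
#'   triplets).
#' @param decoy_fraction decoys per class as a fraction of the planted
#'   rows of each prediction table.
#' @param seed integer RNG seed.
#' @return list with `mirdb`, `targetscan`, `miranda`, `localization`,
#'   `ppi`, `gene_sets`, and `truth` (the input augmented with `decoys`
#'   and `enriched_sets`).
#' @export
simulate_side_tables <- function(truth, decoy_fraction = 0, seed = 1L) {
  stopifnot(is.list(truth), !is.null(truth$ids))
  if (is.null(truth$pairs_lm) || nrow(truth$pairs_lm) == 0L)
    stop("truth has no planted triplets", call. = FALSE)
  set.seed(seed)

  de_dir <- function(layer) {
    d <- truth$de[[layer]]
    stats::setNames(ifelse(d$log2fc > 0, "up", "down"), d$feature_id)
  }
  lnc_dir <- de_dir("lncRNA"); mir_dir <- de_dir("miRNA")
  mrna_dir <- de_dir("mRNA")
  t_lncs <- unique(truth$pairs_lm$lncrna_id)
  t_mirs <- unique(truth$pairs_mg$mirna_id)
  t_mrnas <- unique(truth$pairs_mg$mrna_id)
  nonde_mirs <- setdiff(truth$ids$miRNA, names(mir_dir))
  nonde_mrnas <- setdiff(truth$ids$mRNA, names(mrna_dir))

  ## planted prediction rows
  n_lm <- nrow(truth$pairs_lm)
  mirdb <- data.frame(
    lncrna_id = truth$pairs_lm$lncrna_id,
    mirna_id = truth$pairs_lm$mirna_id,
    target_score = stats::runif(n_lm, 70, 99),
    conservation = stats::runif(n_lm, 0.6, 0.95),
    stringsAsFactors = FALSE)
  n_mg <- nrow(truth$pairs_mg)
  targetscan <- data.frame(
    mirna_id = truth$pairs_mg$mirna_id,
    mrna_id = truth$pairs_mg$mrna_id,
    context_score = stats::runif(n_mg, -0.9, -0.45),
    stringsAsFactors = FALSE)
  miranda <- data.frame(
    mirna_id = truth$pairs_mg$mirna_id,
    mrna_id = truth$pairs_mg$mrna_id,
    miranda_score = stats::runif(n_mg, 150, 190),
    miranda_energy = stats::runif(n_mg, -35, -21),
    stringsAsFactors = FALSE)

  decoys <- list()
  if (decoy_fraction > 0) {
    nd_lm <- ceiling(decoy_fraction * n_lm)
    nd_mg <- ceiling(decoy_fraction * n_mg)
    used_lm <- paste(mirdb$lncrna_id, mirdb$mirna_id, sep = "\r")
    used_mg <- paste(targetscan$mirna_id, targetscan$mrna_id, sep = "\r")
    opp <- c(up = "down", down = "up")

    add_lm <- function(class, mir_pool, score_fail) {
      if (length(mir_pool) == 0L) return(NULL)
      pk <- pick_unused(nd_lm, t_lncs, mir_pool, used_lm)
      if (nrow(pk) == 0L) return(NULL)
      used_lm <<- c(used_lm, paste(pk$a, pk$b, sep = "\r"))
      n <- nrow(pk)
      sc <- stats::runif(n, 70, 99)
      cv <- stats::runif(n, 0.6, 0.95)
      if (score_fail) {
        fail_score <- sample(c(TRUE, FALSE), n, replace = TRUE)
        sc[fail_score] <- stats::runif(sum(fail_score), 10, 59.9)
        cv[!fail_score] <- stats::runif(sum(!fail_score), 0.05, 0.5)
      }
      mirdb <<- rbind(mirdb, data.frame(
        lncrna_id = pk$a, mirna_id = pk$b, target_score = sc,
        conservation = cv, stringsAsFactors = FALSE))
      data.frame(table = "mirdb", a = pk$a, b = pk$b, class = class,
                 stringsAsFactors = FALSE)
    }

    ## direction-compatible miRNA pool per lncRNA differs; draw decoys
    ## against the pooled opposite/same-direction DE miRNAs of up-lncRNAs
    ## (the dominant planted pattern) and let the filters do the rest
    lnc_d <- lnc_dir[t_lncs]
    de_mirs <- names(mir_dir)
    decoys$lm_score <- add_lm("score_fail",
      setdiff(de_mirs[mir_dir[de_mirs] != lnc_d[1L]], t_mirs), TRUE)
    decoys$lm_dir <- add_lm("direction_fail",
      setdiff(de_mirs[mir_dir[de_mirs] == lnc_d[1L]], t_mirs), FALSE)
    decoys$lm_nonde <- add_lm("non_de", nonde_mirs, FALSE)
    ## direction_fail rows drawn for the first lncRNA's direction can
    ## attach to other planted lncRNAs of the opposite sign and pass;
    ## restrict them to lncRNAs sharing that direction
    if (!is.null(decoys$lm_dir)) {
      fix <- decoys$lm_dir$a
      keep_lnc <- names(lnc_d[lnc_d == lnc_d[1L]])
      bad <- !(fix %in% keep_lnc)
      if (any(bad)) {
        repl <- sample(keep_lnc, sum(bad), replace = TRUE)
        key_old <- paste(decoys$lm_dir$a[bad], decoys$lm_dir$b[bad],
                         sep = "\r")
        rows <- match(key_old, paste(mirdb$lncrna_id, mirdb$mirna_id,
                                     sep = "\r"))
        mirdb$lncrna_id[rows] <- repl
        decoys$lm_dir$a[bad] <- repl
      }
    }

    add_mg <- function(class, mrna_pool, kind) {
      if (length(mrna_pool) == 0L) return(NULL)
      pk <- pick_unused(nd_mg, t_mirs, mrna_pool, used_mg)
      if (nrow(pk) == 0L) return(NULL)
      used_mg <<- c(used_mg, paste(pk$a, pk$b, sep = "\r"))
      n <- nrow(pk)
      ctx <- stats::runif(n, -0.9, -0.45)
      msc <- stats::runif(n, 150, 190)
      men <- stats::runif(n, -35, -21)
      single <- rep(FALSE, n)
      if (kind == "score") {
        mode <- sample(4L, n, replace = TRUE)
        ctx[mode == 1L] <- stats::runif(sum(mode == 1L), -0.39, -0.05)
        msc[mode == 2L] <- stats::runif(sum(mode == 2L), 80, 140)
        men[mode == 3L] <- stats::runif(sum(mode == 3L), -19.9, -5)
        single <- mode == 4L
      }
      targetscan <<- rbind(targetscan, data.frame(
        mirna_id = pk$a, mrna_id = pk$b, context_score = ctx,
        stringsAsFactors = FALSE))
      add_mir <- !single
      if (any(add_mir))
        miranda <<- rbind(miranda, data.frame(
          mirna_id = pk$a[add_mir], mrna_id = pk$b[add_mir],
          miranda_score = msc[add_mir], miranda_energy = men[add_mir],
          stringsAsFactors = FALSE))
      data.frame(table = "mir_mrna", a = pk$a, b = pk$b, class = class,
                 stringsAsFactors = FALSE)
    }

    de_mrnas <- names(mrna_dir)
    mir_d <- mir_dir[t_mirs]
    decoys$mg_score <- add_mg("score_fail",
      setdiff(de_mrnas[mrna_dir[de_mrnas] != mir_d[1L]], t_mrnas),
      "score")
    decoys$mg_dir <- add_mg("direction_fail",
      setdiff(de_mrnas[mrna_dir[de_mrnas] == mir_d[1L]], t_mrnas),
      "dir")
    if (!is.null(decoys$mg_dir)) {
      keep_mir <- names(mir_d[mir_d == mir_d[1L]])
      bad <- !(decoys$mg_dir$a %in% keep_mir)
      if (any(bad)) {
        repl <- sample(keep_mir, sum(bad), replace = TRUE)
        key_old <- paste(decoys$mg_dir$a[bad], decoys$mg_dir$b[bad],
                         sep = "\r")
        rows_ts <- match(key_old, paste(targetscan$mirna_id,
                                        targetscan$mrna_id, sep = "\r"))
        targetscan$mirna_id[rows_ts] <- repl
        rows_mr <- match(key_old, paste(miranda$mirna_id,
                                        miranda$mrna_id, sep = "\r"))
        ok <- !is.na(rows_mr)
        miranda$mirna_id[rows_mr[ok]] <- repl[ok]
        decoys$mg_dir$a[bad] <- repl
      }
    }
    decoys$mg_nonde <- add_mg("non_de", nonde_mrnas, "none")
  }
  decoy_tab <- do.call(rbind, decoys[!vapply(decoys, is.null,
                                             logical(1))])
  ## direction reassignment above can in rare cases collide with an
  ## existing pair; keep the first occurrence so pair keys stay unique
  mirdb <- mirdb[!duplicated(paste(mirdb$lncrna_id, mirdb$mirna_id,
                                   sep = "\r")), ]
  targetscan <- targetscan[!duplicated(paste(targetscan$mirna_id,
                                             targetscan$mrna_id,
                                             sep = "\r")), ]
  miranda <- miranda[!duplicated(paste(miranda$mirna_id,
                                       miranda$mrna_id, sep = "\r")), ]

  ## localization: triplet lncRNAs in the cytoplasm; other DE lncRNAs get
  ## a random compartment with realistic nucleus/cytoplasm dominance
  other_lncs <- setdiff(names(lnc_dir), t_lncs)
  comp_other <- sample(.compartments, length(other_lncs), replace = TRUE,
                       prob = c(0.35, 0.45, 0.07, 0.07, 0.06))
  loc_ids <- c(t_lncs, other_lncs)
  loc_comp <- c(rep("cytoplasm", length(t_lncs)), comp_other)
  nl <- length(loc_ids)
  loc <- data.frame(lncrna_id = loc_ids, stringsAsFactors = FALSE)
  for (cm in .compartments) loc[[cm]] <- stats::runif(nl, 0.01, 0.35)
  for (i in seq_len(nl)) loc[[loc_comp[i]]][i] <- stats::runif(1, 0.5, 0.9)

  ## PPI: hub-and-spoke structure over the triplet mRNAs plus background
  de_mrnas <- names(mrna_dir)
  ppi_nodes <- unique(c(t_mrnas,
                        sample(de_mrnas, min(120, length(de_mrnas)))))
  n_hub <- min(5L, length(t_mrnas))
  hubs <- sample(t_mrnas, n_hub)
  ed <- list()
  for (h in hubs) {
    nb <- sample(setdiff(ppi_nodes, h), sample(8:15, 1L))
    ed[[h]] <- data.frame(protein_a = h, protein_b = nb,
                          combined_score = stats::runif(length(nb),
                                                        0.45, 0.95),
                          stringsAsFactors = FALSE)
  }
  nbg <- 2L * length(ppi_nodes)
  bg <- data.frame(protein_a = sample(ppi_nodes, nbg, replace = TRUE),
                   protein_b = sample(ppi_nodes, nbg, replace = TRUE),
                   combined_score = stats::runif(nbg, 0.05, 0.95),
                   stringsAsFactors = FALSE)
  ppi <- rbind(do.call(rbind, ed), bg)
  ppi <- ppi[ppi$protein_a != ppi$protein_b, ]
  key <- paste(pmin(ppi$protein_a, ppi$protein_b),
               pmax(ppi$protein_a, ppi$protein_b))
  ppi <- ppi[!duplicated(key), ]
  rownames(ppi) <- NULL

  ## gene sets: a few sets enriched in up-regulated DE mRNAs + background
  universe <- truth$ids$mRNA
  up_mrnas <- names(mrna_dir)[mrna_dir == "up"]
  sets <- list()
  for (i in 1:3) {
    n_in <- min(30L, length(up_mrnas))
    sets[[sprintf("SET_ENR_%02d", i)]] <-
      unique(c(sample(up_mrnas, n_in),
               sample(universe, 20)))
  }
  for (i in 1:10)
    sets[[sprintf("SET_BG_%02d", i)]] <- sample(universe,
                                                sample(30:80, 1L))
  truth$decoys <- decoy_tab
  truth$enriched_sets <- grep("^SET_ENR", names(sets), value = TRUE)
  truth$localization <- data.frame(lncrna_id = loc_ids,
                                   compartment = loc_comp,
                                   stringsAsFactors = FALSE)
  list(mirdb = mirdb, targetscan = targetscan, miranda = miranda,
       localization = loc, ppi = ppi, gene_sets = sets, truth = truth)
}
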