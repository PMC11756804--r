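#' Simulate a complete two-group ceRNA study
#'
#' One call produces everything the staged pipeline consumes: the three
#' count matrices with planted DE and planted ceRNA triplets
#' ([simulate_counts()]), the prediction / localization / PPI / gene-set
#' side tables ([simulate_side_tables()]), the transcript annotation table
#' for the screening stage (all count features carry lncRNA-compatible
#' class codes, lengths, exon counts, coding-potential scores and
#' count-derived FPKM; a block of decoy transcripts fails each screening
#' rule in turn), and genomic coordinates for the cis/trans association
#' stage.
#'
#' @param config a [pipeline_config()] (supplies the default seed).
#' @param n_features,n_per_group,meanlog,sdlog,dispersion,de_fraction,effect
#'   passed to [simulate_counts()].
#' @param n_triplet planted triplet members per layer.
#' @param decoy_fraction decoy rows per class in the prediction tables,
#'   as a fraction of planted rows.
#' @param n_decoy_transcripts decoy rows in the transcript annotation
#'   table (split evenly across the failing rules).
#' @param seed integer RNG seed (defaults to `config$seed`).
#' @return list with `counts`, `groups`, `samples`, `transcripts`,
#'   `fpkm` (lncRNA layer), `mrna_coords`, `mirdb`, `targetscan`,
#'   `miranda`, `localization`, `ppi`, `gene_sets`, `truth`, `config`.
#' @export
simulate_study <- function(config = pipeline_config(),
                           n_features = c(lncRNA = 2000, miRNA = 600,
                                          mRNA = 2500),
                           n_per_group = 5, meanlog = 5, sdlog = 1.5,
                           dispersion = 0.1,
                           de_fraction = c(lncRNA = 0.08, miRNA = 0.2,
                                           mRNA = 0.15),
                           effect = c(lncRNA = 2, miRNA = 2, mRNA = 3),
                           n_triplet = c(lncRNA = 8, miRNA = 10,
                                         mRNA = 25),
                           decoy_fraction = 0.3,
                           n_decoy_transcripts = 600,
                           seed = config$seed) {
  sc <- simulate_counts(n_features = n_features,
                        n_per_group = n_per_group, meanlog = meanlog,
                        sdlog = sdlog, dispersion = dispersion,
                        de_fraction = de_fraction, effect = effect,
                        n_triplet = n_triplet, seed = seed)
  st <- simulate_side_tables(sc$truth, decoy_fraction = decoy_fraction,
                             seed = seed + 1L)
  truth <- st$truth

  set.seed(seed + 2L)
  lnc_ids <- truth$ids$lncRNA
  n_lnc <- length(lnc_ids)
  lnc_fpkm <- fpkm(sc$counts$lncRNA, truth$lengths$lncRNA)
  colnames(lnc_fpkm) <- sc$samples

  mk_coords <- function(n) {
    chrom <- sample(paste0("chr", 1:20), n, replace = TRUE)
    start <- floor(stats::runif(n, 1, 1e8))
    list(chrom = chrom, start = start)
  }
  co <- mk_coords(n_lnc)
  transcripts <- data.frame(
    transcript_id = lnc_ids,
    class_code = sample(c("u", "i", "x", "o", "e"), n_lnc,
                        replace = TRUE,
                        prob = c(0.072, 0.206, 0.085, 0.32, 0.317)),
    length_nt = round(truth$lengths$lncRNA),
    exon_count = sample(2:20, n_lnc, replace = TRUE),
    cpc_score = stats::runif(n_lnc, -1, 0.45),
    cnci_score = stats::runif(n_lnc, -5, -0.05),
    cpat_score = stats::runif(n_lnc, 0, 0.45),
    pfam_score = stats::runif(n_lnc, -10, -0.5),
    chrom = co$chrom, start = co$start,
    end = co$start + round(truth$lengths$lncRNA) - 1,
    strand = sample(c("+", "-"), n_lnc, replace = TRUE),
    stringsAsFactors = FALSE)
  fpkm_df <- as.data.frame(lnc_fpkm)
  names(fpkm_df) <- paste0("fpkm_", sc$samples)
  transcripts <- cbind(transcripts, fpkm_df)

  ## decoy transcripts: one failing rule each, cycling through the rules
  nd <- n_decoy_transcripts
  if (nd > 0L) {
    rules <- c("class_code", "length", "exons", "fpkm", "cpc", "cnci",
               "cpat", "pfam", "missing_score")
    fail <- rep_len(rules, nd)
    dco <- mk_coords(nd)
    dlen <- round(exp(stats::runif(nd, log(300), log(5000))))
    dec <- data.frame(
      transcript_id = sprintf("TX%05d", seq_len(nd)),
      class_code = ifelse(fail == "class_code",
                          sample(c("=", "j", "c", "p"), nd, TRUE), "u"),
      length_nt = ifelse(fail == "length",
                         round(stats::runif(nd, 50, 199)), dlen),
      exon_count = ifelse(fail == "exons", 1L,
                          sample(2:20, nd, replace = TRUE)),
      cpc_score = ifelse(fail == "cpc", stats::runif(nd, 0.5, 3),
                         stats::runif(nd, -1, 0.45)),
      cnci_score = ifelse(fail == "cnci", stats::runif(nd, 0, 3),
                          stats::runif(nd, -5, -0.05)),
      cpat_score = ifelse(fail == "cpat", stats::runif(nd, 0.5, 1),
                          stats::runif(nd, 0, 0.45)),
      pfam_score = ifelse(fail == "pfam", stats::runif(nd, 0, 5),
                          stats::runif(nd, -10, -0.5)),
      chrom = dco$chrom, start = dco$start,
      end = dco$start + dlen - 1,
      strand = sample(c("+", "-"), nd, replace = TRUE),
      stringsAsFactors = FALSE)
    dec$cpc_score[fail == "missing_score"] <- NA_real_
    dfp <- matrix(stats::runif(nd * length(sc$samples), 0.2, 50),
                  nrow = nd)
    dfp[fail == "fpkm", ] <- stats::runif(sum(fail == "fpkm") *
                                            length(sc$samples), 0, 0.09)
    dfp_df <- as.data.frame(dfp)
    names(dfp_df) <- paste0("fpkm_", sc$samples)
    dec <- cbind(dec, dfp_df)
    truth$transcript_decoys <- data.frame(transcript_id =
                                            dec$transcript_id,
                                          fails = fail,
                                          stringsAsFactors = FALSE)
    transcripts <- rbind(transcripts, dec)
  }

  mco <- mk_coords(length(truth$ids$mRNA))
  mrna_coords <- data.frame(
    transcript_id = truth$ids$mRNA, chrom = mco$chrom,
    start = mco$start,
    end = mco$start + round(truth$lengths$mRNA) - 1,
    stringsAsFactors = FALSE)

  list(counts = sc$counts, groups = sc$groups, samples = sc$samples,
       transcripts = transcripts, fpkm = lnc_fpkm,
       mrna_coords = mrna_coords, mirdb = st$mirdb,
       targetscan = st$targetscan, miranda = st$miranda,
       localization = st$localization, ppi = st$ppi,
       gene_sets = st$gene_sets, truth = truth, config = config)
}

#' Run the full staged ceRNA pipeline
#'
#' Executes, in order: lncRNA screening; NB differential expression for
#' the three layers; core-DEL selection by expression x significance
#' ranks; cytoplasmic gating; lncRNA-miRNA and miRNA-mRNA prediction
#' filtering with the sponge direction rule; triplet assembly; PPI hub
#' genes over the network mRNAs; the hub-induced core subnetwork; and
#' hypergeometric over-representation of the DE mRNAs. When `outdir` is
#' given, stage tables, SIF/GraphML network exports and a JSON run
#' manifest are written there.
#'
#' @param sim a study object from [simulate_study()] or an equivalent
#'   list of input tables.
#' @param config a [pipeline_config()].
#' @param outdir optional output directory.
#' @return list with elements `screen`, `classes`, `de` (per layer),
#'   `dels`, `core`, `gate`, `lnc_mir`, `mir_mrna`, `cerna`, `hubs`,
#'   `core_sub`, `enrichment`, `counts_summary`.
#' @export
run_pipeline <- function(sim, config = pipeline_config(),
                         outdir = NULL) {
  scr <- screen_lncrnas(sim$transcripts, config)
  classes <- classify_lncrnas(scr$retained)
  retained_ids <- intersect(scr$retained$transcript_id,
                            rownames(sim$counts$lncRNA))

  de <- list(
    lncRNA = nb_test(sim$counts$lncRNA[retained_ids, , drop = FALSE],
                     sim$groups, ref = "control", layer = "lncRNA",
                     config = config),
    miRNA = nb_test(sim$counts$miRNA, sim$groups, ref = "control",
                    layer = "miRNA", config = config),
    mRNA = nb_test(sim$counts$mRNA, sim$groups, ref = "control",
                   layer = "mRNA", config = config))

  dels <- de$lncRNA[de$lncRNA$direction != "ns", , drop = FALSE]
  if (nrow(dels) > 0L) {
    core <- suppressWarnings(
      select_core_dels(dels, sim$fpkm, config = config))
  } else {
    core <- list(stage1 = character(0), stage2 = character(0),
                 ranks = NULL)
  }
  gate <- gate_cytoplasmic(core$stage2, sim$localization, config)

  lnc_mir <- lnc_mir_pairs(gate$cytoplasmic, sim$mirdb, de$miRNA,
                           de$lncRNA, config)
  mir_mrna <- mir_mrna_pairs(unique(lnc_mir$pairs$mirna_id),
                             sim$targetscan, sim$miranda, de$mRNA,
                             de$miRNA, config)
  cerna <- assemble_cerna(lnc_mir$pairs, mir_mrna$pairs)

  net_mrnas <- unique(cerna$triplets$mrna_id)
  hubs <- if (length(net_mrnas) > 0L) {
    hub_genes(sim$ppi, net_mrnas, config = config)
  } else {
    list(hubs = character(0), table = NULL, n_nodes = 0L, n_edges = 0L)
  }
  core_sub <- if (length(hubs$hubs) > 0L && nrow(cerna$triplets) > 0L) {
    core_subnetwork(cerna$triplets, hubs$hubs)
  } else {
    NULL
  }

  de_mrnas <- de$mRNA$feature_id[de$mRNA$direction != "ns"]
  enrichment <- enrich(de_mrnas, sim$gene_sets, de$mRNA$feature_id)

  counts_summary <- c(
    transcripts_in = nrow(sim$transcripts),
    lncrnas_retained = unname(scr$tally[["retained"]]),
    dels = nrow(dels),
    dels_up = sum(dels$direction == "up"),
    dels_down = sum(dels$direction == "down"),
    de_mirnas = sum(de$miRNA$direction != "ns"),
    de_mrnas = sum(de$mRNA$direction != "ns"),
    core_stage1 = length(core$stage1),
    core_stage2 = length(core$stage2),
    cytoplasmic = length(gate$cytoplasmic),
    lnc_mir_pairs = nrow(lnc_mir$pairs),
    mir_mrna_pairs = nrow(mir_mrna$pairs),
    cerna_lncrnas = unname(cerna$composition[["lncRNA"]]),
    cerna_mirnas = unname(cerna$composition[["miRNA"]]),
    cerna_mrnas = unname(cerna$composition[["mRNA"]]),
    hub_genes = length(hubs$hubs))

  res <- list(screen = scr, classes = classes, de = de, dels = dels,
              core = core, gate = gate, lnc_mir = lnc_mir,
              mir_mrna = mir_mrna, cerna = cerna, hubs = hubs,
              core_sub = core_sub, enrichment = enrichment,
              counts_summary = counts_summary)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (ly in names(de))
      write_table(de[[ly]], file.path(outdir, paste0("de_", ly, ".tsv")))
    write_table(cerna$triplets, file.path(outdir, "cerna_triplets.tsv"))
    export_network(cerna$network, file.path(outdir, "cerna_network.sif"),
                   "sif")
    export_network(cerna$network,
                   file.path(outdir, "cerna_network.graphml"), "graphml")
    if (!is.null(hubs$table))
      write_table(hubs$table, file.path(outdir, "hub_genes.tsv"))
    write_table(enrichment, file.path(outdir, "enrichment.tsv"))
    write_manifest(config, file.path(outdir, "run_manifest.json"),
                   extra = list(counts_summary = as.list(counts_summary)))
  }
  res
}

#' Planted-triplet recovery
#'
#' Precision and recall of a pipeline triplet set against the planted
#' truth.
#'
#' @param triplets data.frame with `lncrna_id`, `mirna_id`, `mrna_id`
#'   (e.g. `run_pipeline(...)$cerna$triplets`).
#' @param truth `SyntheticTruth` with a planted `triplets` table.
#' @return named numeric: `precision`, `recall`, `tp`, `n_called`,
#'   `n_planted`.
#' @export
triplet_recovery <- function(triplets, truth) {
  key <- function(d) paste(d$lncrna_id, d$mirna_id, d$mrna_id)
  called <- unique(key(triplets))
  planted <- unique(key(truth$triplets))
  tp <- length(intersect(called, planted))
  c(precision = if (length(called) > 0L) tp / length(called) else 1,
    recall = if (length(planted) > 0L) tp / length(planted) else 1,
    tp = tp, n_called = length(called), n_planted = length(planted))
}

#' Write a simulated study to disk
#'
#' Writes every input table of a [simulate_study()] object as plain text
#' (TSV, GMT, JSON truth), mirroring what a real study would provide.
#'
#' @param sim a [simulate_study()] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ly in names(sim$counts)) {
    df <- data.frame(feature_id = rownames(sim$counts[[ly]]),
                     sim$counts[[ly]], check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_table(df, file.path(dir, paste0("counts_", ly, ".tsv")))
  }
  write_table(data.frame(sample = sim$samples, group = sim$groups),
              file.path(dir, "groups.tsv"))
  write_table(sim$transcripts, file.path(dir, "transcripts.tsv"))
  write_table(sim$localization, file.path(dir, "localization.tsv"))
  write_table(sim$mirdb, file.path(dir, "mirdb.tsv"))
  write_table(sim$targetscan, file.path(dir, "targetscan.tsv"))
  write_table(sim$miranda, file.path(dir, "miranda.tsv"))
  write_table(sim$ppi, file.path(dir, "ppi.tsv"))
  write_gmt(sim$gene_sets, file.path(dir, "gene_sets.gmt"))
  truth <- sim$truth
  truth$baseline_mu <- NULL  # bulky, derivable from the seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
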