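#' Pipeline configuration
#'
#' Bundles every threshold the staged ceRNA pipeline applies, so a run is
#' fully described by (input tables, config, seed). Defaults are the
#' screening, differential-expression, target-prediction, localization and
#' network cutoffs used throughout the package documentation.
#'
#' Layer-specific differential-expression gates (a feature is called
#' up/down only if all gates for its layer pass):
#' \itemize{
#'   \item lncRNA: fold change >= 2 (i.e. |log2FC| >= 1, inclusive),
#'     FDR < 0.01 and raw P < 0.05;
#'   \item miRNA: |log2FC| > 1 (strict) and adjusted p (FDR) < 0.05;
#'   \item mRNA: |log2FC| > 2 (strict) and FDR < 0.01.
#' }
#'
#' Target-prediction gates follow the wording of the source databases
#' literally: miRDB-style target score >= 60 (inclusive) with conservation
#' > 0.5 (strict); TargetScan-style context++ score <= -0.4 (inclusive);
#' miRanda-style score > 140 (strict) with energy < -20 kcal/mol (strict).
#'
#' @param lnc_lfc,lnc_fdr,lnc_p lncRNA gates: minimum |log2FC| (inclusive),
#'   FDR ceiling (strict), raw-P ceiling (strict).
#' @param mirna_lfc,mirna_fdr miRNA gates: |log2FC| floor (strict) and
#'   adjusted-p ceiling (strict).
#' @param mrna_lfc,mrna_fdr mRNA gates: |log2FC| floor (strict) and FDR
#'   ceiling (strict).
#' @param mirdb_score miRDB-style minimum target score, inclusive (0-100).
#' @param mirdb_conservation miRDB-style conservation floor, strict (0-1).
#' @param context_max TargetScan-style context++ ceiling, inclusive.
#' @param miranda_min miRanda-style score floor, strict.
#' @param energy_max miRanda-style energy ceiling in kcal/mol, strict.
#' @param ppi_min PPI combined-confidence floor, inclusive (0-1 scale).
#' @param k_big,k_small,n_hub prioritization list sizes: top-K intersection,
#'   top-k union, and hub-gene count.
#' @param length_min,exon_min,fpkm_min basic lncRNA screening floors
#'   (length in nt, inclusive; exon count, inclusive; FPKM, inclusive).
#' @param fpkm_rule whether the FPKM floor applies to the `"max"` (default)
#'   or the `"mean"` across samples.
#' @param cpc_max,cnci_max,cpat_max,pfam_max coding-potential ceilings, all
#'   strict (`<`).
#' @param cis_window maximum edge-to-edge genomic gap, in bp, for a cis
#'   lncRNA-mRNA association (overlap counts as gap 0).
#' @param trans_r,trans_p trans association gates: |Pearson r| floor
#'   (strict) and two-sided P ceiling (strict).
#' @param expr_rank_stat statistic ranking "expression level" for core-DEL
#'   selection: `"mean"` (default) or `"max"` FPKM across samples.
#' @param merge_cytosol if `TRUE`, a cytosol argmax also passes the
#'   cytoplasmic gate. Default `FALSE` (cytosol stays distinct).
#' @param direction_rule how same-trend lncRNA-miRNA predictions are
#'   removed: `"per_pair"` (default; each offending pair is dropped) or
#'   `"per_mirna"` (a miRNA with any same-trend core partner is dropped
#'   entirely).
#' @param hub_measure centrality ranking hub genes: `"degree"` (default),
#'   `"betweenness"` or `"closeness"`.
#' @param sf_fallback what [size_factors()] does when no feature is
#'   positive in all samples: `"error"` (default) or `"poscounts"`.
#' @param seed integer seed recorded in the run manifest.
#'
#' @return An object of class `"pipeline_config"`: a validated named list.
#' @seealso [write_config()], [read_config()], [write_manifest()]
#' @export
#' @examples
#' cfg <- pipeline_config(k_small = 10)
#' cfg$k_small
pipeline_config <- function(lnc_lfc = 1, lnc_fdr = 0.01, lnc_p = 0.05,
                            mirna_lfc = 1, mirna_fdr = 0.05,
                            mrna_lfc = 2, mrna_fdr = 0.01,
                            mirdb_score = 60, mirdb_conservation = 0.5,
                            context_max = -0.4, miranda_min = 140,
                            energy_max = -20,
                            ppi_min = 0.4,
                            k_big = 200, k_small = 20, n_hub = 20,
                            length_min = 200, exon_min = 2, fpkm_min = 0.1,
                            fpkm_rule = c("max", "mean"),
                            cpc_max = 0.5, cnci_max = 0, cpat_max = 0.5,
                            pfam_max = 0,
                            cis_window = 1e5, trans_r = 0.9, trans_p = 0.01,
                            expr_rank_stat = c("mean", "max"),
                            merge_cytosol = FALSE,
                            direction_rule = c("per_pair", "per_mirna"),
                            hub_measure = c("degree", "betweenness",
                                            "closeness"),
                            sf_fallback = c("error", "poscounts"),
                            seed = 1L) {
  nm <- function(x) if (is.numeric(x)) as.numeric(x) else x
  cfg <- list(
    lnc_lfc = nm(lnc_lfc), lnc_fdr = nm(lnc_fdr), lnc_p = nm(lnc_p),
    mirna_lfc = nm(mirna_lfc), mirna_fdr = nm(mirna_fdr),
    mrna_lfc = nm(mrna_lfc), mrna_fdr = nm(mrna_fdr),
    mirdb_score = nm(mirdb_score),
    mirdb_conservation = nm(mirdb_conservation),
    context_max = nm(context_max), miranda_min = nm(miranda_min),
    energy_max = nm(energy_max),
    ppi_min = nm(ppi_min),
    k_big = as.integer(k_big), k_small = as.integer(k_small),
    n_hub = as.integer(n_hub),
    length_min = nm(length_min), exon_min = nm(exon_min),
    fpkm_min = nm(fpkm_min),
    fpkm_rule = match.arg(fpkm_rule),
    cpc_max = nm(cpc_max), cnci_max = nm(cnci_max),
    cpat_max = nm(cpat_max), pfam_max = nm(pfam_max),
    cis_window = nm(cis_window), trans_r = nm(trans_r),
    trans_p = nm(trans_p),
    expr_rank_stat = match.arg(expr_rank_stat),
    merge_cytosol = isTRUE(merge_cytosol),
    direction_rule = match.arg(direction_rule),
    hub_measure = match.arg(hub_measure),
    sf_fallback = match.arg(sf_fallback),
    seed = as.integer(seed)
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  num <- c("lnc_lfc", "lnc_fdr", "lnc_p", "mirna_lfc", "mirna_fdr",
           "mrna_lfc", "mrna_fdr", "mirdb_score", "mirdb_conservation",
           "context_max", "miranda_min", "energy_max", "ppi_min",
           "length_min", "exon_min", "fpkm_min", "cpc_max", "cnci_max",
           "cpat_max", "pfam_max", "cis_window", "trans_r", "trans_p")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("config field '", f, "' must be a single finite number",
           call. = FALSE)
  }
  if (cfg$k_small > cfg$k_big)
    stop("config requires k_small <= k_big", call. = FALSE)
  if (cfg$n_hub < 1L) stop("config requires n_hub >= 1", call. = FALSE)
  if (cfg$k_small < 1L || cfg$k_big < 1L)
    stop("config requires k_small >= 1 and k_big >= 1", call. = FALSE)
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("ceRNA pipeline configuration\n")
  cat(sprintf("  DE gates   lncRNA |log2FC| >= %g, FDR < %g, P < %g\n",
              x$lnc_lfc, x$lnc_fdr, x$lnc_p))
  cat(sprintf("             miRNA  |log2FC| > %g, adj. p < %g\n",
              x$mirna_lfc, x$mirna_fdr))
  cat(sprintf("             mRNA   |log2FC| > %g, FDR < %g\n",
              x$mrna_lfc, x$mrna_fdr))
  cat(sprintf("  targets    miRDB score >= %g, conservation > %g\n",
              x$mirdb_score, x$mirdb_conservation))
  cat(sprintf("             context++ <= %g; miRanda > %g, energy < %g\n",
              x$context_max, x$miranda_min, x$energy_max))
  cat(sprintf("  network    PPI confidence >= %g, %d hub genes (%s)\n",
              x$ppi_min, x$n_hub, x$hub_measure))
  cat(sprintf("  ranks      K_big = %d, K_small = %d (%s FPKM)\n",
              x$k_big, x$k_small, x$expr_rank_stat))
  cat(sprintf("  seed       %d\n", x$seed))
  invisible(x)
}

#' Write / read a pipeline configuration
#'
#' Plain-text JSON serialization; `read_config(write_config(cfg))`
#' reproduces `cfg` exactly.
#'
#' @param config a [pipeline_config()] object.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Emit a run manifest
#'
#' Records every threshold, the seed and the package version alongside a
#' run's outputs, so the run is reproducible from inputs + manifest.
#'
#' @param config a [pipeline_config()].
#' @param path output JSON path.
#' @param extra optional named list of additional fields (input file paths,
#'   stage counts, ...).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, extra = list()) {
  stopifnot(inherits(config, "pipeline_config"))
  man <- list(
    package = "cernet",
    version = as.character(utils::packageVersion("cernet")),
    config = unclass(config)
  )
  man <- c(man, extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
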