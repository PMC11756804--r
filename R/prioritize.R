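#' Select core differentially expressed lncRNAs
#'
#' Two-stage rank intersection over a set of differentially expressed
#' lncRNAs (DELs). Expression rank is descending mean FPKM over all
#' samples (`config$expr_rank_stat` switches to max); significance rank is
#' ascending FDR, then ascending P, then descending |log2FC|, then
#' ascending id. Stage 1 intersects the top `k_big` of both ranks; stage 2
#' takes, within stage 1, the union of the top `k_small` by each rank.
#' All ranked lists break remaining ties by ascending lexicographic id, so
#' the result never depends on input row order.
#'
#' @param dels data.frame of DE-passing lncRNAs with `feature_id`,
#'   `log2fc`, `p_value`, `fdr`.
#' @param fpkm matrix of per-sample FPKM values with row names covering
#'   `dels$feature_id`.
#' @param k_big,k_small list sizes (default from `config`); `k_small <=
#'   k_big`. Values exceeding `nrow(dels)` are clamped with a warning.
#' @param config a [pipeline_config()].
#' @return list with `stage1` and `stage2` (sorted character vectors of
#'   ids) and `ranks` (data.frame with both rank columns).
#' @export
select_core_dels <- function(dels, fpkm, k_big = config$k_big,
                             k_small = config$k_small,
                             config = pipeline_config()) {
  stopifnot(all(c("feature_id", "log2fc", "p_value", "fdr") %in%
                  names(dels)))
  fpkm <- as.matrix(fpkm)
  missing <- setdiff(dels$feature_id, rownames(fpkm))
  if (length(missing) > 0L)
    stop("no FPKM rows for: ", paste(utils::head(missing, 5),
                                     collapse = ", "), call. = FALSE)
  n <- nrow(dels)
  if (k_small > k_big) stop("k_small must be <= k_big", call. = FALSE)
  if (k_big > n) {
    warning("k_big (", k_big, ") exceeds number of DELs (", n,
            "); clamped", call. = FALSE)
    k_big <- n
  }
  if (k_small > n) {
    warning("k_small (", k_small, ") exceeds number of DELs (", n,
            "); clamped", call. = FALSE)
    k_small <- n
  }

  fmat <- fpkm[dels$feature_id, , drop = FALSE]
  expr_stat <- if (config$expr_rank_stat == "max") {
    apply(fmat, 1L, max)
  } else {
    rowMeans(fmat)
  }

  expr_ord <- order(-expr_stat, dels$feature_id)
  sig_ord <- order(dels$fdr, dels$p_value, -abs(dels$log2fc),
                   dels$feature_id)
  expr_rank <- sig_rank <- integer(n)
  expr_rank[expr_ord] <- seq_len(n)
  sig_rank[sig_ord] <- seq_len(n)

  ids <- dels$feature_id
  top_expr <- ids[expr_rank <= k_big]
  top_sig <- ids[sig_rank <= k_big]
  stage1 <- intersect(top_expr, top_sig)

  in1 <- ids %in% stage1
  stage2 <- character(0)
  if (length(stage1) > 0L) {
    ids1 <- ids[in1]
    es1 <- expr_stat[in1]
    d1 <- dels[in1, , drop = FALSE]
    e_ord1 <- order(-es1, ids1)
    s_ord1 <- order(d1$fdr, d1$p_value, -abs(d1$log2fc), ids1)
    kk <- min(k_small, length(ids1))
    stage2 <- union(ids1[e_ord1][seq_len(kk)], ids1[s_ord1][seq_len(kk)])
  }

  list(stage1 = sort(stage1), stage2 = sort(stage2),
       ranks = data.frame(feature_id = ids, expr_stat = unname(expr_stat),
                          expr_rank = expr_rank, sig_rank = sig_rank,
                          stringsAsFactors = FALSE))
}

.compartments <- c("nucleus", "cytoplasm", "ribosome", "cytosol",
                   "exosome")

#' Predict the compartment of each lncRNA
#'
#' Argmax over the five compartment scores. Exact ties are broken by a
#' fixed compartment priority (nucleus > cytoplasm > ribosome > cytosol >
#' exosome) and flagged. Scores need not sum to one; only the argmax is
#' used downstream.
#'
#' @param localization data.frame in the `localization` schema.
#' @return the input with `predicted` and `tie` columns added.
#' @export
predict_compartment <- function(localization) {
  stopifnot(all(c("lncrna_id", .compartments) %in% names(localization)))
  sc <- as.matrix(localization[, .compartments, drop = FALSE])
  best <- apply(sc, 1L, function(x) .compartments[which.max(x)])
  tie <- apply(sc, 1L, function(x) sum(x == max(x)) > 1L)
  localization$predicted <- unname(best)
  localization$tie <- unname(tie)
  localization
}

#' Gate candidate lncRNAs on cytoplasmic localization
#'
#' Keeps the candidates whose predicted compartment is the cytoplasm
#' (plus cytosol when `config$merge_cytosol` is set). Candidates with no
#' localization record are excluded and tallied under `missing`.
#'
#' @param candidates character vector of lncRNA ids.
#' @param localization data.frame in the `localization` schema.
#' @param config a [pipeline_config()].
#' @return list with `cytoplasmic` (sorted ids), `tally` (named counts per
#'   compartment plus `missing`; sums to `length(candidates)`) and `calls`
#'   (per-candidate data.frame).
#' @export
gate_cytoplasmic <- function(candidates, localization,
                             config = pipeline_config()) {
  loc <- predict_compartment(localization)
  idx <- match(candidates, loc$lncrna_id)
  pred <- ifelse(is.na(idx), "missing", loc$predicted[idx])
  pass_set <- if (config$merge_cytosol) c("cytoplasm", "cytosol")
              else "cytoplasm"
  keep <- pred %in% pass_set
  tally <- vapply(c(.compartments, "missing"),
                  function(k) sum(pred == k), integer(1))
  list(cytoplasmic = sort(candidates[keep]),
       tally = tally,
       calls = data.frame(lncrna_id = candidates, predicted = pred,
                          tie = ifelse(is.na(idx), NA, loc$tie[idx]),
                          stringsAsFactors = FALSE))
}
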