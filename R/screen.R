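.lnc_class_codes <- c("i", "x", "u", "o", "e")
.class_map <- c(u = "intergenic", i = "intronic", x = "antisense",
                o = "sense", e = "sense")

fpkm_columns <- function(transcripts) {
  cols <- grep("^fpkm", names(transcripts), value = TRUE)
  if (length(cols) == 0L)
    stop("transcript table has no fpkm_* columns", call. = FALSE)
  cols
}

#' Screen assembled transcripts for lncRNA candidates
#'
#' Applies, in order, the basic and coding-potential filters used to call
#' lncRNAs from an assembled transcriptome: assembler class code in
#' \{i, x, u, o, e\}; length >= 200 nt; >= 2 exons; FPKM >= 0.1 (by default
#' the maximum across samples, see `config$fpkm_rule`); then the four
#' coding-potential ceilings CPC < 0.5, CNCI < 0, CPAT < 0.5, PFAM < 0.
#' A transcript missing any coding score is excluded with its own tally
#' entry. The rejection tally is mutually exclusive: each rejected
#' transcript is counted at the first rule it fails, in the order above.
#'
#' @param transcripts data.frame in the `transcript` schema (see
#'   [table_schemas]).
#' @param config a [pipeline_config()].
#' @return list with `retained` (data.frame subset) and `tally` (named
#'   integer: `class_code`, `length`, `exons`, `fpkm`, `missing_score`,
#'   `cpc`, `cnci`, `cpat`, `pfam`, `retained`); the tally sums to
#'   `nrow(transcripts)`.
#' @export
screen_lncrnas <- function(transcripts, config = pipeline_config()) {
  n <- nrow(transcripts)
  fcols <- fpkm_columns(transcripts)
  fpkm_mat <- as.matrix(transcripts[, fcols, drop = FALSE])
  fpkm_stat <- if (config$fpkm_rule == "max") {
    apply(fpkm_mat, 1L, max)
  } else {
    rowMeans(fpkm_mat)
  }
  missing_score <- is.na(transcripts$cpc_score) |
    is.na(transcripts$cnci_score) | is.na(transcripts$cpat_score) |
    is.na(transcripts$pfam_score)

  rules <- list(
    class_code = transcripts$class_code %in% .lnc_class_codes,
    length = transcripts$length_nt >= config$length_min,
    exons = transcripts$exon_count >= config$exon_min,
    fpkm = fpkm_stat >= config$fpkm_min,
    missing_score = !missing_score,
    cpc = !missing_score & transcripts$cpc_score < config$cpc_max,
    cnci = !missing_score & transcripts$cnci_score < config$cnci_max,
    cpat = !missing_score & transcripts$cpat_score < config$cpat_max,
    pfam = !missing_score & transcripts$pfam_score < config$pfam_max
  )

  reason <- rep(NA_character_, n)
  alive <- rep(TRUE, n)
  for (r in names(rules)) {
    fail <- alive & !rules[[r]]
    reason[fail] <- r
    alive <- alive & rules[[r]]
  }
  tally <- vapply(names(rules), function(r) sum(reason == r, na.rm = TRUE),
                  integer(1))
  tally <- c(tally, retained = sum(alive))
  list(retained = transcripts[alive, , drop = FALSE], tally = tally)
}

#' Classify retained lncRNAs by assembler class code
#'
#' Maps class codes to lncRNA classes: `u` -> intergenic, `i` -> intronic,
#' `x` -> antisense, `o`/`e` -> sense. The partition is exhaustive and
#' disjoint over the retained set.
#'
#' @param retained data.frame of transcripts that passed
#'   [screen_lncrnas()] (must carry `class_code`).
#' @return named integer vector with counts for `sense`, `antisense`,
#'   `intronic`, `intergenic` (sums to `nrow(retained)`).
#' @export
classify_lncrnas <- function(retained) {
  codes <- retained$class_code
  bad <- setdiff(unique(codes), names(.class_map))
  if (length(bad) > 0L)
    stop("unexpected class code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cls <- .class_map[codes]
  out <- c(sense = 0L, antisense = 0L, intronic = 0L, intergenic = 0L)
  tab <- table(cls)
  out[names(tab)] <- as.integer(tab)
  out
}

interval_gap <- function(s1, e1, s2, e2) {
  ## edge-to-edge gap between 1-based inclusive intervals; 0 on overlap
  pmax(0, pmax(s1, s2) - pmin(e1, e2))
}

#' Associate lncRNAs with mRNAs by position (cis) and co-expression (trans)
#'
#' A cis pair lies on the same chromosome with an edge-to-edge gap of at
#' most `config$cis_window` bp (default 100 kb; overlapping intervals are
#' gap 0; strand is ignored). A trans pair has Pearson |r| >
#' `config$trans_r` (default 0.9, strict) with a two-sided P <
#' `config$trans_p` (default 0.01) from the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n` shared samples. Pairs where a
#' constant expression vector makes r undefined are skipped for the trans
#' rule and flagged in the `trans_skipped` attribute.
#'
#' @param lncrnas,mrnas data.frames with `transcript_id`, `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @param lnc_expr,mrna_expr expression matrices (features x samples, row
#'   names = transcript ids, same sample columns); at least 3 shared
#'   samples are required for the trans rule.
#' @param config a [pipeline_config()].
#' @return data.frame of associated pairs: `lncrna_id`, `mrna_id`, `cis`,
#'   `trans` (logicals, at least one TRUE per row), `gap`, `r`, `p`.
#' @export
associate_mrnas <- function(lncrnas, mrnas, lnc_expr, mrna_expr,
                            config = pipeline_config()) {
  stopifnot(all(c("transcript_id", "chrom", "start", "end") %in%
                  names(lncrnas)),
            all(c("transcript_id", "chrom", "start", "end") %in%
                  names(mrnas)))
  lnc_expr <- as.matrix(lnc_expr)
  mrna_expr <- as.matrix(mrna_expr)
  if (ncol(lnc_expr) != ncol(mrna_expr))
    stop("expression matrices must share samples", call. = FALSE)
  ns <- ncol(lnc_expr)
  if (ns < 3L) stop("need >= 3 shared samples for the trans rule",
                    call. = FALSE)

  ## all-pairs Pearson r and two-sided P via the t transform
  sd0_l <- apply(lnc_expr, 1L, stats::sd) == 0
  sd0_m <- apply(mrna_expr, 1L, stats::sd) == 0
  r <- suppressWarnings(stats::cor(t(lnc_expr), t(mrna_expr)))
  r[sd0_l, ] <- NA
  r[, sd0_m] <- NA
  tt <- abs(r) * sqrt((ns - 2) / pmax(1 - r^2, 0))
  pv <- 2 * stats::pt(tt, df = ns - 2, lower.tail = FALSE)
  pv[is.nan(tt) | is.infinite(tt)] <- 0  # |r| = 1 exactly
  pv[is.na(r)] <- NA

  li <- match(lncrnas$transcript_id, rownames(lnc_expr))
  mi <- match(mrnas$transcript_id, rownames(mrna_expr))

  out <- vector("list", nrow(lncrnas))
  for (i in seq_len(nrow(lncrnas))) {
    same <- mrnas$chrom == lncrnas$chrom[i]
    gap <- rep(NA_real_, nrow(mrnas))
    gap[same] <- interval_gap(lncrnas$start[i], lncrnas$end[i],
                              mrnas$start[same], mrnas$end[same])
    cis <- same & !is.na(gap) & gap <= config$cis_window
    rv <- rep(NA_real_, nrow(mrnas))
    pvv <- rep(NA_real_, nrow(mrnas))
    if (!is.na(li[i])) {
      ok <- !is.na(mi)
      rv[ok] <- r[li[i], mi[ok]]
      pvv[ok] <- pv[li[i], mi[ok]]
    }
    trans <- !is.na(rv) & abs(rv) > config$trans_r & pvv < config$trans_p
    hit <- which(cis | trans)
    if (length(hit) > 0L)
      out[[i]] <- data.frame(
        lncrna_id = lncrnas$transcript_id[i],
        mrna_id = mrnas$transcript_id[hit],
        cis = cis[hit], trans = trans[hit],
        gap = gap[hit], r = rv[hit], p = pvv[hit],
        stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(lncrna_id = character(0), mrna_id = character(0),
                      cis = logical(0), trans = logical(0),
                      gap = numeric(0), r = numeric(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "trans_skipped") <- unique(c(rownames(lnc_expr)[sd0_l],
                                         rownames(mrna_expr)[sd0_m]))
  res
}
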