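## small in-code fixtures shared across test files

toy_de <- function(ids, log2fc, pvalue = 1e-4, fdr = 1e-3,
                   direction = NULL) {
  d <- data.frame(feature_id = ids, log2fc = log2fc, p_value = pvalue,
                  fdr = fdr, stringsAsFactors = FALSE)
  d$direction <- if (is.null(direction))
    ifelse(log2fc > 0, "up", "down") else direction
  d
}

toy_transcript <- function(transcript_id = "tx1", class_code = "u",
                           length_nt = 500, exon_count = 2, fpkm = 0.5,
                           cpc = -0.2, cnci = -1, cpat = 0.1, pfam = -5,
                           chrom = "chr1", start = 1000, end = NULL) {
  if (is.null(end)) end <- start + length_nt - 1
  data.frame(transcript_id = transcript_id, class_code = class_code,
             length_nt = length_nt, exon_count = exon_count,
             cpc_score = cpc, cnci_score = cnci, cpat_score = cpat,
             pfam_score = pfam, chrom = chrom, start = start, end = end,
             strand = "+", fpkm_T01 = fpkm, fpkm_T02 = fpkm,
             stringsAsFactors = FALSE)
}

toy_localization <- function(ids, cytoplasm = 0.6, nucleus = 0.2,
                             ribosome = 0.05, cytosol = 0.1,
                             exosome = 0.05) {
  data.frame(lncrna_id = ids, cytoplasm = cytoplasm, nucleus = nucleus,
             ribosome = ribosome, cytosol = cytosol, exosome = exosome,
             stringsAsFactors = FALSE)
}

toy_network <- function() {
  nodes <- data.frame(
    id = c("L1", "m1", "G1"),
    role = c("lncRNA", "miRNA", "mRNA"),
    direction = c("up", "down", "up"), stringsAsFactors = FALSE)
  edges <- data.frame(
    from = c("L1", "m1"), to = c("m1", "G1"),
    kind = c("lncRNA-miRNA", "miRNA-mRNA"),
    score = c(75, 160), stringsAsFactors = FALSE)
  network_export(nodes, edges)
}
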