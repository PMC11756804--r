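#!/usr/bin/env Rscript
## Stage 3 — differential expression, three layers.
##
## Median-of-ratios normalization and the NB Wald test per layer, then
## layer-specific direction calls: lncRNA fold change >= 2 with
## FDR < 0.01 and P < 0.05; miRNA |log2FC| > 1 with adjusted p < 0.05;
## mRNA |log2FC| > 2 with FDR < 0.01.

suppressPackageStartupMessages(library(cernet))

cfg <- read_config("results/data/config.json")
groups <- read_table("results/data/groups.tsv",
                     list(columns = c(sample = "character",
                                      group = "character")))
retained <- read_table("results/lncrna_retained.tsv",
                       list(columns = c(transcript_id = "character")))

for (layer in c("lncRNA", "miRNA", "mRNA")) {
  cnt <- read_table(sprintf("results/data/counts_%s.tsv", layer),
                    "counts")
  m <- as.matrix(cnt[, groups$sample])
  rownames(m) <- cnt$feature_id
  if (layer == "lncRNA")
    m <- m[rownames(m) %in% retained$transcript_id, , drop = FALSE]
  de <- nb_test(m, groups$group, ref = "control", layer = layer,
                config = cfg)
  write_table(de, sprintf("results/de_%s.tsv", layer))
  cat(sprintf("%-6s %5d features tested: %4d up, %4d down\n", layer,
              nrow(de), sum(de$direction == "up"),
              sum(de$direction == "down")))
}
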