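#!/usr/bin/env Rscript
## Stage 5 — target filtering and ceRNA network assembly.
##
## Applies the prediction thresholds (miRDB-style target score >= 60 and
## conservation > 0.5; TargetScan-style context++ <= -0.4; miRanda-style
## score > 140 with energy < -20 kcal/mol; both mRNA tools required) and
## the sponge direction rule (lncRNA vs miRNA opposite, miRNA vs mRNA
## opposite), then joins the two pair sets on the shared miRNA into
## lncRNA-miRNA-mRNA triplets and exports the network.

suppressPackageStartupMessages(library(cernet))

cfg <- read_config("results/data/config.json")
de_schema <- list(columns = c(feature_id = "character",
                              log2fc = "numeric", p_value = "numeric",
                              fdr = "numeric", direction = "character"),
                  id = "feature_id")
lnc_de <- read_table("results/de_lncRNA.tsv", de_schema)
mir_de <- read_table("results/de_miRNA.tsv", de_schema)
mrna_de <- read_table("results/de_mRNA.tsv", de_schema)
core <- readLines("results/core_lncrnas.txt")

lm <- lnc_mir_pairs(core, read_table("results/data/mirdb.tsv", "mirdb"),
                    mir_de, lnc_de, cfg)
cat(sprintf("lncRNA-miRNA: %d pairs kept (%d lncRNAs, %d miRNAs)\n",
            nrow(lm$pairs), length(unique(lm$pairs$lncrna_id)),
            length(unique(lm$pairs$mirna_id))))
if (length(lm$lnc_without_mirna) > 0)
  cat("  core lncRNAs left without a sponged miRNA:",
      paste(lm$lnc_without_mirna, collapse = ", "), "\n")
print(lm$tally)

mm <- mir_mrna_pairs(unique(lm$pairs$mirna_id),
                     read_table("results/data/targetscan.tsv",
                                "targetscan"),
                     read_table("results/data/miranda.tsv", "miranda"),
                     mrna_de, mir_de, cfg)
cat(sprintf("miRNA-mRNA: %d pairs kept (%d miRNAs, %d mRNAs)\n",
            nrow(mm$pairs), length(unique(mm$pairs$mirna_id)),
            length(unique(mm$pairs$mrna_id))))
print(mm$tally)

cn <- assemble_cerna(lm$pairs, mm$pairs)
cat(sprintf("ceRNA network: %d triplets over %d lncRNAs, %d miRNAs, %d mRNAs\n",
            nrow(cn$triplets), cn$composition[["lncRNA"]],
            cn$composition[["miRNA"]], cn$composition[["mRNA"]]))

write_table(cn$triplets, "results/cerna_triplets.tsv")
export_network(cn$network, "results/cerna_network.sif", "sif")
export_network(cn$network, "results/cerna_network.graphml", "graphml")
cat("network written as SIF and GraphML under results/\n")
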