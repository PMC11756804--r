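#!/usr/bin/env Rscript
## Stage 1 — generate the study inputs.
##
## Emulates a two-group (test vs control, n = 5 each) whole-transcriptome
## study at count level: NB counts for lncRNA / miRNA / mRNA layers with
## planted differential expression and planted ceRNA triplets, plus the
## side tables every later stage consumes (transcript annotation with
## coding-potential scores, prediction tables, localization scores, PPI
## edges, gene sets). Everything is written as plain text under
## results/data/ together with the ground truth and a config snapshot.

suppressPackageStartupMessages(library(cernet))

cfg <- pipeline_config(seed = 1)
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

sim <- simulate_study(cfg, seed = cfg$seed)
write_study(sim, "results/data")
write_config(cfg, "results/data/config.json")

tr <- sim$truth
cat(sprintf("simulated %d lncRNA / %d miRNA / %d mRNA features, %d samples\n",
            nrow(sim$counts$lncRNA), nrow(sim$counts$miRNA),
            nrow(sim$counts$mRNA), length(sim$samples)))
cat(sprintf("planted DE: %d lncRNAs, %d miRNAs, %d mRNAs\n",
            nrow(tr$de$lncRNA), nrow(tr$de$miRNA), nrow(tr$de$mRNA)))
cat(sprintf("planted ceRNA triplets: %d (%d lncRNAs, %d miRNAs, %d mRNAs)\n",
            nrow(tr$triplets), length(unique(tr$triplets$lncrna_id)),
            length(unique(tr$triplets$mirna_id)),
            length(unique(tr$triplets$mrna_id))))
cat(sprintf("decoy prediction rows: %d; decoy transcripts: %d\n",
            if (is.null(tr$decoys)) 0L else nrow(tr$decoys),
            nrow(tr$transcript_decoys)))
cat("inputs written to results/data/\n")
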