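#!/usr/bin/env Rscript
## Stage 2 — lncRNA screening and classification.
##
## Applies the basic filters (assembler class code in {i,x,u,o,e},
## length >= 200 nt, >= 2 exons, FPKM >= 0.1) and the four
## coding-potential ceilings (CPC < 0.5, CNCI < 0, CPAT < 0.5, PFAM < 0)
## to the transcript annotation table, then tallies the retained lncRNAs
## into sense / antisense / intronic / intergenic classes.

suppressPackageStartupMessages(library(cernet))

cfg <- read_config("results/data/config.json")
tx <- read_table("results/data/transcripts.tsv", "transcript")

scr <- screen_lncrnas(tx, cfg)
cls <- classify_lncrnas(scr$retained)

dir.create("results", showWarnings = FALSE)
write_table(scr$retained["transcript_id"], "results/lncrna_retained.tsv")
jsonlite::write_json(as.list(scr$tally), "results/screen_tally.json",
                     auto_unbox = TRUE)

cat(sprintf("screened %d transcripts: %d retained as lncRNA candidates\n",
            nrow(tx), nrow(scr$retained)))
cat("rejections by first failing rule:\n")
print(scr$tally[names(scr$tally) != "retained"])
cat("classes of the retained set:\n")
for (k in names(cls))
  cat(sprintf("  %-10s %5d (%.1f%%)\n", k, cls[[k]],
              100 * cls[[k]] / sum(cls)))
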