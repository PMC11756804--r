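---
title: "Methods: staged inference of a direction-consistent ceRNA network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staged inference of a direction-consistent ceRNA network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

## The inference chain

`cernet` turns a two-group bulk RNA-seq design (test vs control, e.g. an
ischemia model vs sham surgery, n = 5 sequenced per group) into a
competing endogenous RNA (ceRNA) network — lncRNAs that sponge miRNAs and
thereby de-repress the miRNAs' mRNA targets. The chain is:

1. **lncRNA screening** (`screen_lncrnas`): assembled transcripts are
   kept when their assembler class code is one of `i, x, u, o, e`, they
   are at least 200 nt long with at least 2 exons, their FPKM reaches
   0.1, and all four coding-potential scores point non-coding
   (CPC < 0.5, CNCI < 0, CPAT < 0.5, PFAM < 0). `classify_lncrnas` maps
   class codes to sense (`o`, `e`), antisense (`x`), intronic (`i`) and
   intergenic (`u`) classes.
2. **Differential expression** (`nb_test`): a negative-binomial Wald
   test per layer (details below), Benjamini–Hochberg correction, and
   layer-specific direction calls.
3. **Prioritization** (`select_core_dels`): intersection of the top-200
   differentially expressed lncRNAs by expression with the top-200 by
   significance, then the union of the top-20 of each rank within that
   intersection.
4. **Localization gating** (`gate_cytoplasmic`): sponging is a
   cytoplasmic mechanism, so only candidates whose five-compartment
   localization argmax is the cytoplasm continue.
5. **Target filtering** (`lnc_mir_pairs`, `mir_mrna_pairs`): prediction
   score thresholds plus the sponge direction rule — a lncRNA and its
   sponged miRNA must change in opposite directions, and likewise the
   miRNA and its mRNA target (so lncRNA and mRNA co-vary).
6. **Assembly** (`assemble_cerna`): natural join of the two pair sets on
   the shared miRNA into lncRNA–miRNA–mRNA triplets; the direction
   invariant is asserted, never assumed.
7. **Hubs and enrichment** (`hub_genes`, `enrich`): centrality ranking
   in the confidence-filtered PPI subgraph of the network mRNAs, the
   hub-induced core subnetwork (`core_subnetwork`), and hypergeometric
   over-representation of the differentially expressed mRNAs.

## The differential-expression model

Counts for feature $i$ in sample $j$ are modelled as negative binomial
with mean $s_j \mu_{ig(j)}$ and variance $\mu + \alpha_i \mu^2$, where
$s_j$ is a sample size factor and $g(j)$ the sample's group.

**Normalization** is median-of-ratios: $s_j = \mathrm{median}_i \,
k_{ij} / (\prod_j k_{ij})^{1/n}$ over features with all-positive counts.
When no such feature exists the default is an explicit error; a
`poscounts`-style fallback (geometric mean over positive counts only) is
available via `pipeline_config(sf_fallback = "poscounts")`.

**Dispersion** $\alpha_i$ is estimated by method of moments on
normalized counts pooled within groups, clipped to $[10^{-8}, 20]$, and
shrunk toward a mean–dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$
fitted by least squares through the median raw dispersion of ~20
mean-quantile bins (a deliberately robust, assumption-light fit). The
shrinkage weight is degrees-of-freedom based:
$\alpha = (d_{res}\,\hat\alpha_i + d_{prior}\,\alpha(\mu_i)) /
(d_{res} + d_{prior})$ with $d_{res} = n - 2$ and $d_{prior} = 10$.

**Testing**: group means are estimated as $\hat\mu_g = \sum_{j \in g}
k_{ij} / \sum_{j \in g} s_j$, the Wald statistic is
$\log(\hat\mu_{test}/\hat\mu_{ctrl})$ over its standard error from the
NB Fisher information, and the reference distribution is a
t with $d_{res} + d_{prior}$ degrees of freedom — the heavier tail
compensates for dispersion estimation noise at n = 5 per group. The test
suite verifies by simulation that the resulting type-I error at the 0.05
level stays inside the two-sided binomial 99% interval for 2000 null
features across dispersions 0.05–0.2, and that power at the reference
point (|log2FC| = 2, dispersion 0.1, n = 5/group) recovers at least 90%
of planted features at FDR < 0.01.

This is an intentionally documented re-design, not a bit-for-bit
reproduction of any historical DE package: the early NB implementations
this field used are versioned and superseded, so the package states its
own estimator and verifies its calibration instead.

**Numerical policies.** The reported `log2fc` adds a pseudo-count of 0.5
to each group mean for display only; the test statistic never uses it.
The single exception is degenerate: when one group's mean is exactly
zero the MLE diverges, so the statistic falls back to the value obtained
as if half a count had been observed there (flagged `zero_group`).
Features with all-zero counts are kept with p = fdr = 1, `log2fc` 0 and
flag `all_zero`.

## Thresholds and boundary semantics

All cutoffs live in `pipeline_config()` and are recorded in the run
manifest. Boundary semantics follow the conventional wording of each
source literally:

| gate | rule | boundary |
|---|---|---|
| lncRNA DE | FC >= 2, FDR < 0.01, P < 0.05 | `|log2FC|` >= 1 inclusive |
| miRNA DE | `|log2FC|` > 1, adj. p < 0.05 | strict |
| mRNA DE | `|log2FC|` > 2, FDR < 0.01 | strict |
| miRDB-style | target score >= 60, conservation > 0.5 | score inclusive, conservation strict |
| TargetScan-style | context++ <= -0.4 | inclusive |
| miRanda-style | score > 140, energy < -20 kcal/mol | both strict |
| PPI | combined confidence >= 0.4 | inclusive; 0–1000 scales auto-rescaled |
| cis association | edge-to-edge gap <= 100 kb | overlap counts as gap 0; strand ignored |
| trans association | `|r|` > 0.9, P < 0.01 | strict; exact t transform, n - 2 df |

Where a study's methods section and its results section disagree on the
DE thresholds (a common editorial slip — "FC >= 2" vs "|log2FC| > 2"),
the defaults follow the thresholds that match reported result counts
(the table above); both are reachable through the config.

## Ranks, ties and determinism

Every ranked list breaks ties by ascending lexicographic id, so no
output depends on input row order. Specifically:

* expression rank: descending mean FPKM over all samples (mean rather
  than max or test-group-only — the symmetric default; switchable via
  `expr_rank_stat`), then id;
* significance rank: ascending FDR, then ascending P, then descending
  `|log2FC|`, then id;
* hub rank: descending centrality (degree by default — the plugin
  convention this field uses does not pin the metric, so all three are
  computed and reported side by side), then id; isolated genes rank
  last with closeness defined as 0;
* localization argmax ties are broken by a fixed compartment priority
  (nucleus > cytoplasm > ribosome > cytosol > exosome) and flagged.
  Cytosol is kept distinct from cytoplasm (localization tools emit
  both); `merge_cytosol = TRUE` folds it into the gate.

Feature identifiers are opaque case-sensitive strings; the only
normalization is whitespace stripping. Silent identifier munging is the
dominant failure mode of network joins, so none is attempted.

The same-trend removal in the lncRNA–miRNA stage is applied per pair by
default: only the offending (lncRNA, miRNA) rows are dropped. The
stricter global reading — a miRNA with any same-trend core partner is
removed from all pairs — is available as
`direction_rule = "per_mirna"`; with hub-like sponges the two readings
can differ, and the per-pair form discards the least evidence.

## What the synthetic generator emulates

`simulate_counts` emits NB counts (`var = mu + alpha mu^2`, dispersion
shared across features) for the three layers with log-normal baseline
means (`meanlog = 5`, `sdlog = 1.5` — a bulk-RNA-seq-like five-decade
abundance range), library-size factors log-uniform in [0.7, 1.4], and
lengths log-uniform in [200, 10000] nt so FPKM derivation and the
length >= 200 screen are exercisable. A planted fraction of features is
differentially expressed with |log2FC| equal to the layer effect
(defaults: 2 for lncRNA and miRNA, 3 for mRNA, so planted mRNAs clear
their strict threshold of 2); planted ceRNA triplets are drawn from the
DE sets with direction-consistent signs. Triplet lncRNAs are emitted at
high abundance relative to their length and triplet miRNAs/mRNAs above
the quantification floor: the generator models exactly the situation
the prioritization stage is designed for — abundant, cytoplasmic,
strongly perturbed sponges — and that choice is what makes perfect
recovery a meaningful target rather than a coin flip.

Default problem sizes are a deliberate scale-down of a whole-cortex
study (2000 lncRNA / 600 miRNA / 2500 mRNA features, 5 samples per
group, DE fractions 0.08 / 0.2 / 0.15, 8 lncRNAs, 10 miRNAs and 25
mRNAs in planted triplets): large enough for stable rank behaviour and
BH calibration, small enough that the whole suite simulates dozens of
studies in seconds.

`simulate_side_tables` supports every planted pair with prediction rows
that clear all thresholds with margin, and plants decoys in three
labelled classes per table — `score_fail` (direction-consistent but
failing at least one score, including single-tool support on the mRNA
side), `direction_fail` (scores pass, partner same-trend), `non_de`
(scores pass, partner not differentially expressed) — so each filter's
rejection is attributable in isolation. The transcript annotation table
gets one decoy block per screening rule in the same spirit.

What the generator does **not** emulate: sequence-level realism (no
seed matching or folding energetics — prediction tables are generated
at score level), correlated features, batch effects, library-prep
biases, gene-length bias in DE, or per-feature dispersion trends beyond
the fitted mean relationship. Passing tests therefore demonstrate that
the inference chain is correct and calibrated under its stated model,
not that the model captures every property of real sequencing data.

## Known limitations

* Single two-level factor only; no covariates or batch correction.
* The NB test's calibration is verified at n = 5 per group over
  dispersions 0.05–0.2; far outside that range (e.g. dispersion > 0.4)
  the FDR < 0.01 gate at this sample size has little power, and the
  recall monotonicity tests document exactly that cliff.
* Localization and coding-potential scores are consumed, never
  recomputed; garbage scores in, garbage gating out.
* Over-representation uses the hypergeometric tail on user-supplied
  gene sets with no ontology-graph propagation; term databases are
  version-dependent, so enrichment outputs are comparable only within
  one gene-set file.
* No quantitative sponge-effect model (no binding-site stoichiometry):
  direction consistency is a necessary-condition filter, not proof of
  sponging.
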