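---
title: "Methods: differential expression, diseasome networks and shared-gene characterisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential expression, diseasome networks and shared-gene characterisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`degnet` implements a comparative transcriptomics workflow that links one
target disease to several risk-factor conditions through the genes they
dysregulate in common. This vignette describes the statistical model at each
stage, the tunable parameters and their defaults, the synthetic-data
generator used for validation, and the design choices made where the
methodology was genuinely open.

## Differential expression model

Each condition contributes a genes × samples intensity matrix with a binary
case/control design. Intensities are analysed on the log2 scale:
`log2(value + offset)` with a pseudo-count `offset` (default 1 intensity
unit) guarding against zeros. Per gene, the pooled-variance (Student)
two-sample t statistic compares cases to controls with
`df = n1 + n2 − 2` and a two-sided p-value; the pooled rather than Welch
form is used because typical microarray cohorts in this design are small
(3–20 samples per arm) and variance differences are dominated by sampling
noise. p-values are adjusted by the Benjamini–Hochberg step-up procedure —
the field's default FDR control for microarray DEG lists. A gene is called
differentially expressed iff

* adjusted p < `alpha` (default 0.05), **and**
* |log2 fold change| > `lfc` (default 1.0, i.e. two-fold),

both inequalities strict. log2FC is defined as the difference of log2 group
means (equivalently the log2 ratio of geometric means); the threshold is
therefore only meaningful on log2 data, which is why `call_degs()` refuses
z-scored input.

Two normalisations are provided and deliberately kept separate in the
pipeline order **raw → log2 → t-test/logFC**:

* `log2_transform()` precedes all testing;
* `zscore_rows()` — per-gene standardisation `z = (g − mean(g))/sd(g)` with
  the sample (n−1) SD — exists for cross-platform comparison and display
  only and is never applied before fold-change computation, because a
  |log2FC| > 1 cutoff has no meaning on unit-variance rows. A per-sample
  variant is available via `margin = "sample"` for workflows that
  standardise arrays rather than genes; it is not the default because the
  gene-wise form is the one that makes expression values comparable across
  platforms.

Zero-variance (constant) genes admit no t statistic; they are excluded
before testing and reported in the `degenerate` field of the result, never
silently dropped and never NaN-filled. Multiple probes mapping to one
symbol are collapsed before DEG calling, either by averaging
(`method = "mean"`) or by keeping the probe with the largest |t| for the
case/control contrast (`method = "max_abs_t"`, the default — it preserves
the most responsive measurement and is the convention that loses the least
signal when probe quality varies). Probe-to-symbol maps are explicit
two-column files; the package does not guess platform annotations. Gene
identity across all files is the uppercased symbol, matched exactly.

## Diseasome construction

For the target disease T and each risk factor F, the shared gene set is the
direction-consistent intersection (up∩up plus down∩down) of their DEG sets.
Direction consistency is the default because the up- and down-regulated
diseasomes are built as separate bipartite graphs; a symbol-only mode
(`direction_consistent = FALSE`) is provided for comparability with
analyses that intersect plain symbol lists. Each direction's diseasome is a
bipartite condition↔gene network: an edge (C, g) means g is a
direction-matched DEG of condition C shared with the target. The multiway
report tallies, per gene, the number of conditions in which it is a DEG
(either direction) and filters at a minimum multiplicity (≥ 2).

No significance is attached to overlap sizes at this stage; the
hypergeometric machinery below can be applied to a pair overlap when a
p-value is wanted.

## Over-representation and gene–disease association

Enrichment of a query set against a library term is the exact upper-tail
hypergeometric probability P(X ≥ k) for X ~ Hypergeometric(N, K, n) — the
one-sided Fisher-type over-representation test — with BH correction across
all terms of one library (never across libraries, mirroring per-category
reporting). The universe defaults to the library's gene union; the pipeline
narrows it to the intersection of the library universe with the genes
actually measured in the contributing datasets, since genes never measured
cannot enter a query and would inflate N. The choice is recorded in the run
manifest. Terms with zero query overlap participate in the BH denominator
(their p is 1) but are not reported.

Gene–disease association uses the same statistic: DEGs of each condition
against a curated disease gene list within the measured-gene universe,
BH-adjusted across the batch of conditions.

## Network analyses

The PPI subnetwork is the node-induced subgraph on the shared genes: both
endpoints must be query genes. First-neighbour expansion is available
behind `expand_neighbors` (default off), since interactome hairballs grow
quickly and the induced form answers the narrower question "how do the
shared genes talk to each other". STRING-style confidence weights are kept
on a 0–1 scale (combined scores above 1 are auto-detected and divided by
1000) and filtered at 0.4 by default — the usual medium-confidence
convention. Hubs are the top `k = 10` nodes by degree; ties are ordered
lexicographically, share a min-convention rank, and a tie spanning the
cutoff extends the list and sets a flag rather than truncating arbitrarily.

Transcription factors and miRNAs are ranked by bipartite degree restricted
to the DEG set — the number of distinct DEGs among a regulator's known
targets — with `top_n = 5` by default, matching the list sizes such studies
report. Alternative centralities are out of scope. Drug lookup restricts a
drug→target table to drugs hitting at least one query gene.

## Synthetic data and what validation shows

`simulate_condition_family()` generates the study conditions used
throughout the tests: per gene, a raw baseline whose log2 is
N(7, 1) (intensities of a few hundred units), i.i.d. Gaussian noise of SD
`noise_sd` (default 0.5) on the log2 scale, and planted DEGs shifting case
means by ±`effect_size` (default 2.0 log2 units). Pairwise DEG sharing is
realised with disjoint gene blocks, one per condition pair with a positive
design entry, so that pairwise shared counts equal the design exactly and
shared genes carry matching directions in both conditions — the structure
the direction-split diseasome assumes. A pairwise design matrix cannot
encode three-way overlaps; tests that need them construct DEG sets
directly. Defaults (2000 genes, 10 vs 10 samples) are desk-speed stand-ins
for cohort-scale data; the validation suite uses 300–1200 genes and the
acceptance script 1000 genes × 20 replicates, sizes at which every planted
property is comfortably identifiable.

The generator deliberately omits several features of real microarray data:
probe-level effects, batch and platform effects, correlated genes,
heavy-tailed and intensity-dependent noise, and missingness. Passing
recovery tests therefore demonstrates the correctness of the statistics and
the plumbing — sensitivity/FDR of the dual filter under the assumed noise
model, exactness of the intersections, rankings and hypergeometric tails,
determinism of the pipeline — not robustness to those real-data
pathologies. The companion generators plant one enriched term
(`simulate_gmt()`), guaranteed-degree hubs in a preferential-attachment PPI
(`simulate_ppi()`), a regulator with boosted DEG targeting
(`simulate_regulator_tables()`), and drug/disease tables seeded with
planted genes, each a pure function of its parameters and seed.

## Numerical and degenerate-input choices

* Sample SD (n−1) everywhere; z-scored rows are checked to mean 0 and SD 1
  within 1e-9, and z-scoring is idempotent at that tolerance.
* Strict inequalities at both DEG thresholds.
* Zero pooled variance: excluded and reported (equal-mean case), or ±Inf t
  with p = 0 when means differ but variance is zero.
* Hypergeometric tails are computed exactly (`phyper`), never by normal
  approximation; k = 0 returns exactly 1.
* All orderings are deterministic: degree/score descending then symbol
  ascending; result tables sort by adjusted p, then p, then term id.
* Undirected edges are stored canonically (lexicographically smaller
  endpoint first), deduplicated; self-loops are dropped with a count.
* Missing or non-numeric expression cells abort the read with the offending
  gene and sample named — rejection, not imputation.
* The pipeline funnels all randomness through explicit seeds and writes a
  manifest of parameters, counts and md5 hashes; identical inputs give
  byte-identical outputs.

## Interface

The package is driven from R: `run_pipeline()` executes the full analysis
from a declarative YAML config (as written by `simulate_workspace()`), and
every stage is also exposed as a documented function, so intermediate
artifacts written by one stage can be re-read and the pipeline restarted
from any point. Networks export to edge-list TSV (lossless round-trip), SIF
and GraphML for viewing in Cytoscape-class tools.

## Known limitations

Probe annotation is the user's responsibility (explicit map files); only
two-group unpaired designs are supported (no covariates, pairing or
empirical-Bayes moderation); enrichment reproduces the hypergeometric/BH
statistic, not any web service's library versions or combined scores; and
overlap designs are pairwise only.
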