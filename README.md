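# degnet

Transcriptome-wide linkage of a target disease to its risk-factor
conditions. `degnet` is written for the common systems-biology study design
in which a disease cohort (e.g. cardiomyopathy) and several risk-factor
cohorts (ageing, smoking, obesity, ...) each contribute a case/control
expression matrix, and the question is which genes the disease shares with
each risk factor, what those shared genes do, and which proteins, regulators
and drugs sit on top of them.

## What it computes

For each condition, genes are tested case vs control with the pooled
(Student) two-sample t-statistic on log2 intensities,

    t = (x̄₁ − x̄₂) / (sₚ · √(1/n₁ + 1/n₂)),   sₚ² = [(n₁−1)s₁² + (n₂−1)s₂²] / (n₁+n₂−2),

p-values are Benjamini–Hochberg adjusted, and a gene is a differentially
expressed gene (DEG) iff `p_adj < 0.05` and `|log2FC| > 1` (both strict),
where log2FC is the difference of log2 group means. Cross-platform
comparability is provided by per-gene z-scoring, `z = (g − mean(g)) / sd(g)`.

Downstream of DEG calling:

- **Diseasome networks** — direction-consistent intersection of the target's
  up/down DEG sets with each risk factor's, rendered as bipartite
  condition↔gene graphs (one per direction) plus pairwise and multiway
  shared-gene reports.
- **Over-representation** — exact upper-tail hypergeometric test of the
  shared genes against a GMT gene-set library, BH-corrected per library.
- **Hub proteins** — degree ranking inside the PPI subnetwork induced on the
  shared genes (STRING-style weighted edge lists, default confidence ≥ 0.4).
- **Regulators** — TFs and miRNAs ranked by how many distinct DEGs appear
  among their known targets (bipartite degree).
- **Drug-target lookup** and **gene–disease association** against curated
  lists, hypergeometric with BH across conditions.

A synthetic-data module generates whole condition families with planted
DEGs, a planted pairwise overlap design, scale-free PPI graphs, planted
enriched terms and boosted regulators, together with a ground-truth
manifest, so the entire pipeline is testable without any external download.

## Worked example

```r
library(degnet)

fam <- simulate_condition_family(
  n_conditions = 2, n_genes = 500, n_deg_per_condition = 25,
  overlap_design = matrix(c(0L, 10L, 10L, 0L), 2, 2),
  condition_ids = c("CMP", "AG"), seed = 11)

called <- lapply(fam$matrices,
                 function(m) call_degs(log2_transform(m, offset = 0)))
called$CMP
#> DEGSet 'CMP': 13 up, 12 down (alpha=0.05, |logFC|>1; 500 tested, 0 degenerate)

intersect_pair(called$CMP, called$AG)
#> DiseasomePair CMP ~ AG: 10 shared (5 up, 5 down)

build_diseasome(called$CMP, called["AG"], "up")
#> InteractionNetwork [diseasome_bipartite]: 7 nodes, 10 edges
#>   node classes: condition=2, gene=5
```

The 25 planted DEGs per condition are all recovered (13 up + 12 down for
CMP), and the 10 genes planted jointly in both conditions are exactly the
10 shared DEGs; the up-direction diseasome links the two condition nodes to
the 5 shared up-regulated genes. Enriching the CMP DEGs against a simulated
library whose planted term contains them puts that term first at
`p_adj ≈ 3e-41` while every random term stays above 0.6.

A full run — preprocessing, DEG calling, diseasome, enrichment, hubs,
regulators, drugs, disease association, with a hashed manifest — is one
call:

```r
cfg <- simulate_workspace("workspace", seed = 1)   # writes all inputs + config.yaml
manifest <- run_pipeline(cfg)                      # writes workspace/results/
```

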