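Package: degnet
Title: Differential-Expression Diseasome Networks and Shared-Gene Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links a target disease to risk-factor conditions through
    transcriptome-wide differential expression. For each condition it calls
    differentially expressed genes (DEGs) with a pooled two-sample t-test and
    Benjamini-Hochberg correction, intersects DEG sets into bipartite
    condition-gene (diseasome) networks split by direction of regulation,
    characterises the shared genes by hypergeometric gene-set
    over-representation, ranks hub proteins by degree in an induced
    protein-protein interaction subnetwork, ranks transcription factors and
    miRNAs by the number of DEG targets they regulate, looks up drug-target
    interactions, and tests gene-disease association against curated disease
    gene lists. A synthetic-data generator with ground-truth manifests makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
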