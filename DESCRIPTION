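Package: zfatlas
Title: C2H2 Zinc-Finger Family Scanning, Phylogeny, Expression and
    Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and classifies C2H2 zinc fingers in protein sequences
    with a deterministic spacing-grammar scan and a configurable motif
    taxonomy (Q-, M-, Z- and C-type fingers), builds neighbor-joining
    phylogenies of extracted finger domains with bootstrap support,
    computes tissue-specificity (coefficient of variation) and
    fold-change stress statistics from expression atlases, and performs
    candidate-gene association mapping (minor-allele-frequency filtering,
    multi-environment BLUPs, PCA population-structure covariates,
    per-marker general linear models) together with pairwise linkage
    disequilibrium r-squared and decay profiles. Ships seeded synthetic
    generators for every input - proteomes with implanted fingers,
    expression atlases, diploid inbred genotype panels with planted
    causal variants, and resequenced-locus alignments - each with a
    machine-readable ground-truth sidecar so the whole pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    lme4,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
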