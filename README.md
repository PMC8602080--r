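# zfatlas

Analysis of a plant C2H2 zinc-finger (ZF) transcription-factor family,
from protein sequences to marker-trait associations. The package was
built for maize-style family studies — hundreds of zinc-finger
proteins, an 11-organ expression atlas, a 500-line inbred association
panel, and resequenced candidate loci — but every stage is generic and
every stage can be exercised on seeded synthetic data with exact
ground truth.

## What it computes

**Finger detection and typing.** A C2H2 finger is
`C X(a) C X(b) H X(c) H` (two zinc-coordinating cysteines and
histidines; `X(n)` = n arbitrary residues). `scan_protein()` detects
fingers with a deterministic left-to-right spacing-grammar scan
(default spacers: a ∈ {1,2,3,4}, b ∈ {10..17,20}, c ∈ {1..8}, the
union over the taxonomy), including truncated fingers lacking the
terminal H. `classify_finger()` types each finger against a
configurable motif taxonomy — Q-type (conserved `QALGGH` recognition
motif), M1–M11 (its degenerate variants), Z1–Z13 (other conserved
finger-plus-flank motifs) and the motif-free C-type fallback — with
first-match-wins precedence.

**Phylogeny.** `anchor_align()` aligns extracted finger domains on
their C,C,H,H anchors; `nj_tree()` is a deterministic Saitou–Nei
neighbor joining (exact on additive matrices); `bootstrap_support()`
resamples alignment columns (default 1,000 replicates) and reports
bipartition support; `place_with_references()` maps query domains to
their nearest annotated reference.

**Expression.** `compute_cv()` is the tissue-specificity statistic
CV = 100·SD/mean; `hier_cluster()` cuts an average-linkage dendrogram
into k expression tiers (default 3); `stress_screen()` flags
responses by the strict 2-fold rule |log2(treated/control)| > 1.

**Association.** `fit_blup()` reduces multi-environment phenotypes to
per-line BLUPs (REML, environment fixed + line random);
`pca_covariates()` supplies population-structure covariates;
`glm_assoc()` runs per-marker F-tests of
`trait ~ covariates + dosage`, reporting incremental marker R² and
raw-threshold significance (p < 1e-4 panel mode, −log10 p ≥ 2
candidate-gene mode); `msa_to_variants()` turns a resequenced-locus
alignment into SNP and presence/absence Indel markers;
`pairwise_r2()`/`ld_decay()` give composite LD r² and its decay.

**Synthetic data.** `make_proteome()`, `make_expression()`,
`make_stress_data()`, `make_panel()` and `make_locus_alignment()`
generate every input the pipeline consumes, byte-identical under a
seed, with JSON-able truth sidecars.

## Worked example

```r
library(zfatlas)
seqs <- c(ZFP1 = "MTCAACGKGFRSYQALGGHMRSHEELLAG",
          ZFP2 = "MSEPRVCAACSRSFSSGKALGGHMRVHGATSLLQKPKTNMSNSHKCPYCFRVFPSGQALGGHKRCHWITSGS")
prof <- profile_proteome(seqs)
prof
#> zf_profile: 3 fingers in 2 of 2 sequences
#>
#>  Q M1
#>  2  1
prof$fingers[, c("protein_id","ordinal","c1","c2","h1","h2","a","b","cc","label")]
#>   protein_id ordinal c1 c2 h1 h2 a  b cc label
#> 1       ZFP1       1  3  6 19 23 2 12  3     Q
#> 2       ZFP2       1  7 10 23 27 2 12  3    M1
#> 3       ZFP2       2 46 49 62 66 2 12  3     Q
```

ZFP1 carries one Q-type finger: cysteines at residues 3 and 6 (a = 2),
12 spacer residues, then histidines at 19 and 23 (c = 3), with the
conserved `QALGGH` ending at the first histidine. ZFP2 is a two-finger
protein whose first finger carries `ALGGH` without the preceding Q —
the M1 degeneration — and whose second is again Q-type. Coordinates
are 1-based inclusive in R; `write_finger_table()` exports 0-based
half-open spans.

The `analysis/` directory holds the numbered end-to-end study:
`01_simulate_inputs.R` writes the synthetic bundle under
`results/data/`, and `02`–`06` scan fingers, build the bootstrap NJ
tree, run the expression analyses, the BLUP + PCA + GLM association
scan (panel and candidate-locus modes), and the LD profiles, each
printing what it found and writing its tables under `results/`.

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

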