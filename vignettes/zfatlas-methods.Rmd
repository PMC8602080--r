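---
title: "Methods: zinc-finger scanning, phylogeny, expression and association in zfatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zinc-finger scanning, phylogeny, expression and association in zfatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

zfatlas analyzes a plant C2H2 zinc-finger transcription-factor family
end to end: it finds and types the fingers in a proteome, relates the
finger domains by a bootstrap neighbor-joining phylogeny, summarizes
the family's expression atlas (tissue specificity, stress response),
and maps candidate-gene marker-trait associations with the
accompanying linkage-disequilibrium structure. Every stage can be run
on seeded synthetic data whose ground truth is recorded in machine-
readable sidecars, so the whole pipeline is testable offline. This
vignette explains the models, the tunable parameters, and the design
choices that were genuinely open.

## The finger grammar

A C2H2 zinc finger is a ~25-residue module coordinating a zinc ion via
two cysteines and two histidines, written `C X(a) C X(b) H X(c) H`,
where `X(n)` is `n` arbitrary residues. Detection is a deterministic
spacing-grammar scan, not an HMM: the default allowed spacer sets are
the union over every class in the shipped taxonomy table —
a ∈ {1,2,3,4}, b ∈ {10..17, 20}, c ∈ {1..8}. (The motif-free C class
alone spans a ∈ {1,2,4}, b ∈ {10..17}, c ∈ {1..7}; the union also
covers the Z classes that use a = 3, b = 20 or c = 8, which a C-only
grammar would never detect.) The grammar is an ordinary argument, so a
narrower or wider scan is one call away.

The scan is left-to-right and deterministic: the candidate with the
smallest first-cysteine position wins; ties are broken by smallest
`b`, then smallest `c`, then smallest `a` (shortest-first); scanning
resumes after the terminal histidine, so fingers never share
coordinating residues. With `allow_truncated = TRUE` a
`C X(a) C X(b) H` candidate with no grammar-compatible terminal
histidine is reported as a truncated finger (three taxonomy classes
are truncated) and its span is closed at the first histidine plus the
largest allowed `c` plus one. The scanner is verified against an
independent brute-force oracle that enumerates all index quadruples
and applies the same reduction.

Coordinates are 1-based inclusive inside the package (the R
convention); the finger-table writer emits 0-based half-open
`start`/`end` for interoperability.

## The motif taxonomy

Classification into Q, M1-M11, Z1-Z13 (with sub-variants) and the
fallback C class is driven entirely by a TSV rulebook shipped in
`inst/extdata/zf_taxonomy.tsv`: one row per class with its conserved
motif, its spacing constraint, and the row order as precedence. The
file is data, not hard-coded truth — several motif rows contain
typographically ambiguous wildcard runs, and users can edit them.

Three choices here were genuinely open:

* **Wildcard semantics.** A `_` in a motif can be read as "any one
  residue" or as "matched by omission" (the motif matches with that
  residue deleted). The default is any-one-residue, because omission
  is structurally inconsistent with the Z rows: deleting the
  wildcards shifts the motifs' internal histidines off the spacing
  their own row prescribes (e.g. the Z2A motif's two terminal
  histidines end up 2 residues apart where the row requires `c` = 3),
  so no sequence could both contain the collapsed motif and satisfy
  the row. Omission remains available via
  `zf_taxonomy(wildcard = "omission")`.
* **Precedence.** First match wins in row order — Q, then the M
  variants, then the Z classes, then C as the total fallback. One
  inversion of the printed order is required: `LG_H` (M10) is a
  subpattern of `Q_LG_H` (M11) with a superset spacing, so M11 must
  precede M10 to be reachable at all. The shipped file encodes that.
* **Search windows.** Q and M motifs are variations of the QALGGH
  recognition motif, whose histidine is the first coordinating one;
  they are searched only in the recognition window (from after the
  second cysteine through the first histidine). Z motifs extend into
  the flanking regions, so they are searched in the whole finger span
  widened by `flank_length` (default 6) residues on each side — wide
  enough to cover motifs that end at the second histidine.

Classification is total and deterministic: a finger that matches no
motif-and-spacing row is a C-type.

## Finger-domain phylogeny

Because every domain shares the C,C,H(,H) anatomy, multiple sequence
alignment reduces to laying the domains on a common frame: the four
coordinating residues occupy four shared anchor columns and each
spacer is right-padded with gaps to the per-segment maximum
(`anchor_align()`). Distances are p-distances (mismatches over
columns where neither row is gapped; a pair with no comparable
columns gets the maximum, 1). Fingers are short (~25 aa), so a simple
distance is stable; a substitution-model correction would add little
at these divergences.

Trees are built by the standard Saitou-Nei neighbor-joining
agglomeration, written for determinism: ties in the Q criterion are
broken by the lexicographically smallest pair of cluster
representatives, and negative branch-length estimates are clamped to
zero. On additive matrices the implementation recovers the generating
topology and branch lengths exactly (tested to 8 taxa, cross-checked
against an independent NJ implementation). Bootstrap support resamples
alignment columns with replacement (default 1,000 replicates, seeded),
rebuilds the tree per replicate, and reports for each internal
bipartition of the point tree the percentage of replicates containing
it, ignoring branch lengths. Query proteins are placed against an
annotated reference set by building the joint tree and reporting the
nearest reference leaf by path length.

## Expression statistics

Tissue specificity uses the coefficient of variation, CV = SD/mean
across tissues (reported in percent), with the sample (n-1) standard
deviation. Note the denominator: at equal absolute variability, a
highly expressed transcript has a lower CV, so tissue-specific rows in
a high-expression tier rank slightly lower than the same elevation in
a low tier. Rows with nonpositive mean are flagged and excluded from
ranking rather than given an undefined CV.

The atlas is clustered by agglomerative hierarchical clustering
(average linkage on Euclidean distances of the log-signal rows by
default, both configurable) cut at `k = 3` — the three expression
tiers. Cluster labels are renumbered by ascending mean expression so
label 1 is always the low tier; comparisons should be on the
partition, which is what the tests do.

The stress screen is a fold-change rule, not a replicate-aware model:
a row is responsive when `|log2(treated/control)| > 1` — strictly, so
an exactly 2-fold change is not responsive, following the printed
inequality. Log2-scale inputs are differenced directly; linear-scale
inputs are divided, with a pseudocount of 1.0 added to both sides of
any row containing a nonpositive value (flagged).

## Association mapping

Phenotypes measured in several environments are reduced to one value
per line by BLUP under the one-way random-effects model
`y_ij = mu + env_j + line_i + e_ij` (environment fixed, line random),
fitted by REML via `lme4::lmer`. In balanced designs the BLUP is the
line-mean deviation shrunk by `n/(n + lambda)` with
`lambda = sigma2_e / sigma2_line`; the tests verify this closed form
from ANOVA mean squares independently of lme4. A single-environment
trait cannot be shrunk and passes through centered, with a warning.

Population structure is captured by genotype PCA: per-marker mean
imputation of missing calls, centering (optionally allele-frequency
standardization), and the top components (default 3) as covariates.

The marker test is ordinary least squares: for each marker and trait,
`trait ~ covariates + dosage`, with the marker term tested by the
partial F-test against the covariate-only model. Reported `r_squared`
is the marker's incremental R² — the additional fraction of total
trait variance explained — because per-marker R² values in
candidate-gene tables are far below plausible full-model values;
full-model R² is one subtraction away. Missing genotypes are handled
by casewise deletion; markers collinear with the covariates are
flagged with `NA` p. Significance is the raw threshold of each mode —
`p < 1e-4` for panel scans and `-log10 p >= 2` for candidate-gene
scans — deliberately without multiple-testing adjustment, matching
the conventions of candidate-gene studies of this kind.

Resequenced amplicons enter as one aligned FASTA per locus:
polymorphic substitution columns become SNP markers and maximal runs
of adjacent gap-vs-residue columns with identical line membership
collapse into single biallelic presence/absence Indel markers,
positioned in reference coordinates. Inbred lines are coded 0/2;
ambiguous residues are missing. Columns mixing gaps and a
substitution are treated as indel columns only.

## Linkage disequilibrium

LD is composite r²: the squared Pearson correlation of dosage vectors
over lines observed at both markers. For fully homozygous inbred
lines this equals haplotype r² (verified against a haplotype-counting
oracle), and it requires no phasing. Under independence the expected
r² is approximately 1/n, which the tests use as a calibration. The
decay profile bins pairs by distance (`[0, w), [w, 2w), ...`) and
reports per-bin mean r² and counts.

## The synthetic generators

Each generator is deterministic under its seed (byte-identical
outputs) and emits a sidecar sufficient to score the corresponding
stage exactly.

* `make_proteome()` implants fingers with known label, spacing and
  coordinates. Backgrounds and spacers are drawn from the 18
  non-C/non-H residues and fingers are separated by linkers of at
  least 18 residues, so no accidental grammar match can exist — the
  "reject accidental matches" policy is satisfied by construction.
  Each implant is additionally verified to be recovered exactly by
  the scanner and classifier before acceptance (resampling the random
  fill on collision, e.g. when a wildcard realization creates a
  higher-precedence motif); a label whose row cannot be realized is
  rejected with a diagnostic. Default label weights follow the
  taxonomy's reference composition; per-protein finger counts default
  to a distribution over 1/2/3/4/5/9 fingers (the A/B/D/E/F/G size
  classes).
* `make_expression()` draws 169 transcripts over 11 organs in three
  clusters at mean log2 signals 7/10/13 (proportions 92/39/38), with
  Gaussian noise (default SD 0.5) and a 10% fraction of rows given
  one +4 log2 tissue elevation.
* `make_stress_data()` plants per-condition responder counts
  (default 15/10/8) with true |log2 FC| in [1.5, 4] and keeps all
  other rows strictly inside the 2-fold band, so the screen's
  recovery is exact by design — it emulates the thresholding, not
  measurement noise around the threshold.
* `make_panel()` builds inbred haplotypes by a block-copying Markov
  walk over a founder pool (switch probability
  `1 - exp(-rate * distance)`), which yields monotone LD decay
  without a coalescent; defaults are 513 lines and a per-bp switch
  rate of 2e-4. Subpopulations draw founder frequencies from a
  Balding-Nichols-style beta. Phenotypes are environment shifts plus
  planted marker effects plus Gaussian noise scaled to the target
  single-observation heritability (default 0.5).
* `make_locus_alignment()` defaults to 109 lines and a 4,516-bp
  locus with 31 substitution sites and 11 deletion blocks, all at
  minor-allele frequency >= 0.05 and separated by at least 2 bp so
  no two events merge; indels are deletions relative to the
  reference, so reference coordinates equal column indices.

What the generators do **not** emulate — real amino-acid composition
around fingers (no background C/H), alignment error, microarray
normalization artifacts, coalescent LD structure, genotyping error —
bounds what passing tests show: they demonstrate correctness of the
algorithms under their stated models, not robustness to every
property of field data.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale: 200
random sequences (<= 500 aa) for scanner-oracle equivalence; ~1,000
implanted fingers spanning every taxonomy label for classification
ground truth; additive matrices to 8 taxa for NJ; 10,000 independent
null tests and 500 power replicates at n = 109 for GLM calibration;
1,000 replicate pairs at n = 500 for the LD independence law; and the
full 109 x 4,516 locus for variant extraction. These sizes give
stable Monte-Carlo estimates in seconds to a couple of minutes.

Worth knowing: a marker truly explaining 10% of trait variance at
n = 109 has F-test power almost exactly 0.80 at alpha = 0.01, so a
500-replicate power estimate naturally lands a point or two either
side of 80%. Ties in NJ are resolved lexicographically with a 1e-12
relative tolerance on the Q criterion; bootstrap supports on the root
bipartition are reported empty (trivial on an unrooted tree); and the
expression cluster relabeling by ascending mean makes the arbitrary
hclust labels deterministic.

## Known limitations

Detection is grammar-exact: fingers whose spacing falls outside every
taxonomy row are invisible, where an HMM would degrade gracefully.
The anchored alignment presumes the finger anatomy and is not a
general aligner. The stress screen has no replicate model and hence
no error control. The GLM is a fixed-effects model without kinship;
closely related panels will inflate its test statistics. Indel
extraction collapses gap runs by exact membership identity, so two
overlapping deletion alleles at one site become distinct markers
rather than one multiallelic site.
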