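#!/usr/bin/env Rscript
# Candidate-gene association mapping: MAF-filter the panel, compute
# multi-environment BLUPs, PCA structure covariates, and per-marker GLM
# tests; then extract SNP/Indel markers from the resequenced locus
# alignment and test them the same way (the candidate-gene mode,
# -log10 p >= 2).

suppressPackageStartupMessages(library(zfatlas))
out <- "results"
panel <- read_vcf_panel("results/data/panel.vcf")
phen <- utils::read.delim("results/data/phenotypes.tsv",
                          stringsAsFactors = FALSE)
truth <- jsonlite::read_json("results/data/panel_truth.json",
                             simplifyVector = TRUE)

panel <- filter_maf(panel, 0.05)
cat(sprintf("panel after MAF >= 0.05: %d markers x %d lines\n",
            nrow(panel$markers), length(panel$lines)))

blup <- fit_blup(phen)
cat(sprintf("BLUP variance components: %s\n",
            paste(sprintf("%s sigma2_line=%.2f sigma2_e=%.2f",
                          blup$varcomp$trait, blup$varcomp$var_line,
                          blup$varcomp$var_resid), collapse = "; ")))

pcs <- pca_covariates(panel, 3)
cat(sprintf("PCA covariates: 3 PCs explaining %.1f%% of genotype variance\n",
            100 * sum(attr(pcs, "variance_explained"))))

assoc <- glm_assoc(panel, blup$blups, covariates = pcs, alpha = 1e-4)
utils::write.table(assoc, file.path(out, "association.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
sig <- assoc[assoc$significant, ]
cat(sprintf("panel scan: %d significant marker-trait pairs (p < 1e-4) of %d tests\n",
            nrow(sig), nrow(assoc)))
planted <- truth$causal
for (tr in unique(planted$trait)) {
  a <- assoc[assoc$trait == tr, ]
  top <- a$marker_id[which.min(a$p_value)]
  cat(sprintf("  trait %s: top marker %s (planted index %s)\n", tr,
              top, paste(planted$marker[planted$trait == tr],
                         collapse = ",")))
}

# candidate-gene mode on the resequenced locus
loc <- read_alignment_fasta("results/data/locus.afa")
vpanel <- msa_to_variants(loc, "REF", chrom = "chr6")
vpanel <- filter_maf(vpanel, 0.05)
cat(sprintf("locus: %d polymorphic sites (%d SNP, %d Indel)\n",
            nrow(vpanel$markers),
            sum(vpanel$markers$type == "SNP"),
            sum(vpanel$markers$type == "Indel")))
# phenotype for the 109 locus lines: one causal site + noise
set.seed(31)
g <- vpanel$calls[5, ]
y <- 0.35 * as.numeric(g) + stats::rnorm(length(g))
lpcs <- pca_covariates(vpanel, 3)
lassoc <- glm_assoc(vpanel, data.frame(line = vpanel$lines, SDW = y),
                    covariates = lpcs, alpha = 1e-2)
lassoc$neg_log10_p <- -log10(lassoc$p_value)
utils::write.table(lassoc, file.path(out, "locus_association.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("locus scan: %d sites at -log10 p >= 2; strongest %s (p=%.2g, R2=%.3f)\n",
            sum(lassoc$significant, na.rm = TRUE),
            lassoc$marker_id[which.min(lassoc$p_value)],
            min(lassoc$p_value, na.rm = TRUE),
            lassoc$r_squared[which.min(lassoc$p_value)]))
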