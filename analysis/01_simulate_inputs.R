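#!/usr/bin/env Rscript
# Generate the synthetic input bundle every downstream analysis reads:
# a proteome with implanted fingers, an 11-tissue expression atlas, a
# treated/control stress screen, an inbred genotype panel with planted
# causal variants and multi-environment phenotypes, and a resequenced
# locus alignment. Each generator writes a ground-truth sidecar.

suppressPackageStartupMessages(library(zfatlas))
seed <- 20211105L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

prot <- make_proteome(n_proteins = 120, seed = seed, out_dir = out)
cat(sprintf("proteome: %d proteins, %d planted fingers (%d labels)\n",
            nrow(prot$records), nrow(prot$sidecar),
            length(unique(prot$sidecar$label))))

atlas <- make_expression(seed = seed, out_dir = out)
cat(sprintf("atlas: %d transcripts x %d tissues, %d tissue-specific\n",
            nrow(atlas$matrix), ncol(atlas$matrix),
            sum(atlas$sidecar$specific)))

stress <- make_stress_data(seed = seed)
write_matrix_tsv(stress$treated, file.path(out, "stress_treated.tsv"))
write_matrix_tsv(stress$control, file.path(out, "stress_control.tsv"))
cat(sprintf("stress screen: %d rows x %d conditions, %d planted responders\n",
            nrow(stress$treated), ncol(stress$treated),
            sum(stress$sidecar$responsive)))

panel <- make_panel(n_lines = 513, n_markers = 600,
                    causal = data.frame(marker = c(120L, 121L, 400L),
                                        trait = c("SDW", "SDW", "TDW"),
                                        effect = c(0.6, 0.3, 0.5)),
                    n_envs = 3, h2 = 0.5, seed = seed, out_dir = out)
cat(sprintf("panel: %d lines x %d markers, causal at %s\n",
            length(panel$panel$lines), nrow(panel$panel$markers),
            paste(panel$panel$markers$marker_id[
              unique(panel$sidecar$causal$marker)], collapse = ", ")))

locus <- make_locus_alignment(seed = seed, out_dir = out)
cat(sprintf("locus: %d lines x %d bp, %d SNP + %d Indel sites planted\n",
            nrow(locus$alignment), ncol(locus$alignment),
            sum(locus$sidecar$markers$type == "SNP"),
            sum(locus$sidecar$markers$type == "Indel")))
cat("inputs written to", out, "\n")
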