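#!/usr/bin/env Rscript
# Expression analyses: hierarchical clustering of the atlas into three
# expression tiers, tissue-specificity by coefficient of variation, the
# 2-fold stress screen, and a detectability audit.

suppressPackageStartupMessages(library(zfatlas))
out <- "results"
atlas <- read_matrix_tsv("results/data/atlas.tsv")
truth <- jsonlite::read_json("results/data/atlas_truth.json",
                             simplifyVector = TRUE)

cl <- hier_cluster(atlas, k = 3)
utils::write.table(cl$assignment, file.path(out, "clusters.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("clusters: sizes %s, mean log2 signal %s\n",
            paste(cl$sizes, collapse = "/"),
            paste(round(cl$cluster_means, 1), collapse = "/")))
cat(sprintf("membership agreement with planted clusters: %.1f%%\n",
            100 * mean(cl$assignment$cluster == truth$cluster)))

cv <- compute_cv(atlas)
utils::write.table(cv, file.path(out, "cv.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("CV range: %.1f-%.1f%%\n", min(cv$cv), max(cv$cv)))
n_spec <- sum(truth$specific)
top <- cv$id[order(cv$cv, decreasing = TRUE)][seq_len(n_spec)]
cat(sprintf("top-%d CV rows vs planted tissue-specific rows: %d/%d\n",
            n_spec, sum(top %in% truth$id[truth$specific]), n_spec))

treated <- read_matrix_tsv("results/data/stress_treated.tsv")
control <- read_matrix_tsv("results/data/stress_control.tsv")
screen <- stress_screen(treated, control, scale = "log2")
utils::write.table(screen, file.path(out, "stress.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
smry <- attr(screen, "summary")
cat("responsive genes per condition (|log2 FC| > 1):\n")
print(smry)

rep <- detectability_report(atlas, sprintf("t%04d", 1:200), floor = 0)
cat(sprintf("detectability vs a 200-gene reference list: %d detected, %d undetected\n",
            rep$summary["n_detected"], rep$summary["n_undetected"]))
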