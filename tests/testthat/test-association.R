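toy_panel <- function(calls, pos = NULL, chrom = "chr1") {
  m <- nrow(calls)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  markers <- data.frame(marker_id = sprintf("%s.S_%d", chrom, pos),
                        chrom = chrom, pos = pos, type = "SNP",
                        stringsAsFactors = FALSE)
  genotype_panel(markers, sprintf("L%02d", seq_len(ncol(calls))), calls)
}

test_that("MAF is computed over non-missing alleles and filters work", {
  calls <- rbind(c(rep(0L, 7), rep(1L, 3)),      # 3/20 = 0.15
                 rep(0L, 10),                    # monomorphic
                 c(rep(2L, 5), rep(0L, 4), NA))  # 10/18
  pan <- toy_panel(calls)
  st <- compute_maf(pan)
  expect_equal(st$maf, c(0.15, 0, min(10 / 18, 8 / 18)))
  expect_equal(st$call_rate, c(1, 1, 0.9))
  kept <- filter_maf(pan, 0.05)
  expect_equal(nrow(kept$markers), 2)
  # coding flip leaves maf unchanged
  flip <- 2L - calls[1, , drop = FALSE]
  expect_equal(compute_maf(toy_panel(flip))$maf, 0.15)
})

test_that("gene-interval extraction is inclusive and equals a scan oracle", {
  set.seed(9)
  pan <- toy_panel(matrix(0L, 50, 4), pos = sort(sample(1:5000, 50)))
  iv <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                   start = c(pan$markers$pos[5], 4800),
                   end = c(pan$markers$pos[9], 4900))
  res <- extract_gene_snps(pan, iv)
  expect_true(pan$markers$marker_id[5] %in% res$panel$markers$marker_id)
  # brute-force oracle
  want <- sapply(seq_len(nrow(iv)), function(i)
    sum(pan$markers$pos >= iv$start[i] & pan$markers$pos <= iv$end[i]))
  expect_equal(res$gene_counts$n_markers, want)
  # empty intersection
  res0 <- extract_gene_snps(pan, data.frame(gene_id = "g0",
                                            chrom = "chr9", start = 1,
                                            end = 10))
  expect_equal(nrow(res0$panel$markers), 0)
  expect_equal(res0$gene_counts$n_markers, 0L)
  expect_error(extract_gene_snps(pan, data.frame(gene_id = "bad",
                                                 chrom = "chr1",
                                                 start = 10, end = 5)),
               "malformed")
})

test_that("BLUPs match the balanced-design closed form", {
  set.seed(15)
  n_line <- 25; n_env <- 4
  d <- expand.grid(line = sprintf("L%02d", 1:n_line),
                   env = sprintf("E%d", 1:n_env),
                   stringsAsFactors = FALSE)
  u <- rnorm(n_line, 0, 1.5)
  d$y <- 10 + as.numeric(factor(d$env)) * 0.7 +
    u[match(d$line, unique(d$line))] + rnorm(nrow(d), 0, 1)
  fit <- fit_blup(d)
  oracle <- oracle_balanced_blup(d)
  expect_equal(fit$blups$y,
               as.numeric(oracle$blup[fit$blups$line]),
               tolerance = 1e-5)
  expect_equal(fit$varcomp$var_line, oracle$var_line, tolerance = 1e-4)
  expect_equal(fit$varcomp$var_resid, oracle$var_resid,
               tolerance = 1e-4)
  expect_lt(abs(mean(fit$blups$y)), 1e-6)
  # shrinkage: |BLUP| never exceeds |raw line-mean deviation|
  dev <- oracle_balanced_blup(d)
  raw <- tapply(d$y - ave(d$y, d$env), d$line, mean)
  raw <- raw - mean(raw)
  expect_true(all(abs(fit$blups$y) <=
                  abs(raw[fit$blups$line]) + 1e-8))
})

test_that("BLUPs shrink to ~0 without line variance and pass through with one env", {
  set.seed(16)
  n_line <- 40; n_env <- 3
  d <- expand.grid(line = sprintf("L%02d", 1:n_line),
                   env = sprintf("E%d", 1:n_env),
                   stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d))  # no true line effect
  fit <- fit_blup(d)
  raw <- tapply(d$y, d$line, mean)
  expect_lt(mean(abs(fit$blups$y)), mean(abs(raw - mean(raw))))

  d1 <- d[d$env == "E1", ]
  expect_warning(f1 <- fit_blup(d1), "single environment")
  mu <- tapply(d1$y, d1$line, mean)
  expect_equal(f1$blups$y, unname(mu[f1$blups$line] - mean(mu)))
})

test_that("genotype PCA separates planted subpopulations", {
  sim <- make_panel(n_lines = 120, n_markers = 300, n_subpops = 2,
                    fst = 0.25, seed = 18)
  pcs <- pca_covariates(sim$panel, 3)
  lab <- sim$sidecar$subpop$subpop
  # two-class silhouette on PC1
  x <- pcs[, 1]
  sil <- vapply(seq_along(x), function(i) {
    a <- mean(abs(x[i] - x[lab == lab[i]][-which(
      which(lab == lab[i]) == i)]))
    b <- mean(abs(x[i] - x[lab != lab[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.8)
  # scores orthogonal
  g <- crossprod(pcs)
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-8)
  expect_error(pca_covariates(sim$panel, 200), "smaller")
})

test_that("duplicate lines get identical PCA scores", {
  set.seed(19)
  calls <- matrix(sample(c(0L, 2L), 200, TRUE), 20, 10)
  calls[, 10] <- calls[, 1]
  pcs <- pca_covariates(toy_panel(calls), 2)
  expect_equal(unname(pcs[10, ]), unname(pcs[1, ]), tolerance = 1e-10)
})

test_that("GLM equals the closed-form simple-regression F-test", {
  # 5-line toy data, no covariates
  g <- c(0, 0, 2, 2, 2)
  y <- c(1.1, 0.8, 2.3, 2.0, 2.6)
  pan <- toy_panel(matrix(as.integer(g), 1, 5))
  res <- glm_assoc(pan, data.frame(line = pan$lines, y = y),
                   alpha = 0.05)
  fit <- stats::lm(y ~ g)
  an <- stats::anova(fit)
  expect_equal(res$p_value, an$`Pr(>F)`[1], tolerance = 1e-12)
  expect_equal(res$r_squared, summary(fit)$r.squared,
               tolerance = 1e-12)
  expect_equal(res$model, "GLM")
})

test_that("GLM r2 is the incremental marker R2 over covariates", {
  set.seed(23)
  n <- 80
  covar <- matrix(rnorm(2 * n), n, 2)
  g <- sample(c(0L, 2L), n, TRUE)
  y <- 0.5 * covar[, 1] + 0.3 * g + rnorm(n)
  pan <- toy_panel(matrix(g, 1, n))
  rownames(covar) <- pan$lines
  res <- glm_assoc(pan, data.frame(line = pan$lines, y = y),
                   covariates = covar, alpha = 1e-2)
  f0 <- stats::lm(y ~ covar)
  f1 <- stats::lm(y ~ covar + g)
  expect_equal(res$r_squared,
               summary(f1)$r.squared - summary(f0)$r.squared,
               tolerance = 1e-10)
  expect_equal(res$p_value, stats::anova(f0, f1)$`Pr(>F)`[2],
               tolerance = 1e-10)
  expect_equal(res$model, "GLM+PCA")
  # a marker that is an exact copy of the trait
  pan2 <- toy_panel(matrix(rep(c(0L, 2L), each = 10), 1, 20))
  y2 <- as.numeric(pan2$calls[1, ])
  r2 <- glm_assoc(pan2, data.frame(line = pan2$lines, y = y2))
  expect_gt(r2$r_squared, 0.999999)
  expect_lt(r2$p_value, 1e-20)
  # collinear marker flagged
  const <- toy_panel(matrix(2L, 1, 20))
  rc <- glm_assoc(const, data.frame(line = const$lines,
                                    y = rnorm(20)))
  expect_true(rc$flagged)
  expect_true(is.na(rc$p_value))
})

test_that("maf and marker r2 are invariant under allele-coding flips", {
  set.seed(24)
  n <- 60
  g <- sample(c(0L, 2L), n, TRUE)
  y <- 0.4 * g + rnorm(n)
  r1 <- glm_assoc(toy_panel(matrix(g, 1, n)),
                  data.frame(line = sprintf("L%02d", 1:n), y = y))
  r2 <- glm_assoc(toy_panel(matrix(2L - g, 1, n)),
                  data.frame(line = sprintf("L%02d", 1:n), y = y))
  expect_equal(r1$r_squared, r2$r_squared, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
})

test_that("variant extraction handles SNPs, indel runs and edge cases", {
  # one A/A/G/A column -> one SNP with minor count 1
  aln <- matrix("T", 4, 8, dimnames = list(c("REF", "l1", "l2", "l3"),
                                           NULL))
  aln[3, 4] <- "G"
  pan <- msa_to_variants(aln, "REF")
  expect_equal(pan$markers$type, "SNP")
  expect_equal(pan$markers$pos, 4)
  expect_equal(unname(pan$calls[1, ]), c(0L, 0L, 2L, 0L))
  expect_equal(compute_maf(pan)$maf, 0.25)

  # a 2-column gap run in two of four rows -> one Indel, maf 0.5
  aln2 <- matrix("A", 4, 10, dimnames = list(c("REF", "l1", "l2", "l3"),
                                             NULL))
  aln2[c(2, 3), 5:6] <- "-"
  pan2 <- msa_to_variants(aln2, "REF")
  expect_equal(nrow(pan2$markers), 1)
  expect_equal(pan2$markers$type, "Indel")
  expect_equal(pan2$markers$pos, 5)
  expect_equal(compute_maf(pan2)$maf, 0.5)

  # no polymorphism -> empty panel
  mono <- matrix("G", 3, 6, dimnames = list(c("REF", "x", "y"), NULL))
  expect_equal(nrow(msa_to_variants(mono, "REF")$markers), 0)

  # ambiguous residues become missing calls
  aln3 <- matrix("C", 4, 6, dimnames = list(c("REF", "l1", "l2", "l3"),
                                            NULL))
  aln3[2, 2] <- "T"; aln3[3, 2] <- "N"
  pan3 <- msa_to_variants(aln3, "REF")
  expect_true(is.na(pan3$calls[1, "l2"]))

  # random deletions-only alignments match the column-scan oracle
  set.seed(25)
  for (k in 1:5) {
    loc <- make_locus_alignment(n_lines = 30, locus_len = 300,
                                n_snps = 6, n_indels = 3, seed = k)
    pan <- msa_to_variants(loc$alignment, loc$reference_row)
    want <- oracle_variant_count(loc$alignment, loc$reference_row)
    expect_equal(sum(pan$markers$type == "SNP"), unname(want["snp"]))
    expect_equal(sum(pan$markers$type == "Indel"),
                 unname(want["indel"]))
  }
})
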