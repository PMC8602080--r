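test_that("generators are byte-identical under a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  make_proteome(8, seed = 41, out_dir = d1)
  make_proteome(8, seed = 41, out_dir = d2)
  expect_identical(readLines(file.path(d1, "proteome.fasta")),
                   readLines(file.path(d2, "proteome.fasta")))
  e1 <- make_expression(n_rows = 40, seed = 41)
  e2 <- make_expression(n_rows = 40, seed = 41)
  expect_identical(e1, e2)
  p1 <- make_panel(n_lines = 30, n_markers = 40, seed = 41)
  p2 <- make_panel(n_lines = 30, n_markers = 40, seed = 41)
  expect_identical(p1, p2)
  l1 <- make_locus_alignment(n_lines = 20, locus_len = 200, n_snps = 4,
                             n_indels = 2, seed = 41)
  l2 <- make_locus_alignment(n_lines = 20, locus_len = 200, n_snps = 4,
                             n_indels = 2, seed = 41)
  expect_identical(l1, l2)
  # generators restore the caller RNG state
  set.seed(99); before <- .Random.seed
  invisible(make_expression(n_rows = 10, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("proteome implants carry exact ground truth per label", {
  tax <- zf_taxonomy()
  p <- make_proteome(30, seed = 42, taxonomy = tax)
  prof <- profile_proteome(p$records, tax)
  got <- prof$fingers[order(prof$fingers$protein_id,
                            prof$fingers$ordinal), ]
  want <- p$sidecar[order(p$sidecar$protein_id, p$sidecar$ordinal), ]
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$c1, want$c1)
  expect_equal(got$c2, want$c2)
  expect_equal(got$h1, want$h1)
  expect_equal(got$h2, want$h2)
  expect_equal(got$label, want$label)
  # a pure-label spec: 10 proteins x 2 Q fingers
  q <- make_proteome(10, label_weights = c(Q = 1),
                     finger_count_probs = c(`2` = 1), seed = 43)
  expect_equal(nrow(q$sidecar), 20)
  expect_true(all(q$sidecar$label == "Q"))
})

test_that("unsatisfiable implant specs are rejected with a diagnostic", {
  tax <- zf_taxonomy()
  bad <- tax
  # motif longer than any allowed spacer plus flank
  bad$motif[bad$label == "Q"] <- paste0(strrep("Q", 40), "H")
  expect_error(zfatlas:::implant_finger("Q", bad, taxonomy_grammar(tax),
                                        tries = 10),
               "unsatisfiable")
})

test_that("expression generator emulates the atlas structure", {
  atlas <- make_expression(seed = 44)
  expect_equal(ncol(atlas$matrix), 11)
  expect_equal(nrow(atlas$matrix), 169)
  # noise-free atlas clusters recover membership exactly
  clean <- make_expression(n_rows = 60, noise_sd = 0, seed = 45)
  cl <- hier_cluster(clean$matrix, 3)
  expect_equal(cl$assignment$cluster, clean$sidecar$cluster)
  # planted tissue-specific rows are exactly the high-CV rows
  spec <- make_expression(n_rows = 200, specific_fraction = 0.1,
                          specific_shift = 4, noise_sd = 0.3, seed = 46)
  cv <- compute_cv(spec$matrix)
  n_spec <- sum(spec$sidecar$specific)
  top <- order(cv$cv, decreasing = TRUE)[seq_len(n_spec)]
  expect_setequal(cv$id[top], spec$sidecar$id[spec$sidecar$specific])
})

test_that("panel generator output passes validation and plants truth", {
  sim <- make_panel(n_lines = 60, n_markers = 80, n_subpops = 2,
                    causal = data.frame(marker = 5, trait = "t1",
                                        effect = 1),
                    missing_rate = 0.02, seed = 47)
  pan <- sim$panel
  expect_s3_class(pan, "zf_panel")
  expect_true(all(is.na(pan$calls) | pan$calls %in% c(0L, 2L)))
  expect_equal(nrow(sim$phenotypes), 60 * 3)
  expect_equal(sim$sidecar$causal$marker, 5)
  expect_error(make_panel(n_lines = 10, n_markers = 10, h2 = 1.5),
               "h2")
})

test_that("locus generator matches the variant extractor exactly", {
  loc <- make_locus_alignment(n_lines = 40, locus_len = 600,
                              n_snps = 8, n_indels = 4, seed = 48)
  pan <- msa_to_variants(loc$alignment, loc$reference_row)
  expect_equal(pan$markers$marker_id, loc$sidecar$markers$marker_id)
  expect_equal(pan$markers$type, loc$sidecar$markers$type)
  expect_equal(unname(pan$calls), unname(loc$sidecar$calls))
  # empty spec yields an empty panel
  none <- make_locus_alignment(n_lines = 10, locus_len = 100,
                               n_snps = 0, n_indels = 0, seed = 49)
  expect_equal(nrow(msa_to_variants(none$alignment,
                                    none$reference_row)$markers), 0)
})
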