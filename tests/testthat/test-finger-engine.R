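tax <- zf_taxonomy()
grammar <- taxonomy_grammar(tax)

test_that("scanner finds the canonical Q-type finger with exact anatomy", {
  s <- "MTCAACGKGFRSYQALGGHMRSHEE"
  f <- scan_protein(s, grammar, id = "p1")
  expect_equal(nrow(f), 1)
  # 1-based equivalents of the finger at C3..C6..H19..H23
  expect_equal(f$c1, 3L); expect_equal(f$c2, 6L)
  expect_equal(f$h1, 19L); expect_equal(f$h2, 23L)
  expect_equal(c(f$a, f$b, f$cc), c(2L, 12L, 3L))
  expect_equal(f$recognition_window, "GKGFRSYQALGGH")
  expect_equal(classify_finger(f[1, ], s, tax), "Q")
})

test_that("degenerate inputs behave as documented", {
  expect_equal(nrow(scan_protein("MAAAAKLL", grammar)), 0)
  expect_equal(nrow(scan_protein("", grammar)), 0)
  expect_error(scan_protein("MACU*", grammar, id = "px"),
               "position 4")
})

test_that("every emitted match satisfies the grammar invariants", {
  set.seed(101)
  for (i in 1:40) {
    s <- random_protein(sample(80:400, 1))
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    f <- scan_protein(s, grammar, allow_truncated = i %% 2 == 0)
    if (nrow(f) == 0) next
    expect_true(all(ch[f$c1] == "C" & ch[f$c2] == "C" & ch[f$h1] == "H"))
    expect_true(all(ch[f$h2[!f$truncated]] == "H"))
    expect_equal(f$a, f$c2 - f$c1 - 1L)
    expect_equal(f$b, f$h1 - f$c2 - 1L)
    expect_equal(f$cc[!f$truncated],
                 (f$h2 - f$h1 - 1L)[!f$truncated])
    expect_true(all(f$a %in% grammar$a_allowed))
    expect_true(all(f$b %in% grammar$b_allowed))
    expect_true(all(f$cc[!f$truncated] %in% grammar$c_allowed))
    # sorted, non-overlapping coordinating residues
    expect_true(all(diff(f$c1) > 0))
    last_h <- ifelse(f$truncated, f$h1, f$h2)
    expect_true(all(f$c1[-1] > last_h[-nrow(f)]))
  }
})

test_that("scanner equals the exhaustive-enumeration oracle", {
  set.seed(202)
  for (i in 1:60) {
    s <- random_protein(sample(50:500, 1))
    trunc <- i %% 2 == 0
    got <- scan_protein(s, grammar, allow_truncated = trunc)
    want <- oracle_scan(s, grammar, allow_truncated = trunc)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0)
      expect_equal(unname(as.matrix(got[, finger_cols])),
                   unname(as.matrix(want[, finger_cols])))
  }
})

test_that("classification is total, deterministic, and motif-driven", {
  # ALGGH without a preceding Q is the M1 degeneration, not Q-type
  s <- "MCAACKKKKKKKSALGGHAAAH"
  f <- scan_protein(s, grammar)
  expect_equal(nrow(f), 1)
  expect_equal(classify_finger(f[1, ], s, tax), "M1")
  # no conserved motif at all falls back to C
  s2 <- "MCAACKKKKKKKKKKKKHAAAH"
  f2 <- scan_protein(s2, grammar)
  expect_equal(classify_finger(f2[1, ], s2, tax), "C")
  # determinism
  set.seed(7)
  s3 <- random_protein(300)
  f3 <- scan_protein(s3, grammar, allow_truncated = TRUE)
  if (nrow(f3) > 0) {
    l1 <- zfatlas:::classify_fingers(f3, s3, tax)
    l2 <- zfatlas:::classify_fingers(f3, s3, tax)
    expect_identical(l1, l2)
    expect_true(all(l1 %in% tax$label))
  }
})

test_that("truncated taxonomy classes need allow_truncated", {
  set.seed(11)
  fng <- zfatlas:::implant_finger("Z4B", tax, grammar)
  s <- paste0(paste(zfatlas:::rand_fill(20), collapse = ""),
              paste(fng$chars, collapse = ""),
              paste(zfatlas:::rand_fill(20), collapse = ""))
  expect_equal(nrow(scan_protein(s, grammar, allow_truncated = FALSE)), 0)
  f <- scan_protein(s, grammar, allow_truncated = TRUE)
  expect_equal(nrow(f), 1)
  expect_true(f$truncated)
  expect_equal(classify_finger(f[1, ], s, tax), "Z4B")
})

test_that("proteome profiling conserves counts and assigns size classes", {
  p <- make_proteome(25, seed = 31, taxonomy = tax)
  prof <- profile_proteome(p$records, tax)
  expect_equal(sum(prof$summary$counts), prof$summary$total_fingers)
  expect_equal(prof$summary$total_fingers, nrow(p$sidecar))
  counts <- table(p$sidecar$protein_id)
  expect_equal(
    prof$proteins$size_class,
    zfatlas:::size_class_of(
      as.integer(counts[prof$proteins$protein_id])))
  # two explicit proteins with 1 and 2 fingers
  r2 <- p$records[match(names(sort(counts)[c(1, length(counts))]),
                        p$records$id), ]
  expect_error(profile_proteome(rbind(r2, r2)), "duplicate")
})

test_that("transcript deduplication follows policy and counts", {
  rec <- data.frame(
    id = c("t1", "t2", "t3"), gene_id = "g1",
    sequence = c(strrep("A", 100), strrep("A", 200), strrep("A", 150)),
    stringsAsFactors = FALSE)
  out <- dedup_transcripts(rec, "longest")
  expect_equal(out$id, "t2")

  # the family-scale bookkeeping: 203 singletons plus 44 genes
  # carrying 123 transcripts collapse to 247 proteins
  singles <- data.frame(id = sprintf("s%03d", 1:203),
                        gene_id = NA_character_, sequence = "MATT",
                        stringsAsFactors = FALSE)
  sizes <- rep(2L, 44); sizes[seq_len(123 - 88)] <- 3L
  stopifnot(sum(sizes) == 123)
  multi <- data.frame(
    id = sprintf("m%03d", 1:123),
    gene_id = rep(sprintf("g%02d", 1:44), times = sizes),
    sequence = "MATT", stringsAsFactors = FALSE)
  out <- dedup_transcripts(rbind(singles, multi), "longest")
  expect_equal(nrow(out), 247)

  # first-occurrence policy equals a one-pass oracle
  set.seed(5)
  rnd <- data.frame(id = sprintf("r%03d", 1:60),
                    gene_id = sample(sprintf("g%d", 1:20), 60,
                                     replace = TRUE),
                    sequence = replicate(60, random_protein(30)),
                    stringsAsFactors = FALSE)
  got <- dedup_transcripts(rnd, "first")
  want <- rnd[!duplicated(rnd$gene_id), ]
  expect_equal(got$id, want$id)
})

test_that("extracted finger domains re-scan to the same anatomy", {
  p <- make_proteome(15, seed = 77, taxonomy = tax)
  prof <- profile_proteome(p$records, tax)
  dom <- extract_finger_domains(prof, p$records)
  expect_equal(nrow(dom), prof$summary$total_fingers)
  expect_equal(dom$domain_id,
               sprintf("%s_Zf%d", dom$protein_id, dom$ordinal))
  for (i in seq_len(min(nrow(dom), 30))) {
    f <- scan_protein(dom$sequence[i], grammar, allow_truncated = TRUE)
    expect_equal(nrow(f), 1)
    expect_equal(c(f$a, f$b), c(dom$a[i], dom$b[i]))
    if (!dom$truncated[i]) expect_equal(f$cc, dom$cc[i])
  }
})

test_that("the proteome benchmark wrapper reports headline counts", {
  dirp <- tempfile()
  p <- make_proteome(12, seed = 13, out_dir = dirp)
  bm <- benchmark_proteome(file.path(dirp, "proteome.fasta"))
  expect_equal(unname(bm$counts["n_sequences"]), 12)
  expect_equal(unname(bm$counts["total_fingers"]), nrow(p$sidecar))
  expect_equal(unname(bm$counts["Q_fingers"] + bm$counts["M_fingers"] +
                      bm$counts["Z_fingers"] + bm$counts["C_fingers"]),
               unname(bm$counts["total_fingers"]))
})
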