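make_domains <- function(n, seed = 1) {
  p <- make_proteome(n, seed = seed)
  prof <- profile_proteome(p$records)
  extract_finger_domains(prof, p$records)
}

test_that("anchor alignment shares anchor columns and pads spacers", {
  dom <- data.frame(
    domain_id = c("d1", "d2", "d3"),
    sequence = c(paste0("C", "AA", "C", strrep("K", 12), "H", "RS", "H"),
                 paste0("C", "AA", "C", strrep("L", 12), "H", "RS", "H"),
                 paste0("C", "AA", "C", strrep("M", 11), "H", "RS", "H")),
    a = c(2L, 2L, 2L), b = c(12L, 12L, 11L), cc = c(2L, 2L, 2L),
    truncated = FALSE, stringsAsFactors = FALSE)
  aln <- anchor_align(dom)
  expect_equal(ncol(aln), 2 + 2 + 12 + 2 + 2)
  anchors <- attr(aln, "anchor_columns")
  expect_true(all(aln[, anchors[1:2]] == "C"))
  expect_true(all(aln[, anchors[3:4]] == "H"))
  # the b = 11 row is padded with exactly one gap before its H anchor
  expect_equal(sum(aln["d3", ] == "-"), 1)
  expect_equal(unname(aln["d3", anchors[3] - 1]), "-")
})

test_that("alignment length follows the per-segment maxima", {
  dom <- make_domains(10, seed = 3)
  aln <- anchor_align(dom)
  cs <- ifelse(dom$truncated,
               nchar(dom$sequence) - (dom$a + dom$b + 3L), dom$cc)
  max_c <- if (all(dom$truncated)) max(cs) else
    max(dom$cc[!dom$truncated])
  expect_equal(ncol(aln), 2 + max(dom$a) + max(dom$b) + max_c + 2)
})

test_that("p-distance equals a position-by-position counting oracle", {
  a <- matrix(c("A", "A", "A", "A",
                "A", "A", "A", "A"), 2, 4, byrow = TRUE,
              dimnames = list(c("x", "y"), NULL))
  expect_equal(p_distance(a)["x", "y"], 0)

  set.seed(12)
  aln <- anchor_align(make_domains(8, seed = 12))
  d <- p_distance(aln)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  for (k in 1:10) {
    ij <- sample(nrow(aln), 2)
    use <- aln[ij[1], ] != "-" & aln[ij[2], ] != "-"
    expect_equal(d[ij[1], ij[2]],
                 sum(aln[ij[1], use] != aln[ij[2], use]) / sum(use))
  }
  # 3 mismatches over 20 comparable columns
  b <- matrix("A", 2, 20, dimnames = list(c("p", "q"), NULL))
  b[2, 1:3] <- "G"
  expect_equal(p_distance(b)["p", "q"], 0.15)
})

test_that("three-taxon NJ solves the closed form exactly", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(len[c("A", "B", "C")]), c(1, 1, 3))
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers additive matrices exactly up to 8 taxa", {
  for (n in 4:8) {
    set.seed(n)
    true <- ape::rtree(n, rooted = FALSE,
                       br = function(k) runif(k, 0.1, 1))
    D <- ape::cophenetic.phylo(true)
    D <- D[order(rownames(D)), order(colnames(D))]
    est <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(true), est), 0,
                 ignore_attr = TRUE)
    # branch lengths via the path-length matrix
    expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)],
                 D, tolerance = 1e-8)
    # independent cross-check against ape's NJ topology
    expect_equal(ape::dist.topo(ape::nj(D), est), 0,
                 ignore_attr = TRUE)
  }
})

test_that("taxon input order does not change the unrooted topology", {
  set.seed(42)
  aln <- anchor_align(make_domains(9, seed = 9))
  d <- p_distance(aln)
  t1 <- nj_tree(d)
  perm <- sample(nrow(d))
  t2 <- nj_tree(d[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})

test_that("Newick write-read-write round trip is byte-identical", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  f1 <- tempfile(); f2 <- tempfile()
  write_newick(tr, f1)
  write_newick(read_newick(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("bootstrap supports are percentages, seeded, and signal-driven", {
  # two well-separated clades over many columns
  set.seed(8)
  n_col <- 60
  base1 <- sample(c("A", "G"), n_col, replace = TRUE)
  base2 <- sample(c("L", "V"), n_col, replace = TRUE)
  mut <- function(x, k) { i <- sample(length(x), k); x[i] <- "S"; x }
  aln <- rbind(a1 = mut(base1, 2), a2 = mut(base1, 2),
               a3 = mut(base1, 2), b1 = mut(base2, 2),
               b2 = mut(base2, 2), b3 = mut(base2, 2))
  tr <- bootstrap_support(aln, replicates = 200, seed = 5)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_true(any(sup > 95))  # the clade split is near-certain
  # determinism under the seed
  tr2 <- bootstrap_support(aln, replicates = 200, seed = 5)
  expect_identical(tr$node.label, tr2$node.label)
  # single replicate: supports only 0 or 100
  tr3 <- bootstrap_support(aln, replicates = 1, seed = 2)
  s3 <- suppressWarnings(as.numeric(tr3$node.label))
  expect_true(all(s3[!is.na(s3)] %in% c(0, 100)))
})

test_that("reference placement finds planted parents", {
  set.seed(21)
  refs <- make_domains(8, seed = 33)
  refs <- refs[!refs$truncated, ][1:6, ]
  refs$domain_id <- sprintf("REF%d", 1:6)
  # queries: copies of references with 2 substituted non-anchor residues
  mutate_domain <- function(row) {
    ch <- strsplit(row$sequence, "", fixed = TRUE)[[1]]
    interior <- setdiff(seq_along(ch),
                        c(1, row$a + 2, row$a + row$b + 3, length(ch)))
    i <- sample(interior, 2)
    ch[i] <- sample(setdiff(zfatlas:::FILL_ALPHABET, ch[i]), 2)
    row$sequence <- paste(ch, collapse = "")
    row
  }
  queries <- do.call(rbind, lapply(1:18, function(k) {
    q <- mutate_domain(refs[((k - 1) %% 6) + 1, ])
    q$domain_id <- sprintf("Q%02d", k)
    q$parent <- sprintf("REF%d", ((k - 1) %% 6) + 1)
    q
  }))
  res <- place_with_references(queries[, names(refs)], refs)
  hit <- res$placement$nearest_reference ==
    queries$parent[match(res$placement$query_id, queries$domain_id)]
  expect_gte(mean(hit), 0.95)
  # a query identical to a reference sits at distance ~0
  exact <- refs[1, ]; exact$domain_id <- "QX"
  res2 <- place_with_references(exact, refs)
  expect_equal(res2$placement$nearest_reference, "REF1")
  expect_lt(res2$placement$distance, 1e-8)
  expect_error(place_with_references(exact, refs[0, ]), "empty")
})
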