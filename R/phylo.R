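#' Anchor-align finger domains
#'
#' Finger domains share the C,C,H,H anatomy, so a gapless progressive
#' alignment is unnecessary: each domain is laid out on a common frame
#' with the four coordinating residues in four shared anchor columns and
#' each spacer right-padded with gaps to the per-segment maximum.
#' Truncated domains get a gap in the terminal-histidine column.
#'
#' @param domains A data frame from [extract_finger_domains()] (needs
#'   `domain_id`, `sequence`, `a`, `b`, `cc`, `truncated`).
#' @return A character matrix (rows = domains, columns = alignment
#'   positions) with attribute `anchor_columns`; alignment length is
#'   `2 + max(a) + max(b) + max(c) + 2`.
#' @export
anchor_align <- function(domains) {
  stopifnot(is.data.frame(domains), nrow(domains) >= 1,
            all(c("domain_id", "sequence", "a", "b", "cc", "truncated")
                %in% names(domains)))
  if (anyDuplicated(domains$domain_id))
    stop("duplicate domain ids")
  n <- nrow(domains)
  max_a <- max(domains$a)
  max_b <- max(domains$b)
  trail_len <- nchar(domains$sequence) -
    (domains$a + domains$b + 3L) - ifelse(domains$truncated, 0L, 1L)
  cs <- ifelse(domains$truncated, trail_len, domains$cc)
  max_c <- if (all(domains$truncated)) max(cs) else
    max(domains$cc[!domains$truncated])
  pad <- function(x, width) {
    out <- strsplit(x, "", fixed = TRUE)[[1]]
    c(out, rep("-", width - length(out)))[seq_len(width)]
  }
  rows <- matrix("-", n, 2L + max_a + max_b + max_c + 2L,
                 dimnames = list(domains$domain_id, NULL))
  for (i in seq_len(n)) {
    s <- domains$sequence[i]
    a <- domains$a[i]; b <- domains$b[i]
    if (substr(s, 1, 1) != "C" || substr(s, a + 2L, a + 2L) != "C" ||
        substr(s, a + b + 3L, a + b + 3L) != "H")
      stop("domain ", domains$domain_id[i], " lacks C,C,H anatomy")
    aseg <- substr(s, 2L, a + 1L)
    bseg <- substr(s, a + 3L, a + b + 2L)
    if (domains$truncated[i]) {
      cseg <- substr(s, a + b + 4L, a + b + 3L + min(cs[i], max_c))
      h2 <- "-"
    } else {
      cseg <- substr(s, a + b + 4L, a + b + 3L + domains$cc[i])
      h2 <- substr(s, a + b + domains$cc[i] + 4L,
                   a + b + domains$cc[i] + 4L)
      if (h2 != "H")
        stop("domain ", domains$domain_id[i], " lacks terminal H")
    }
    rows[i, ] <- c("C", pad(aseg, max_a), "C", pad(bseg, max_b), "H",
                   pad(cseg, max_c), h2)
  }
  structure(rows, anchor_columns = c(1L, max_a + 2L, max_a + max_b + 3L,
                                     max_a + max_b + max_c + 4L))
}

#' Pairwise p-distance of an alignment
#'
#' `d(i, j)` is the proportion of mismatching residues over columns where
#' neither row is gapped. A pair with no comparable columns gets the
#' configured maximum (1) with a diagnostic.
#'
#' @param alignment Character matrix (rows = sequences), e.g. from
#'   [anchor_align()].
#' @param max_distance Distance assigned to incomparable pairs.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance <- function(alignment, max_distance = 1) {
  stopifnot(is.matrix(alignment), nrow(alignment) >= 2)
  n <- nrow(alignment)
  ids <- rownames(alignment)
  gap <- alignment == "-"
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- !gap[i, ] & !gap[j, ]
      if (!any(use)) {
        message("no comparable columns for pair ", ids[i], "/", ids[j],
                "; distance set to ", max_distance)
        d[i, j] <- d[j, i] <- max_distance
      } else {
        d[i, j] <- d[j, i] <-
          sum(alignment[i, use] != alignment[j, use]) / sum(use)
      }
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration on a distance matrix. Ties in the
#' Q criterion are broken by the lexicographically smallest pair of
#' cluster representatives (each cluster is represented by its smallest
#' leaf label), so the result is deterministic and invariant to input
#' order; negative branch-length estimates are clamped to zero.
#'
#' @param d Symmetric distance matrix with at least 3 labelled taxa.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  ids <- rownames(d)
  stopifnot(!is.null(ids), !anyDuplicated(ids),
            isTRUE(all.equal(d, t(d))), all(diag(d) == 0),
            all(is.finite(d)))
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  nwk <- ids       # growing newick fragment per active cluster
  rep <- ids       # representative (smallest leaf) per active cluster
  D <- d
  while (length(nwk) > 3) {
    m <- length(nwk)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      pr <- sort(c(rep[ij[1]], rep[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    merged <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    nwk <- c(nwk[keep], merged)
    rep <- c(rep[keep], min(rep[c(i, j)]))
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(la), nwk[2],
                 fmt(lb), nwk[3], fmt(lc))
  ape::read.tree(text = txt)
}

#' Bootstrap support for an anchor-aligned tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' p-distance NJ tree for each replicate, and reports for every internal
#' bipartition of the point-estimate tree the percentage of replicate
#' trees containing it (branch lengths ignored). Supports are stored as
#' internal node labels.
#'
#' @param alignment Character matrix from [anchor_align()].
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the column resampling.
#' @return The point-estimate `phylo` tree with `node.label` set to
#'   support percentages (root label empty).
#' @export
bootstrap_support <- function(alignment, replicates = 1000L, seed = 1L) {
  stopifnot(replicates >= 1)
  point <- nj_tree(p_distance(alignment))
  reps <- with_seed(seed, {
    lapply(seq_len(replicates), function(b) {
      cols <- sample.int(ncol(alignment), replace = TRUE)
      nj_tree(p_distance(alignment[, cols, drop = FALSE]))
    })
  })
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / replicates, 1)
  support[1] <- NA  # root bipartition of the unrooted tree is trivial
  point$node.label <- ifelse(is.na(support), "", as.character(support))
  point
}

#' Place query domains against annotated references
#'
#' Builds a joint anchor-aligned NJ tree of query and reference finger
#' domains and reports, for each query, the nearest reference leaf by
#' path length on the tree.
#'
#' @param query_domains,reference_domains Data frames in the
#'   [extract_finger_domains()] layout; reference ids must not collide
#'   with query ids.
#' @return List: `tree` (joint `phylo`) and `placement` (data frame
#'   `query_id`, `nearest_reference`, `distance`).
#' @export
place_with_references <- function(query_domains, reference_domains) {
  stopifnot(is.data.frame(reference_domains))
  if (nrow(reference_domains) == 0)
    stop("reference set must not be empty")
  all_domains <- rbind(query_domains[, names(reference_domains)],
                       reference_domains)
  aln <- anchor_align(all_domains)
  tree <- nj_tree(p_distance(aln))
  pd <- ape::cophenetic.phylo(tree)
  qids <- query_domains$domain_id
  rids <- reference_domains$domain_id
  nearest <- vapply(qids, function(q) {
    rids[which.min(pd[q, rids])]
  }, character(1))
  placement <- data.frame(
    query_id = qids, nearest_reference = nearest,
    distance = pd[cbind(qids, nearest)],
    stringsAsFactors = FALSE, row.names = NULL)
  list(tree = tree, placement = placement)
}

#' Leaf metadata table for tree annotation
#'
#' Emits the per-leaf annotation used for external tree rendering: size
#' class of the parent protein, finger ordinal, and Q/C supertype.
#'
#' @param domains Data frame from [extract_finger_domains()].
#' @param profile The `zf_profile` the domains came from.
#' @param taxonomy The taxonomy used.
#' @return Data frame `domain_id`, `size_class`, `ordinal`, `type`.
#' @export
leaf_metadata <- function(domains, profile, taxonomy = zf_taxonomy()) {
  sc <- stats::setNames(profile$proteins$size_class,
                        profile$proteins$protein_id)
  cls <- stats::setNames(taxonomy$class, taxonomy$label)
  type <- ifelse(cls[domains$label] %in% c("Q", "M"), "Q", "C")
  data.frame(domain_id = domains$domain_id,
             size_class = unname(sc[domains$protein_id]),
             ordinal = domains$ordinal, type = unname(type),
             stringsAsFactors = FALSE)
}
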