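AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

check_protein_sequence <- function(sequence, id = "protein") {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  ok <- c(AA_ALPHABET, "X")
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% ok)
  if (length(bad) > 0)
    stop(sprintf("sequence '%s' has non-amino-acid character '%s' at position %d",
                 id, ch[bad[1]], bad[1]))
  sequence
}

empty_finger_table <- function() {
  data.frame(protein_id = character(), ordinal = integer(),
             c1 = integer(), c2 = integer(), h1 = integer(), h2 = integer(),
             a = integer(), b = integer(), cc = integer(),
             start = integer(), end = integer(), truncated = logical(),
             recognition_window = character(), stringsAsFactors = FALSE)
}

#' Scan a protein for C2H2 zinc fingers
#'
#' Detects fingers by the spacing grammar `C X(a) C X(b) H X(c) H`
#' left-to-right: the match at the smallest first-cysteine position wins,
#' ties broken by smallest `b`, then smallest `c`, then smallest `a`
#' (shortest-first), and scanning resumes after the terminal histidine so
#' fingers never share coordinating residues. With
#' `allow_truncated = TRUE`, a `C X(a) C X(b) H` candidate with no
#' grammar-compatible terminal histidine is emitted as a truncated finger
#' and scanning resumes after its single histidine.
#'
#' All coordinates are 1-based inclusive; `start`/`end` delimit the finger
#' span (`end` is the terminal histidine, or for truncated fingers the
#' first histidine plus the largest allowed `c` plus one, clipped to the
#' sequence). The recognition window runs from the residue after the
#' second cysteine through the first histidine inclusive.
#'
#' @param sequence Amino-acid string (20 standard letters plus `X`;
#'   upper-cased on ingestion). An empty sequence yields no matches.
#' @param grammar A [spacing_constraint()]; defaults to the union grammar
#'   of the shipped taxonomy.
#' @param allow_truncated Detect fingers lacking the terminal histidine.
#' @param id Protein identifier recorded in the output.
#' @return A data frame with one row per finger: coordinates (`c1`, `c2`,
#'   `h1`, `h2`), spacers (`a`, `b`, `cc`), `start`/`end`, `truncated`,
#'   `ordinal` and `recognition_window`. `h2` and `cc` are `NA` for
#'   truncated fingers.
#' @export
scan_protein <- function(sequence, grammar = taxonomy_grammar(),
                         allow_truncated = FALSE, id = "protein") {
  stopifnot(inherits(grammar, "zf_spacing"))
  sequence <- check_protein_sequence(sequence, id)
  n <- nchar(sequence)
  out <- empty_finger_table()
  if (n == 0) return(out)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  is_c <- ch == "C"
  is_h <- ch == "H"
  c_pos <- which(is_c)
  max_c <- max(grammar$c_allowed)
  rows <- list()
  cursor <- 1L
  for (c1 in c_pos) {
    if (c1 < cursor) next
    c2s <- c1 + grammar$a_allowed + 1L
    c2s <- c2s[c2s <= n & is_c[pmin(c2s, n)]]
    if (length(c2s) == 0) next
    # full candidates (a, b, cc) ordered by (b, cc, a)
    best <- NULL
    for (c2 in c2s) {
      h1s <- c2 + grammar$b_allowed + 1L
      h1s <- h1s[h1s <= n & is_h[pmin(h1s, n)]]
      for (h1 in h1s) {
        h2s <- h1 + grammar$c_allowed + 1L
        h2s <- h2s[h2s <= n & is_h[pmin(h2s, n)]]
        for (h2 in h2s) {
          cand <- c(b = h1 - c2 - 1L, cc = h2 - h1 - 1L, a = c2 - c1 - 1L,
                    c2 = c2, h1 = h1, h2 = h2)
          if (is.null(best) ||
              cand["b"] < best["b"] ||
              (cand["b"] == best["b"] && cand["cc"] < best["cc"]) ||
              (cand["b"] == best["b"] && cand["cc"] == best["cc"] &&
               cand["a"] < best["a"]))
            best <- cand
        }
      }
    }
    if (!is.null(best)) {
      c2 <- best[["c2"]]; h1 <- best[["h1"]]; h2 <- best[["h2"]]
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = id, ordinal = NA_integer_,
        c1 = c1, c2 = c2, h1 = h1, h2 = h2,
        a = best[["a"]], b = best[["b"]], cc = best[["cc"]],
        start = c1, end = h2, truncated = FALSE,
        recognition_window = substr(sequence, c2 + 1L, h1),
        stringsAsFactors = FALSE)
      cursor <- h2 + 1L
      next
    }
    if (allow_truncated) {
      tbest <- NULL
      for (c2 in c2s) {
        h1s <- c2 + grammar$b_allowed + 1L
        h1s <- h1s[h1s <= n & is_h[pmin(h1s, n)]]
        for (h1 in h1s) {
          cand <- c(b = h1 - c2 - 1L, a = c2 - c1 - 1L, c2 = c2, h1 = h1)
          if (is.null(tbest) ||
              cand["b"] < tbest["b"] ||
              (cand["b"] == tbest["b"] && cand["a"] < tbest["a"]))
            tbest <- cand
        }
      }
      if (!is.null(tbest)) {
        c2 <- tbest[["c2"]]; h1 <- tbest[["h1"]]
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = id, ordinal = NA_integer_,
          c1 = c1, c2 = c2, h1 = h1, h2 = NA_integer_,
          a = tbest[["a"]], b = tbest[["b"]], cc = NA_integer_,
          start = c1, end = min(n, h1 + max_c + 1L), truncated = TRUE,
          recognition_window = substr(sequence, c2 + 1L, h1),
          stringsAsFactors = FALSE)
        cursor <- h1 + 1L
      }
    }
  }
  if (length(rows) == 0) return(out)
  out <- do.call(rbind, rows)
  out$ordinal <- seq_len(nrow(out))
  out
}

# Spacing-compatibility of one detected finger with one taxonomy row.
spacing_ok <- function(finger, sp) {
  if (finger$truncated != !sp$h2_required) return(FALSE)
  if (!(finger$a %in% sp$a_allowed)) return(FALSE)
  if (!(finger$b %in% sp$b_allowed)) return(FALSE)
  if (!finger$truncated && !(finger$cc %in% sp$c_allowed)) return(FALSE)
  TRUE
}

#' Classify a detected finger into the taxonomy
#'
#' Tries each taxonomy class in precedence order (Q, then M1..M11, then
#' the Z classes, in listed order); a class matches when the finger's
#' spacers satisfy the class's spacing constraint and its motif is found
#' in the class's search window. Q/M motifs are sought in the recognition
#' window (after the second cysteine through the first histidine); Z
#' motifs, which extend into the flanking regions, are sought in the
#' finger span extended by the taxonomy's flank length on each side.
#' Fingers matching no class fall back to C, so classification is total
#' and deterministic.
#'
#' @param finger One row of a [scan_protein()] result (data frame or list).
#' @param sequence The protein sequence the finger was found in.
#' @param taxonomy A [zf_taxonomy()].
#' @return A single class label.
#' @export
classify_finger <- function(finger, sequence, taxonomy = zf_taxonomy()) {
  stopifnot(inherits(taxonomy, "zf_taxonomy"))
  sequence <- toupper(sequence)
  wildcard <- attr(taxonomy, "wildcard")
  flank <- attr(taxonomy, "flank_length")
  n <- nchar(sequence)
  recog <- substr(sequence, finger$c2 + 1L, finger$h1)
  flanked <- substr(sequence, max(1L, finger$start - flank),
                    min(n, finger$end + flank))
  fallback <- taxonomy$label[nrow(taxonomy)]
  for (i in seq_len(nrow(taxonomy) - 1L)) {
    if (!spacing_ok(finger, taxonomy$spacing_parsed[[i]])) next
    window <- if (taxonomy$class[i] == "Z") flanked else recog
    if (motif_matches(window, taxonomy$motif[i], wildcard))
      return(taxonomy$label[i])
  }
  fallback
}

classify_fingers <- function(fingers, sequence, taxonomy = zf_taxonomy()) {
  if (nrow(fingers) == 0) return(character(0))
  vapply(seq_len(nrow(fingers)), function(i)
    classify_finger(fingers[i, ], sequence, taxonomy), character(1))
}

size_class_of <- function(count) {
  map <- c(`1` = "A", `2` = "B", `3` = "D", `4` = "E", `5` = "F", `9` = "G")
  out <- unname(map[as.character(count)])
  out[is.na(out)] <- "other"
  out
}

as_protein_records <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "sequence") %in% names(x)))
    rec <- x
  } else if (is.character(x)) {
    stopifnot(!is.null(names(x)))
    rec <- data.frame(id = names(x), sequence = unname(x),
                      stringsAsFactors = FALSE)
  } else {
    stop("protein records must be a data frame or a named character vector")
  }
  if (!"gene_id" %in% names(rec)) rec$gene_id <- NA_character_
  if (!"transcript_index" %in% names(rec))
    rec$transcript_index <- NA_integer_
  if (anyDuplicated(rec$id))
    stop("duplicate protein ids: ",
         paste(unique(rec$id[duplicated(rec$id)]), collapse = ", "))
  rec
}

#' Scan and classify a whole proteome
#'
#' Runs [scan_protein()] and [classify_finger()] over a protein
#' collection and aggregates per-protein finger profiles (finger count
#' and size class: A/B/D/E/F/G for 1/2/3/4/5/9 fingers, `other`
#' otherwise) and a taxonomy summary whose per-label counts sum to the
#' total number of fingers.
#'
#' @param records Protein records: a named character vector of sequences
#'   or a data frame with columns `id`, `sequence` (optionally `gene_id`,
#'   `transcript_index`).
#' @param taxonomy A [zf_taxonomy()].
#' @param grammar Scan grammar; defaults to the taxonomy's union grammar.
#' @param allow_truncated Passed to [scan_protein()]; truncated fingers
#'   are counted by default because several taxonomy classes are
#'   truncated.
#' @return A list of class `zf_profile`: `fingers` (all classified
#'   fingers), `proteins` (per-protein count and size class, zero-finger
#'   proteins excluded), `summary` (label counts, totals, and the number
#'   of scanned sequences without fingers).
#' @export
profile_proteome <- function(records, taxonomy = zf_taxonomy(),
                             grammar = taxonomy_grammar(taxonomy),
                             allow_truncated = TRUE) {
  rec <- as_protein_records(records)
  fingers <- lapply(seq_len(nrow(rec)), function(i) {
    f <- scan_protein(rec$sequence[i], grammar, allow_truncated,
                      id = rec$id[i])
    if (nrow(f) > 0)
      f$label <- classify_fingers(f, rec$sequence[i], taxonomy)
    else f$label <- character(0)
    f
  })
  fingers <- do.call(rbind, fingers)
  if (is.null(fingers) || nrow(fingers) == 0) {
    fingers <- cbind(empty_finger_table(),
                     data.frame(label = character()))
  }
  with_fingers <- unique(fingers$protein_id)
  proteins <- data.frame(
    protein_id = with_fingers,
    finger_count = as.integer(table(fingers$protein_id)[with_fingers]),
    stringsAsFactors = FALSE)
  proteins$size_class <- size_class_of(proteins$finger_count)
  counts <- table(factor(fingers$label, levels = taxonomy$label))
  summary <- list(
    counts = counts,
    total_fingers = nrow(fingers),
    total_proteins = nrow(proteins),
    total_sequences = nrow(rec),
    sequences_without_fingers = nrow(rec) - nrow(proteins))
  stopifnot(sum(counts) == summary$total_fingers)
  structure(list(fingers = fingers, proteins = proteins,
                 summary = summary), class = "zf_profile")
}

#' @export
print.zf_profile <- function(x, ...) {
  s <- x$summary
  cat(sprintf("zf_profile: %d fingers in %d of %d sequences\n",
              s$total_fingers, s$total_proteins, s$total_sequences))
  print(s$counts[s$counts > 0])
  invisible(x)
}

#' Collapse transcripts to one protein per gene
#'
#' @param records Protein records (see [profile_proteome()]); entries
#'   without a `gene_id` pass through unchanged.
#' @param policy Keep the `longest` transcript per gene (ties broken by
#'   input order) or the `first` by input order.
#' @return The deduplicated records, one row per gene plus all
#'   singletons, in input order.
#' @export
dedup_transcripts <- function(records, policy = c("longest", "first")) {
  policy <- match.arg(policy)
  rec <- as_protein_records(records)
  key <- ifelse(is.na(rec$gene_id) | rec$gene_id == "",
                paste0(".singleton.", seq_len(nrow(rec))), rec$gene_id)
  keep <- vapply(split(seq_len(nrow(rec)), key)[unique(key)],
                 function(idx) {
                   if (policy == "longest")
                     idx[which.max(nchar(rec$sequence[idx]))]
                   else idx[1L]
                 }, integer(1))
  rec[sort(unname(keep)), , drop = FALSE]
}

#' Extract finger-domain sequences from a proteome profile
#'
#' One entry per finger; the domain id encodes protein and ordinal, and
#' the sequence spans the finger from first cysteine to terminal
#' histidine (or the truncated window end).
#'
#' @param profile A `zf_profile` from [profile_proteome()].
#' @param records The protein records the profile was computed from.
#' @return A data frame with `domain_id`, `protein_id`, `ordinal`,
#'   `label`, `sequence`, the finger-relative spacers and `truncated`
#'   flag (used by [anchor_align()]).
#' @export
extract_finger_domains <- function(profile, records) {
  stopifnot(inherits(profile, "zf_profile"))
  rec <- as_protein_records(records)
  seqs <- stats::setNames(toupper(rec$sequence), rec$id)
  f <- profile$fingers
  if (nrow(f) == 0)
    return(data.frame(domain_id = character(), protein_id = character(),
                      ordinal = integer(), label = character(),
                      sequence = character(), a = integer(), b = integer(),
                      cc = integer(), truncated = logical(),
                      stringsAsFactors = FALSE))
  data.frame(
    domain_id = sprintf("%s_Zf%d", f$protein_id, f$ordinal),
    protein_id = f$protein_id, ordinal = f$ordinal, label = f$label,
    sequence = substr(seqs[f$protein_id], f$start, f$end),
    a = f$a, b = f$b, cc = f$cc, truncated = f$truncated,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize a profile as a taxonomy table
#'
#' @param profile A `zf_profile`.
#' @param taxonomy The taxonomy used to build it.
#' @return A data frame mirroring the taxonomy table layout: class,
#'   label, motif, spacing and the number of fingers found per label.
#' @export
taxonomy_summary_table <- function(profile, taxonomy = zf_taxonomy()) {
  stopifnot(inherits(profile, "zf_profile"))
  data.frame(class = taxonomy$class, label = taxonomy$label,
             motif = taxonomy$motif, spacing = taxonomy$spacing,
             n_fingers = as.integer(profile$summary$counts[taxonomy$label]),
             stringsAsFactors = FALSE)
}

#' Headline counts for a proteome FASTA
#'
#' Convenience wrapper for benchmarking a whole proteome file: reads the
#' FASTA (and optional gene map), deduplicates transcripts, profiles the
#' proteome and returns the headline counts (sequences, genes after
#' deduplication, proteins with fingers, total fingers, per-class
#' totals).
#'
#' @param fasta_path Protein FASTA path.
#' @param gene_map Optional data frame (`protein_id`, `gene_id`,
#'   `transcript_index`) or TSV path assigning transcripts to genes.
#' @param taxonomy A [zf_taxonomy()].
#' @param ... Passed to [profile_proteome()].
#' @return A list with `counts` (named numeric vector) and the underlying
#'   `profile`.
#' @export
benchmark_proteome <- function(fasta_path, gene_map = NULL,
                               taxonomy = zf_taxonomy(), ...) {
  seqs <- read_fasta(fasta_path, type = "AA")
  rec <- as_protein_records(seqs)
  n_sequences <- nrow(rec)
  if (!is.null(gene_map)) {
    if (is.character(gene_map))
      gene_map <- utils::read.delim(gene_map, stringsAsFactors = FALSE)
    idx <- match(rec$id, gene_map$protein_id)
    rec$gene_id <- gene_map$gene_id[idx]
    if ("transcript_index" %in% names(gene_map))
      rec$transcript_index <- gene_map$transcript_index[idx]
  }
  rec <- dedup_transcripts(rec)
  profile <- profile_proteome(rec, taxonomy, ...)
  cls <- tapply(as.integer(profile$summary$counts[taxonomy$label]),
                taxonomy$class, sum)
  counts <- c(n_sequences = n_sequences,
              n_proteins = nrow(rec),
              n_with_fingers = profile$summary$total_proteins,
              total_fingers = profile$summary$total_fingers,
              stats::setNames(as.numeric(cls[c("Q", "M", "Z", "C")]),
                              c("Q_fingers", "M_fingers", "Z_fingers",
                                "C_fingers")))
  list(counts = counts, profile = profile)
}
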