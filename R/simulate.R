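# Synthetic-data generators. Every generator is deterministic under its
# seed (byte-identical re-runs) and returns a ground-truth sidecar
# sufficient to score the corresponding analysis stage exactly.

# Background/spacer residues exclude C and H so the only coordinating
# residues in a synthetic protein are the implanted ones; this realizes
# the "reject windows that accidentally satisfy the grammar" policy by
# construction rather than by resampling whole backgrounds.
FILL_ALPHABET <- setdiff(AA_ALPHABET, c("C", "H"))

rand_fill <- function(n) {
  if (n <= 0) return(character(0))
  sample(FILL_ALPHABET, n, replace = TRUE)
}

# Build one finger string realizing `label`. Returns the characters plus
# the finger-relative 1-based anchor coordinates, or NULL if this random
# attempt is structurally impossible.
build_finger <- function(label, taxonomy) {
  row <- which(taxonomy$label == label)
  stopifnot(length(row) == 1)
  sp <- taxonomy$spacing_parsed[[row]]
  motif <- taxonomy$motif[row]
  mt <- if (motif == "") character(0)
        else strsplit(motif, "", fixed = TRUE)[[1]]
  hs <- which(mt == "H")
  a <- sample(rep(sp$a_allowed, 2), 1)
  # decide the anchor alignment of the motif
  pair_anchor <- FALSE
  if (!sp$h2_required) {
    if (length(hs) == 0) return(NULL)
    h1_idx <- hs[length(hs)]
  } else if (length(hs) >= 2 &&
             (hs[length(hs)] - hs[length(hs) - 1] - 1) %in% sp$c_allowed) {
    pair_anchor <- TRUE
    h1_idx <- hs[length(hs) - 1]
    cc <- hs[length(hs)] - hs[length(hs) - 1] - 1
  } else if (length(hs) >= 1) {
    h1_idx <- hs[length(hs)]
  } else {
    h1_idx <- NA_integer_                  # motif-free fallback class
  }
  if (sp$h2_required && !pair_anchor)
    cc <- sample(rep(sp$c_allowed, 2), 1)
  n_before <- if (is.na(h1_idx)) 0L else h1_idx - 1L
  b_ok <- sp$b_allowed[sp$b_allowed >= n_before]
  if (length(b_ok) == 0) return(NULL)
  b <- sample(rep(b_ok, 2), 1)
  truncated <- !sp$h2_required
  len <- if (truncated) 2L + a + b + 1L + 8L
         else 2L + a + b + cc + 2L
  f <- c("C", rand_fill(a), "C", rand_fill(b), "H",
         if (truncated) rand_fill(8L)
         else c(rand_fill(cc), "H"))
  c1 <- 1L; c2 <- a + 2L; h1 <- a + b + 3L
  h2 <- if (truncated) NA_integer_ else h1 + cc + 1L
  # lay the motif down relative to the first-histidine anchor
  if (!is.na(h1_idx)) {
    offset <- h1 - h1_idx                  # motif char k -> position offset+k
    for (k in seq_along(mt)) {
      pos <- offset + k
      if (pos < 1 || pos > len) return(NULL)
      anchor <- pos %in% c(c1, c2, h1, h2)
      if (mt[k] == "_") {
        if (anchor) next                   # wildcard realizes the anchor
        f[pos] <- sample(FILL_ALPHABET, 1)
      } else {
        if (anchor && f[pos] != mt[k]) return(NULL)
        f[pos] <- mt[k]
      }
    }
  }
  list(chars = f, a = a, b = b, cc = if (truncated) NA_integer_ else cc,
       truncated = truncated, c1 = c1, c2 = c2, h1 = h1, h2 = h2)
}

# Build a finger for `label` and verify in a padded context that the
# scanner and classifier recover exactly the planted anatomy and label.
implant_finger <- function(label, taxonomy, grammar, tries = 60L) {
  for (t in seq_len(tries)) {
    fng <- build_finger(label, taxonomy)
    if (is.null(fng)) next
    pad_l <- paste(rand_fill(20), collapse = "")
    pad_r <- paste(rand_fill(20), collapse = "")
    ctx <- paste0(pad_l, paste(fng$chars, collapse = ""), pad_r)
    hits <- scan_protein(ctx, grammar, allow_truncated = TRUE, id = "ctx")
    off <- nchar(pad_l)
    ok <- nrow(hits) == 1 &&
      hits$c1 == off + fng$c1 && hits$c2 == off + fng$c2 &&
      hits$h1 == off + fng$h1 &&
      identical(is.na(hits$h2), is.na(fng$h2)) &&
      (is.na(fng$h2) || hits$h2 == off + fng$h2)
    if (ok && classify_finger(hits[1, ], ctx, taxonomy) == label)
      return(fng)
  }
  stop("could not implant a recoverable '", label, "' finger; the ",
       "taxonomy row may be unsatisfiable under the scan grammar")
}

#' Synthetic proteome with implanted fingers
#'
#' Generates proteins whose zinc fingers are planted with known
#' coordinates and taxonomy labels. Background and spacer residues are
#' drawn from the 18 non-C/H residues and fingers are separated by
#' linkers of at least 18 residues, so no accidental grammar match can
#' arise; each implant is verified to be recovered exactly by
#' [scan_protein()] + [classify_finger()] before acceptance.
#'
#' @param n_proteins Number of proteins.
#' @param label_weights Named sampling weights over taxonomy labels;
#'   defaults to the taxonomy's `reference_count` column (the observed
#'   family composition).
#' @param finger_count_probs Named probabilities over per-protein finger
#'   counts; defaults favour 1-2 fingers with a tail to 9 (the size
#'   classes A/B/D/E/F/G).
#' @param taxonomy A [zf_taxonomy()].
#' @param seed Integer seed.
#' @param out_dir Optional directory: writes `proteome.fasta` and
#'   `proteome_truth.json`.
#' @return List: `records` (data frame `id`, `sequence`), `sidecar`
#'   (data frame of planted fingers: protein, ordinal, label, anchors,
#'   spacers, span), and file paths when `out_dir` is given.
#' @export
make_proteome <- function(n_proteins = 50L,
                          label_weights = NULL,
                          finger_count_probs = c(`1` = 0.45, `2` = 0.28,
                                                 `3` = 0.12, `4` = 0.08,
                                                 `5` = 0.05, `9` = 0.02),
                          taxonomy = zf_taxonomy(),
                          seed = 1L, out_dir = NULL) {
  stopifnot(n_proteins >= 1)
  grammar <- taxonomy_grammar(taxonomy)
  if (is.null(label_weights)) {
    if (!"reference_count" %in% names(taxonomy))
      stop("taxonomy has no reference_count column; supply label_weights")
    label_weights <- stats::setNames(taxonomy$reference_count,
                                     taxonomy$label)
  }
  stopifnot(all(names(label_weights) %in% taxonomy$label))
  res <- with_seed(seed, {
    records <- data.frame(id = sprintf("SYNP%03d", seq_len(n_proteins)),
                          sequence = NA_character_,
                          stringsAsFactors = FALSE)
    sidecar <- list()
    for (i in seq_len(n_proteins)) {
      n_fingers <- as.integer(sample(names(finger_count_probs), 1,
                                     prob = finger_count_probs))
      labels <- sample(names(label_weights), n_fingers, replace = TRUE,
                       prob = label_weights)
      fingers <- lapply(labels, implant_finger, taxonomy = taxonomy,
                        grammar = grammar)
      pieces <- character(0)
      offset <- 0L
      rows <- list()
      for (k in seq_along(fingers)) {
        linker <- paste(rand_fill(sample(18:40, 1)), collapse = "")
        pieces <- c(pieces, linker)
        offset <- offset + nchar(linker)
        fng <- fingers[[k]]
        fstr <- paste(fng$chars, collapse = "")
        pieces <- c(pieces, fstr)
        rows[[k]] <- data.frame(
          protein_id = records$id[i], ordinal = k, label = labels[k],
          c1 = offset + fng$c1, c2 = offset + fng$c2,
          h1 = offset + fng$h1,
          h2 = if (is.na(fng$h2)) NA_integer_ else offset + fng$h2,
          a = fng$a, b = fng$b, cc = fng$cc,
          start = offset + 1L,
          truncated = fng$truncated, stringsAsFactors = FALSE)
        offset <- offset + nchar(fstr)
      }
      pieces <- c(pieces, paste(rand_fill(sample(18:40, 1)),
                                collapse = ""))
      records$sequence[i] <- paste(pieces, collapse = "")
      sidecar[[i]] <- do.call(rbind, rows)
    }
    sidecar <- do.call(rbind, sidecar)
    sidecar$end <- ifelse(sidecar$truncated,
                          pmin(nchar(records$sequence[
                            match(sidecar$protein_id, records$id)]),
                            sidecar$h1 + max(grammar$c_allowed) + 1L),
                          sidecar$h2)
    list(records = records, sidecar = sidecar)
  })
  # paranoia: the full proteome must reproduce the sidecar exactly
  prof <- profile_proteome(res$records, taxonomy, grammar,
                           allow_truncated = TRUE)
  got <- prof$fingers[order(prof$fingers$protein_id,
                            prof$fingers$ordinal), ]
  want <- res$sidecar[order(res$sidecar$protein_id, res$sidecar$ordinal), ]
  stopifnot(nrow(got) == nrow(want),
            all(got$c1 == want$c1), all(got$h1 == want$h1),
            all(got$label == want$label))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fasta <- file.path(out_dir, "proteome.fasta")
    truth <- file.path(out_dir, "proteome_truth.json")
    write_fasta(stats::setNames(res$records$sequence, res$records$id),
                fasta)
    jsonlite::write_json(res$sidecar, truth, digits = NA, na = "null")
    res$paths <- c(fasta = fasta, truth = truth)
  }
  res
}

#' Synthetic expression atlas
#'
#' Emulates a log2-signal developmental atlas: rows fall into `k`
#' expression-level clusters (default means 7/10/13, the low, wide and
#' high tiers) with Gaussian noise, and a fraction of rows get one
#' elevated tissue (tissue-specific expression, hence high CV).
#'
#' @param n_rows Number of transcripts (default 169, three clusters of
#'   92/39/38).
#' @param tissues Tissue names (default 11 organs).
#' @param cluster_levels Mean log2 signal per cluster (ascending).
#' @param cluster_props Sampling proportions per cluster.
#' @param specific_fraction Fraction of rows made tissue-specific.
#' @param specific_shift Log2 elevation of the specific tissue.
#' @param noise_sd Gaussian noise SD (log2 units).
#' @param seed Integer seed.
#' @param out_dir Optional directory: writes `atlas.tsv` and
#'   `atlas_truth.json`.
#' @return List: `matrix`, `sidecar` (data frame `id`, `cluster`,
#'   `specific`, `specific_tissue`).
#' @export
make_expression <- function(n_rows = 169L,
                            tissues = c("root", "stem", "leaf", "SAM",
                                        "tassel", "anthers", "silks",
                                        "seed", "embryo", "endosperm",
                                        "pericarp"),
                            cluster_levels = c(7, 10, 13),
                            cluster_props = c(92, 39, 38) / 169,
                            specific_fraction = 0.1,
                            specific_shift = 4,
                            noise_sd = 0.5,
                            seed = 1L, out_dir = NULL) {
  stopifnot(length(cluster_levels) == length(cluster_props),
            !is.unsorted(cluster_levels), n_rows >= length(cluster_levels))
  res <- with_seed(seed, {
    k <- length(cluster_levels)
    cluster <- sort(sample(seq_len(k), n_rows, replace = TRUE,
                           prob = cluster_props))
    m <- matrix(stats::rnorm(n_rows * length(tissues),
                             mean = cluster_levels[cluster],
                             sd = noise_sd),
                nrow = n_rows,
                dimnames = list(sprintf("t%04d", seq_len(n_rows)),
                                tissues))
    n_spec <- floor(specific_fraction * n_rows)
    spec_rows <- sort(sample.int(n_rows, n_spec))
    spec_tissue <- rep(NA_character_, n_rows)
    if (n_spec > 0) {
      tsel <- sample(seq_along(tissues), n_spec, replace = TRUE)
      m[cbind(spec_rows, tsel)] <- m[cbind(spec_rows, tsel)] +
        specific_shift
      spec_tissue[spec_rows] <- tissues[tsel]
    }
    sidecar <- data.frame(id = rownames(m), cluster = cluster,
                          specific = seq_len(n_rows) %in% spec_rows,
                          specific_tissue = spec_tissue,
                          stringsAsFactors = FALSE)
    list(matrix = m, sidecar = sidecar)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix_tsv(res$matrix, file.path(out_dir, "atlas.tsv"))
    jsonlite::write_json(res$sidecar,
                         file.path(out_dir, "atlas_truth.json"),
                         digits = NA, na = "null")
  }
  res
}

#' Synthetic treated/control screen with planted responders
#'
#' Control signal is drawn per row; responsive rows get a true log2
#' fold change of magnitude > 1, all others a sub-threshold shift, so
#' the planted responder set is exactly recoverable by the 2-fold rule.
#'
#' @param n_rows Rows per condition.
#' @param conditions Condition names.
#' @param n_responsive Planted responders per condition (recycled;
#'   default 15/10/8, low-temperature/nitrogen/phosphorus style counts).
#' @param lfc_range Magnitude range of planted log2 fold changes.
#' @param seed Integer seed.
#' @return List: `treated`, `control` (log2 matrices), `sidecar`.
#' @export
make_stress_data <- function(n_rows = 100L,
                             conditions = c("lowT", "lowN", "lowP"),
                             n_responsive = c(15L, 10L, 8L),
                             lfc_range = c(1.5, 4),
                             seed = 1L) {
  n_responsive <- rep_len(n_responsive, length(conditions))
  with_seed(seed, {
    ids <- sprintf("g%04d", seq_len(n_rows))
    control <- matrix(stats::runif(n_rows * length(conditions), 6, 14),
                      nrow = n_rows,
                      dimnames = list(ids, conditions))
    treated <- control
    side <- list()
    for (j in seq_along(conditions)) {
      resp <- sort(sample.int(n_rows, n_responsive[j]))
      lfc <- stats::runif(n_rows, -0.8, 0.8)
      mag <- stats::runif(n_responsive[j], lfc_range[1], lfc_range[2])
      lfc[resp] <- mag * sample(c(-1, 1), n_responsive[j],
                                replace = TRUE)
      treated[, j] <- control[, j] + lfc
      side[[j]] <- data.frame(id = ids, condition = conditions[j],
                              true_lfc = lfc,
                              responsive = seq_len(n_rows) %in% resp,
                              stringsAsFactors = FALSE)
    }
    list(treated = treated, control = control,
         sidecar = do.call(rbind, side))
  })
}

#' Synthetic inbred genotype panel with phenotypes
#'
#' Haplotypes are generated by a block-copying Markov process over a
#' small founder pool: each line walks along the chromosome copying one
#' founder haplotype and switches founders with probability
#' `1 - exp(-switch_rate * distance)` between adjacent markers, so
#' linkage disequilibrium decays with distance. Lines are fully
#' homozygous (dosage 0/2). Optional subpopulations draw founder allele
#' frequencies from a Balding-Nichols-style beta around the base
#' frequency. Phenotypes are `env shift + sum(effect * dosage) +
#' Gaussian noise` with the noise variance set from the target
#' single-observation heritability.
#'
#' @param n_lines Number of inbred lines (default 513, an
#'   association-panel size).
#' @param n_markers Number of markers.
#' @param n_founders Founder haplotypes per subpopulation.
#' @param maf_range Base allele-frequency range.
#' @param spacing_range Inter-marker spacing range in bp.
#' @param switch_rate Per-bp founder switch rate (LD decay scale).
#' @param n_subpops Number of subpopulations (1 = unstructured).
#' @param fst Divergence of subpopulation frequencies.
#' @param causal Optional data frame `marker` (index), `trait`, `effect`
#'   planting causal variants; `NULL` plants a polygenic line effect for
#'   one trait.
#' @param n_envs Number of environments.
#' @param h2 Target heritability in (0, 1].
#' @param missing_rate Fraction of calls set missing.
#' @param seed Integer seed.
#' @param out_dir Optional directory: writes `panel.vcf`,
#'   `phenotypes.tsv`, `panel_truth.json`.
#' @return List: `panel` ([genotype_panel()]), `phenotypes` (long data
#'   frame `line`, `env`, one column per trait), `sidecar`.
#' @export
make_panel <- function(n_lines = 513L, n_markers = 500L,
                       n_founders = 16L, maf_range = c(0.05, 0.5),
                       spacing_range = c(50L, 150L),
                       switch_rate = 2e-4, n_subpops = 1L, fst = 0.1,
                       causal = NULL, n_envs = 3L, h2 = 0.5,
                       missing_rate = 0, seed = 1L, out_dir = NULL) {
  if (!(h2 > 0 && h2 <= 1)) stop("h2 must lie in (0, 1]")
  stopifnot(n_lines >= 2, n_markers >= 2)
  res <- with_seed(seed, {
    pos <- cumsum(sample(spacing_range[1]:spacing_range[2], n_markers,
                         replace = TRUE))
    p_base <- stats::runif(n_markers, maf_range[1], maf_range[2])
    subpop <- rep_len(seq_len(n_subpops), n_lines)
    founders <- vector("list", n_subpops)
    for (s in seq_len(n_subpops)) {
      p_s <- if (n_subpops == 1) p_base else {
        shape <- (1 - fst) / fst
        pmin(pmax(stats::rbeta(n_markers, p_base * shape,
                               (1 - p_base) * shape), 0.01), 0.99)
      }
      founders[[s]] <- matrix(
        stats::rbinom(n_founders * n_markers, 1,
                      rep(p_s, each = n_founders)),
        nrow = n_founders)
    }
    switch_p <- 1 - exp(-switch_rate * diff(pos))
    calls <- matrix(NA_integer_, n_markers, n_lines)
    for (i in seq_len(n_lines)) {
      fo <- founders[[subpop[i]]]
      f <- integer(n_markers)
      f[1] <- sample.int(n_founders, 1)
      sw <- stats::runif(n_markers - 1) < switch_p
      for (j in 2:n_markers)
        f[j] <- if (sw[j - 1]) sample.int(n_founders, 1) else f[j - 1]
      calls[, i] <- 2L * fo[cbind(f, seq_len(n_markers))]
    }
    if (missing_rate > 0) {
      nmiss <- round(missing_rate * length(calls))
      calls[sample.int(length(calls), nmiss)] <- NA_integer_
    }
    lines <- sprintf("L%04d", seq_len(n_lines))
    markers <- data.frame(
      marker_id = sprintf("chr1.S_%d", pos), chrom = "chr1", pos = pos,
      type = "SNP", stringsAsFactors = FALSE)
    panel <- genotype_panel(markers, lines, calls)
    # phenotypes
    if (is.null(causal)) {
      causal_tab <- data.frame(marker = integer(), trait = character(),
                               effect = numeric())
      g <- list(trait1 = stats::rnorm(n_lines))
    } else {
      stopifnot(all(c("marker", "trait", "effect") %in% names(causal)))
      causal_tab <- causal
      g <- lapply(split(causal, causal$trait), function(cz) {
        dos <- calls[cz$marker, , drop = FALSE]
        dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
        as.vector(crossprod(dos, cz$effect))
      })
    }
    env_shift <- seq_len(n_envs) - (n_envs + 1) / 2
    phen <- expand.grid(line = lines, env = sprintf("E%d", seq_len(n_envs)),
                        stringsAsFactors = FALSE)
    for (tr in names(g)) {
      gi <- g[[tr]]
      var_g <- stats::var(gi)
      if (var_g == 0) var_g <- 1
      sd_e <- sqrt(var_g * (1 - h2) / h2)
      phen[[tr]] <- env_shift[match(phen$env,
                                    sprintf("E%d", seq_len(n_envs)))] +
        gi[match(phen$line, lines)] +
        stats::rnorm(nrow(phen), 0, sd_e)
    }
    sidecar <- list(subpop = data.frame(line = lines, subpop = subpop,
                                        stringsAsFactors = FALSE),
                    causal = causal_tab, base_freq = p_base,
                    h2 = h2, env_shift = env_shift,
                    switch_rate = switch_rate)
    list(panel = panel, phenotypes = phen, sidecar = sidecar)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_vcf_panel(res$panel, file.path(out_dir, "panel.vcf"))
    utils::write.table(res$phenotypes,
                       file.path(out_dir, "phenotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(res$sidecar,
                         file.path(out_dir, "panel_truth.json"),
                         digits = NA, na = "null")
  }
  res
}

#' Synthetic resequenced-locus alignment
#'
#' A reference sequence plus mutated copies for a panel of inbred lines:
#' planted substitution sites and deletion blocks (indels, relative to
#' the reference) at known positions, all with minor-allele frequency at
#' or above 0.05 and separated so no two events merge. The sidecar lists
#' every planted marker with the dosage coding [msa_to_variants()] is
#' expected to emit.
#'
#' @param n_lines Number of lines including the reference row (default
#'   109, an amplicon-panel size).
#' @param locus_len Locus length in bp (default 4516).
#' @param n_snps,n_indels Planted substitution sites / deletion blocks
#'   (defaults 31 and 11).
#' @param indel_len_range Deletion-block length range.
#' @param maf_range Carrier-frequency range for planted variants.
#' @param chrom Locus tag for marker ids.
#' @param seed Integer seed.
#' @param out_dir Optional directory: writes `locus.afa` and
#'   `locus_truth.json`.
#' @return List: `alignment` (character matrix, first row `REF`),
#'   `reference_row`, `sidecar` (`markers` data frame and expected
#'   `calls` matrix).
#' @export
make_locus_alignment <- function(n_lines = 109L, locus_len = 4516L,
                                 n_snps = 31L, n_indels = 11L,
                                 indel_len_range = c(1L, 6L),
                                 maf_range = c(0.05, 0.45),
                                 chrom = "locus", seed = 1L,
                                 out_dir = NULL) {
  stopifnot(n_lines >= 4, locus_len >= 10)
  res <- with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, locus_len, replace = TRUE)
    # place events with >= 2 bp clearance so indel runs never merge
    events <- data.frame(pos = integer(), len = integer(),
                         type = character(), stringsAsFactors = FALSE)
    lens <- c(rep(1L, n_snps),
              if (n_indels > 0)
                sample(indel_len_range[1]:indel_len_range[2], n_indels,
                       replace = TRUE))
    types <- c(rep("SNP", n_snps), rep("Indel", n_indels))
    ord <- sample(seq_along(lens))
    occupied <- rep(FALSE, locus_len)
    for (k in ord) {
      placed <- FALSE
      for (t in seq_len(200)) {
        s <- sample.int(locus_len - lens[k] + 1L, 1)
        span <- max(1, s - 2):min(locus_len, s + lens[k] + 1)
        if (!any(occupied[span])) {
          occupied[s:(s + lens[k] - 1)] <- TRUE
          events <- rbind(events, data.frame(
            pos = s, len = lens[k], type = types[k],
            stringsAsFactors = FALSE))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place all variants without overlap; ",
             "reduce n_snps/n_indels or lengthen the locus")
    }
    events <- events[order(events$pos), , drop = FALSE]
    lines <- c("REF", sprintf("L%03d", seq_len(n_lines - 1L)))
    aln <- matrix(rep(ref, each = n_lines), nrow = n_lines,
                  dimnames = list(lines, NULL))
    markers <- list(); calls <- list()
    n_carrier_ok <- function(k) {
      k >= ceiling(0.05 * n_lines) && 2 * k < n_lines
    }
    for (e in seq_len(nrow(events))) {
      repeat {
        p <- stats::runif(1, maf_range[1], maf_range[2])
        carrier <- which(stats::runif(n_lines - 1) < p) + 1L  # never REF
        if (n_carrier_ok(length(carrier))) break
      }
      s <- events$pos[e]
      if (events$type[e] == "SNP") {
        alt <- sample(setdiff(bases, ref[s]), 1)
        aln[carrier, s] <- alt
      } else {
        aln[carrier, s:(s + events$len[e] - 1L)] <- "-"
      }
      dosage <- integer(n_lines)
      dosage[carrier] <- 2L
      markers[[e]] <- data.frame(
        marker_id = sprintf("%s.S_%d", chrom, s), chrom = chrom,
        pos = s, type = events$type[e],
        maf = length(carrier) / n_lines, stringsAsFactors = FALSE)
      calls[[e]] <- dosage
    }
    sidecar <- list(
      markers = if (length(markers)) do.call(rbind, markers)
                else data.frame(marker_id = character(), chrom = character(),
                                pos = integer(), type = character(),
                                maf = numeric(), stringsAsFactors = FALSE),
      calls = if (length(calls))
        matrix(unlist(calls), ncol = n_lines, byrow = TRUE,
               dimnames = list(vapply(markers, `[[`, character(1),
                                      "marker_id"), lines))
      else matrix(integer(), 0, n_lines))
    list(alignment = aln, reference_row = "REF", sidecar = sidecar)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    seqs <- apply(res$alignment, 1, paste, collapse = "")
    write_fasta(seqs, file.path(out_dir, "locus.afa"))
    jsonlite::write_json(res$sidecar$markers,
                         file.path(out_dir, "locus_truth.json"),
                         digits = NA, na = "null")
  }
  res
}
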