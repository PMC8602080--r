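#' Genotype panel container
#'
#' Markers-by-lines dosage calls with marker metadata. Calls are coded
#' 0/1/2 as minor- (or alternate-) allele dosage with `NA` for missing;
#' fully inbred lines carry only 0/2.
#'
#' @param markers Data frame with columns `marker_id`, `chrom`, `pos`
#'   (1-based bp) and `type` (`"SNP"` or `"Indel"`).
#' @param lines Character vector of line ids.
#' @param calls Integer matrix, markers x lines.
#' @return An object of class `zf_panel`.
#' @export
genotype_panel <- function(markers, lines, calls) {
  stopifnot(is.data.frame(markers),
            all(c("marker_id", "chrom", "pos", "type") %in% names(markers)),
            is.matrix(calls),
            nrow(calls) == nrow(markers),
            ncol(calls) == length(lines))
  if (anyDuplicated(markers$marker_id))
    stop("duplicate marker ids")
  if (anyDuplicated(lines))
    stop("duplicate line ids")
  bad <- !is.na(calls) & !calls %in% c(0L, 1L, 2L)
  if (any(bad))
    stop("genotype calls must be 0/1/2 or NA")
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (is.unsorted(p))
      stop("marker positions must be nondecreasing within chromosome ", ch)
  }
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(markers$marker_id, lines)
  structure(list(markers = markers, lines = lines, calls = calls),
            class = "zf_panel")
}

#' @export
print.zf_panel <- function(x, ...) {
  cat(sprintf("zf_panel: %d markers x %d lines (%d SNP, %d Indel)\n",
              nrow(x$markers), length(x$lines),
              sum(x$markers$type == "SNP"),
              sum(x$markers$type == "Indel")))
  invisible(x)
}

subset_panel <- function(panel, idx) {
  genotype_panel(panel$markers[idx, , drop = FALSE], panel$lines,
                 panel$calls[idx, , drop = FALSE])
}

#' Minor allele frequency and call rate per marker
#'
#' MAF is computed over non-missing alleles only and lies in \[0, 0.5\];
#' all-missing markers get `NA`.
#'
#' @param panel A [genotype_panel()].
#' @return Data frame `marker_id`, `maf`, `call_rate`.
#' @export
compute_maf <- function(panel) {
  stopifnot(inherits(panel, "zf_panel"))
  n_obs <- rowSums(!is.na(panel$calls))
  p <- rowSums(panel$calls, na.rm = TRUE) / (2 * n_obs)
  p[n_obs == 0] <- NA_real_
  data.frame(marker_id = panel$markers$marker_id,
             maf = pmin(p, 1 - p),
             call_rate = n_obs / length(panel$lines),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter a panel by minor allele frequency
#'
#' Retains markers with MAF at or above the threshold; all-missing
#' markers are dropped with a diagnostic message.
#'
#' @param panel A [genotype_panel()].
#' @param threshold MAF threshold (default 0.05, the conventional panel
#'   filter).
#' @return The filtered panel.
#' @export
filter_maf <- function(panel, threshold = 0.05) {
  stats <- compute_maf(panel)
  if (any(is.na(stats$maf)))
    message(sum(is.na(stats$maf)), " all-missing marker(s) dropped")
  keep <- !is.na(stats$maf) & stats$maf >= threshold
  subset_panel(panel, keep)
}

#' Extract markers falling in gene intervals
#'
#' Intervals are 1-based inclusive; a marker at `start` or `end` is
#' retained. An optional symmetric flank widens each interval.
#'
#' @param panel A [genotype_panel()].
#' @param intervals Data frame with `gene_id`, `chrom`, `start`, `end`.
#' @param flank Flank in bp added on each side (default 0).
#' @return List: `panel` (markers in any interval) and `gene_counts`
#'   (markers per gene, including zero-count genes).
#' @export
extract_gene_snps <- function(panel, intervals, flank = 0L) {
  stopifnot(inherits(panel, "zf_panel"),
            all(c("gene_id", "chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$end < intervals$start))
    stop("malformed interval: end < start for gene ",
         intervals$gene_id[which(intervals$end < intervals$start)[1]])
  m <- panel$markers
  hits <- lapply(seq_len(nrow(intervals)), function(i) {
    which(m$chrom == intervals$chrom[i] &
          m$pos >= intervals$start[i] - flank &
          m$pos <= intervals$end[i] + flank)
  })
  counts <- data.frame(gene_id = intervals$gene_id,
                       n_markers = lengths(hits),
                       stringsAsFactors = FALSE)
  keep <- sort(unique(unlist(hits)))
  sub <- if (length(keep) == 0)
    genotype_panel(m[0, , drop = FALSE], panel$lines,
                   panel$calls[0, , drop = FALSE])
  else subset_panel(panel, keep)
  list(panel = sub, gene_counts = counts)
}
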