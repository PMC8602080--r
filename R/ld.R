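#' Pairwise linkage-disequilibrium r-squared
#'
#' Composite LD: r-squared is the squared Pearson correlation of the
#' dosage vectors of the two markers over lines non-missing at both
#' (for fully homozygous inbred lines this coincides with haplotype
#' r-squared). Markers below the MAF threshold are excluded first; pairs
#' with fewer than `min_obs` jointly observed lines or a monomorphic
#' member are skipped with a diagnostic count.
#'
#' @param panel A [genotype_panel()].
#' @param maf_threshold MAF filter applied before pairing (default
#'   0.05, the all-polymorphic-sites convention).
#' @param min_obs Minimum jointly observed lines per pair.
#' @return Data frame `id1`, `id2`, `distance` (bp, `NA` across
#'   chromosomes), `r2`; attribute `n_skipped`.
#' @export
pairwise_r2 <- function(panel, maf_threshold = 0.05, min_obs = 3L) {
  stopifnot(inherits(panel, "zf_panel"))
  panel <- filter_maf(panel, maf_threshold)
  m <- nrow(panel$markers)
  if (m < 2)
    return(structure(data.frame(id1 = character(), id2 = character(),
                                distance = integer(), r2 = numeric(),
                                stringsAsFactors = FALSE),
                     n_skipped = 0L))
  G <- t(panel$calls)
  suppressWarnings(
    C <- stats::cor(G, use = "pairwise.complete.obs"))
  obs <- crossprod(!is.na(G))
  idx <- which(upper.tri(C), arr.ind = TRUE)
  mk <- panel$markers
  out <- data.frame(
    id1 = mk$marker_id[idx[, 1]], id2 = mk$marker_id[idx[, 2]],
    distance = ifelse(mk$chrom[idx[, 1]] == mk$chrom[idx[, 2]],
                      abs(mk$pos[idx[, 1]] - mk$pos[idx[, 2]]),
                      NA_integer_),
    r2 = C[idx]^2,
    stringsAsFactors = FALSE)
  skip <- obs[idx] < min_obs | is.na(out$r2)
  if (any(skip))
    message(sum(skip), " marker pair(s) skipped (insufficient joint ",
            "observations or zero variance)")
  structure(out[!skip, , drop = FALSE], n_skipped = sum(skip))
}

#' LD decay profile
#'
#' Bins pairwise r-squared by inter-marker distance and reports the mean
#' r-squared and pair count per bin; bin edges are `[0, w), [w, 2w), ...`
#' over the observed distance range.
#'
#' @param results Data frame from [pairwise_r2()] (same-chromosome pairs
#'   only; rows with `NA` distance are dropped).
#' @param bin_width Bin width in bp.
#' @return Data frame `bin_start`, `bin_end`, `mean_r2`, `n_pairs`;
#'   pair counts sum to the number of usable input pairs.
#' @export
ld_decay <- function(results, bin_width) {
  stopifnot(is.data.frame(results), nrow(results) >= 1, bin_width > 0)
  d <- results[!is.na(results$distance), , drop = FALSE]
  bin <- floor(d$distance / bin_width)
  agg <- do.call(rbind, lapply(split(d$r2, bin), function(r)
    data.frame(mean_r2 = mean(r), n_pairs = length(r))))
  bins <- as.integer(rownames(agg))
  out <- data.frame(bin_start = bins * bin_width,
                    bin_end = (bins + 1) * bin_width,
                    mean_r2 = agg$mean_r2, n_pairs = agg$n_pairs,
                    stringsAsFactors = FALSE)
  out[order(out$bin_start), , drop = FALSE]
}
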