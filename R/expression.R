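#' Coefficient of variation per expression row
#'
#' CV = 100 * SD / mean across tissues, with the sample (n - 1) standard
#' deviation; low CV marks housekeeping-like profiles, high CV marks
#' tissue-specific ones. Rows with nonpositive mean are flagged and carry
#' `NA` CV (excluded from ranking).
#'
#' @param matrix Numeric matrix, rows = genes/transcripts, columns =
#'   tissues (log-scale signal); at least 2 columns.
#' @return Data frame `id`, `mean`, `sd`, `cv`, `flagged`.
#' @export
compute_cv <- function(matrix) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 2,
            all(is.finite(matrix)))
  mu <- rowMeans(matrix)
  sd <- apply(matrix, 1, stats::sd)
  flagged <- mu <= 0
  cv <- ifelse(flagged, NA_real_, 100 * sd / mu)
  data.frame(id = rownames(matrix), mean = mu, sd = sd, cv = cv,
             flagged = flagged, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of rows (average linkage on Euclidean
#' distance by default), cut into `k` groups. Cluster labels are
#' renumbered 1..k by increasing mean expression (mean of row means), so
#' label 1 is always the lowest-expression cluster; membership, not the
#' arbitrary hclust labels, is the meaningful output.
#'
#' @param matrix Numeric matrix (rows clustered).
#' @param k Number of clusters (default 3).
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param metric Distance metric for [stats::dist()].
#' @return List of class `zf_clusters`: `assignment` (data frame `id`,
#'   `cluster`), `sizes`, `cluster_means` (mean of row means per
#'   cluster), `hclust`, `order` (dendrogram row order).
#' @export
hier_cluster <- function(matrix, k = 3L, linkage = "average",
                         metric = "euclidean") {
  stopifnot(is.matrix(matrix), k >= 2)
  if (k > nrow(matrix))
    stop("k exceeds the number of rows")
  hc <- stats::hclust(stats::dist(matrix, method = metric),
                      method = linkage)
  raw <- stats::cutree(hc, k = k)
  mm <- tapply(rowMeans(matrix), raw, mean)
  relabel <- match(names(sort(mm)), names(mm))
  cluster <- match(raw, relabel)
  assignment <- data.frame(id = rownames(matrix), cluster = cluster,
                           stringsAsFactors = FALSE, row.names = NULL)
  structure(list(assignment = assignment,
                 sizes = as.integer(table(cluster)),
                 cluster_means = as.numeric(sort(mm)),
                 hclust = hc, order = hc$order),
            class = "zf_clusters")
}

#' @export
print.zf_clusters <- function(x, ...) {
  cat(sprintf("zf_clusters: %d clusters (sizes %s; means %s)\n",
              length(x$sizes), paste(x$sizes, collapse = "/"),
              paste(round(x$cluster_means, 2), collapse = "/")))
  invisible(x)
}

#' Fold-change stress screen
#'
#' Computes log2(treated/control) per row and condition and flags rows
#' responsive by the more-than-2-fold rule: `|log2 ratio| > 1`, strictly.
#' Matrices may be log2-scale (ratios by subtraction) or linear-scale
#' (ratios by division; rows with a nonpositive value get the pseudocount
#' added to both sides and are flagged).
#'
#' @param treated,control Numeric matrices with identical dimnames
#'   (columns = conditions).
#' @param scale `"log2"` or `"linear"`.
#' @param pseudocount Added to both values of a flagged linear-scale row.
#' @param threshold Responsiveness cutoff on |log2 ratio| (default 1).
#' @return Data frame `id`, `condition`, `log2_ratio`, `responsive`,
#'   `direction` (`up`/`down`/`neutral`), `flagged`; attribute
#'   `summary` counts up/down rows per condition.
#' @export
stress_screen <- function(treated, control, scale = c("log2", "linear"),
                          pseudocount = 1, threshold = 1) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(treated), is.matrix(control),
            identical(dim(treated), dim(control)),
            identical(dimnames(treated), dimnames(control)))
  if (scale == "log2") {
    lr <- treated - control
    flagged <- matrix(FALSE, nrow(treated), ncol(treated))
  } else {
    flagged <- treated <= 0 | control <= 0
    tr <- treated + pseudocount * flagged
    ct <- control + pseudocount * flagged
    lr <- log2(tr / ct)
  }
  out <- data.frame(
    id = rep(rownames(treated), times = ncol(treated)),
    condition = rep(colnames(treated), each = nrow(treated)),
    log2_ratio = as.vector(lr),
    flagged = as.vector(flagged),
    stringsAsFactors = FALSE)
  out$responsive <- abs(out$log2_ratio) > threshold
  out$direction <- ifelse(!out$responsive, "neutral",
                          ifelse(out$log2_ratio > 0, "up", "down"))
  smry <- do.call(rbind, lapply(split(out, out$condition), function(d)
    data.frame(condition = d$condition[1],
               n_up = sum(d$direction == "up"),
               n_down = sum(d$direction == "down"),
               n_responsive = sum(d$responsive))))
  rownames(smry) <- NULL
  attr(out, "summary") <- smry
  out
}

#' Detectability report against a reference gene set
#'
#' Marks each matrix row detected when its maximum signal exceeds the
#' detection floor, and summarizes the reference set: how many reference
#' genes are detected, undetected, or absent from the matrix entirely
#' (absent counts as undetected).
#'
#' @param matrix Expression matrix (rows = genes).
#' @param reference_genes Character vector of gene ids to audit.
#' @param floor Detection floor on the matrix scale; `-Inf` marks every
#'   present row detected.
#' @return List: `status` (data frame `gene`, `present`, `detected`) and
#'   `summary` (named counts).
#' @export
detectability_report <- function(matrix, reference_genes, floor = -Inf) {
  stopifnot(is.matrix(matrix))
  detected_rows <- apply(matrix, 1, max) > floor
  present <- reference_genes %in% rownames(matrix)
  detected <- present & detected_rows[
    match(reference_genes, rownames(matrix))]
  detected[is.na(detected)] <- FALSE
  status <- data.frame(gene = reference_genes, present = present,
                       detected = detected, stringsAsFactors = FALSE)
  list(status = status,
       summary = c(n_reference = length(reference_genes),
                   n_detected = sum(detected),
                   n_undetected = sum(!detected),
                   n_absent = sum(!present)))
}
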