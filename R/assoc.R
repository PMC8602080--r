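#' Multi-environment BLUPs per trait
#'
#' Fits, for each trait, the one-way random-effects model
#' `y_ij = mu + env_j + line_i + e_ij` (environment fixed, line random)
#' by REML and returns each line's best linear unbiased prediction — the
#' shrunken line effect used as the association-mapping phenotype. With a
#' single environment (no replication) the model degenerates and the
#' centered phenotype is returned unshrunken, with a warning.
#'
#' @param phenotypes Data frame with columns `line`, `env` and one
#'   numeric column per trait.
#' @return List of class `zf_blup`: `blups` (lines x traits data frame,
#'   each trait centered) and `varcomp` (per-trait line and residual
#'   variance components; `NA` in the degenerate case).
#' @export
fit_blup <- function(phenotypes) {
  stopifnot(is.data.frame(phenotypes),
            all(c("line", "env") %in% names(phenotypes)))
  traits <- setdiff(names(phenotypes), c("line", "env"))
  stopifnot(length(traits) >= 1)
  lines <- unique(phenotypes$line)
  blups <- data.frame(line = lines, stringsAsFactors = FALSE)
  varcomp <- data.frame(trait = traits, var_line = NA_real_,
                        var_resid = NA_real_, stringsAsFactors = FALSE)
  for (tr in traits) {
    d <- phenotypes[!is.na(phenotypes[[tr]]),
                    c("line", "env", tr), drop = FALSE]
    names(d)[3] <- "y"
    if (length(unique(d$env)) < 2) {
      warning("trait '", tr, "' has a single environment; ",
              "returning centered values without shrinkage")
      mu <- tapply(d$y, d$line, mean)
      blups[[tr]] <- unname(mu[lines] - mean(mu, na.rm = TRUE))
      next
    }
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(y ~ env + (1 | line), data = d, REML = TRUE)))
    re <- lme4::ranef(fit)$line
    blups[[tr]] <- re[match(lines, rownames(re)), 1]
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp$var_line[varcomp$trait == tr] <-
      vc$vcov[vc$grp == "line"]
    varcomp$var_resid[varcomp$trait == tr] <-
      vc$vcov[vc$grp == "Residual"]
  }
  structure(list(blups = blups, varcomp = varcomp), class = "zf_blup")
}

#' Population-structure covariates by genotype PCA
#'
#' Principal components of the lines x markers dosage matrix. Missing
#' calls are mean-imputed per marker; markers are centered and optionally
#' standardized by `sqrt(2 p (1 - p))` (allele-frequency scaling).
#'
#' @param panel A [genotype_panel()].
#' @param n_components Number of components (< number of lines).
#' @param standardize Frequency-standardize markers before the PCA.
#' @return Numeric matrix, lines x components (`PC1`, `PC2`, ...), with
#'   attribute `variance_explained`.
#' @export
pca_covariates <- function(panel, n_components = 3L,
                           standardize = FALSE) {
  stopifnot(inherits(panel, "zf_panel"))
  n_lines <- length(panel$lines)
  if (n_components >= n_lines)
    stop("n_components must be smaller than the number of lines")
  G <- t(panel$calls)                      # lines x markers
  mu <- colMeans(G, na.rm = TRUE)
  idx <- which(is.na(G), arr.ind = TRUE)
  if (nrow(idx) > 0) G[idx] <- mu[idx[, 2]]
  G <- sweep(G, 2, mu)
  if (standardize) {
    p <- mu / 2
    sc <- sqrt(2 * p * (1 - p))
    ok <- sc > 0
    G <- sweep(G[, ok, drop = FALSE], 2, sc[ok], "/")
  }
  keep <- apply(G, 2, function(x) any(x != 0))
  pc <- stats::prcomp(G[, keep, drop = FALSE], center = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- panel$lines
  attr(scores, "variance_explained") <-
    (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  scores
}

#' Per-marker general linear model association scan
#'
#' For every marker and trait, fits ordinary least squares
#' `trait ~ covariates + dosage` and tests the marker term with an
#' F-test against the covariate-only model. The reported `r_squared` is
#' the marker's incremental R-squared — the additional fraction of total
#' trait variance explained over the covariate-only model. Missing
#' genotypes are handled by casewise deletion; a marker collinear with
#' the covariates (no residual dosage variance) is flagged with `NA` p.
#'
#' @param panel A [genotype_panel()] (typically MAF-filtered).
#' @param traits Data frame of phenotypes per line: a `line` column plus
#'   one numeric column per trait (e.g. `fit_blup()$blups`).
#' @param covariates Optional lines x components matrix (e.g. from
#'   [pca_covariates()]); rows matched to `panel$lines`.
#' @param alpha Significance threshold on the raw p-value (the panel
#'   screen convention is 1e-4; the candidate-gene convention is 1e-2,
#'   i.e. -log10 p >= 2).
#' @return Data frame `marker_id`, `trait`, `p_value`, `r_squared`,
#'   `model` (`GLM` or `GLM+PCA`), `significant`, `flagged`.
#' @export
glm_assoc <- function(panel, traits, covariates = NULL, alpha = 1e-4) {
  stopifnot(inherits(panel, "zf_panel"), is.data.frame(traits),
            "line" %in% names(traits))
  trait_names <- setdiff(names(traits), "line")
  stopifnot(length(trait_names) >= 1)
  lines <- panel$lines
  model_tag <- if (is.null(covariates)) "GLM" else "GLM+PCA"
  X <- matrix(1, length(lines), 1)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (!is.null(rownames(covariates)))
      covariates <- covariates[match(lines, rownames(covariates)), ,
                               drop = FALSE]
    if (anyNA(covariates))
      stop("covariates must be complete for every panel line")
    X <- cbind(X, covariates)
  }
  G <- t(panel$calls)                      # lines x markers
  res <- list()
  for (tr in trait_names) {
    y <- traits[[tr]][match(lines, traits$line)]
    out <- data.frame(marker_id = panel$markers$marker_id, trait = tr,
                      p_value = NA_real_, r_squared = NA_real_,
                      model = model_tag, significant = FALSE,
                      flagged = FALSE, stringsAsFactors = FALSE)
    complete_y <- !is.na(y)
    for (j in seq_len(ncol(G))) {
      use <- complete_y & !is.na(G[, j])
      n <- sum(use)
      p0 <- ncol(X)
      if (n < p0 + 2) { out$flagged[j] <- TRUE; next }
      Xu <- X[use, , drop = FALSE]
      yu <- y[use]; gu <- G[use, j]
      q <- qr(Xu)
      ry <- qr.resid(q, yu)
      rg <- qr.resid(q, gu)
      ss_g <- sum(rg^2)
      if (ss_g < 1e-12) { out$flagged[j] <- TRUE; next }
      rss0 <- sum(ry^2)
      beta <- sum(rg * ry) / ss_g
      rss1 <- rss0 - beta^2 * ss_g
      df2 <- n - p0 - 1
      fstat <- (rss0 - rss1) / (rss1 / df2)
      out$p_value[j] <- stats::pf(fstat, 1, df2, lower.tail = FALSE)
      tss <- sum((yu - mean(yu))^2)
      out$r_squared[j] <- if (tss > 0) (rss0 - rss1) / tss else NA_real_
    }
    out$significant <- !is.na(out$p_value) & out$p_value < alpha
    res[[tr]] <- out
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Extract SNP and Indel markers from a locus alignment
#'
#' Converts an aligned set of resequenced amplicons (one locus across
#' inbred lines) into a genotype panel: polymorphic substitution columns
#' become SNP markers; maximal runs of adjacent gap-vs-residue columns
#' with identical line membership collapse into single biallelic
#' presence/absence Indel markers. Positions are reference coordinates
#' (1-based; columns gapped in the reference anchor to the preceding
#' reference base). Lines are coded 0/2 minor-allele dosage (inbred,
#' homozygous); ambiguous residues are missing.
#'
#' @param alignment Character matrix (rows = lines, columns = alignment
#'   columns) or aligned-FASTA path.
#' @param reference_row Row name of the reference line.
#' @param chrom Chromosome/locus tag used in marker ids
#'   (`<chrom>.S_<pos>`).
#' @return A [genotype_panel()]; zero markers if the alignment is
#'   monomorphic.
#' @export
msa_to_variants <- function(alignment, reference_row,
                            chrom = "locus") {
  if (is.character(alignment) && length(alignment) == 1)
    alignment <- read_alignment_fasta(alignment)
  stopifnot(is.matrix(alignment), reference_row %in% rownames(alignment))
  A <- toupper(alignment)
  lines <- rownames(A)
  valid <- c("A", "C", "G", "T")
  ref <- A[reference_row, ]
  refpos <- cumsum(ref != "-")           # reference coordinate per column
  refpos[refpos == 0] <- 1L
  n_col <- ncol(A)
  gap <- A == "-"
  markers <- list(); calls <- list()
  add_marker <- function(id, pos, type, dosage) {
    markers[[length(markers) + 1L]] <<- data.frame(
      marker_id = id, chrom = chrom, pos = pos, type = type,
      stringsAsFactors = FALSE)
    calls[[length(calls) + 1L]] <<- dosage
  }
  run_cols <- integer(0)
  run_members <- NULL
  flush_run <- function() {
    if (length(run_cols) == 0) return()
    pos <- refpos[run_cols[1]]
    carrier <- run_members
    minor_is_gap <- sum(carrier) <= length(carrier) / 2
    dosage <- if (minor_is_gap) ifelse(carrier, 2L, 0L)
              else ifelse(carrier, 0L, 2L)
    add_marker(sprintf("%s.S_%d", chrom, pos), pos, "Indel", dosage)
    run_cols <<- integer(0); run_members <<- NULL
  }
  for (j in seq_len(n_col)) {
    col <- A[, j]
    g <- gap[, j]
    if (any(g) && !all(g)) {               # indel column
      if (length(run_cols) > 0 &&
          run_cols[length(run_cols)] == j - 1L &&
          identical(run_members, g)) {
        run_cols <- c(run_cols, j)
      } else {
        flush_run()
        run_cols <- j
        run_members <- g
      }
      next
    }
    flush_run()
    if (all(g)) next
    obs <- col[col %in% valid]
    alleles <- unique(obs)
    if (length(alleles) < 2) next          # monomorphic (or all ambiguous)
    tab <- sort(table(obs), decreasing = TRUE)
    major <- names(tab)[1]
    dosage <- ifelse(col %in% valid, ifelse(col == major, 0L, 2L),
                     NA_integer_)
    add_marker(sprintf("%s.S_%d", chrom, refpos[j]), refpos[j], "SNP",
               dosage)
  }
  flush_run()
  if (length(markers) == 0) {
    empty <- data.frame(marker_id = character(), chrom = character(),
                        pos = integer(), type = character(),
                        stringsAsFactors = FALSE)
    return(genotype_panel(empty, lines,
                          matrix(integer(), 0, length(lines))))
  }
  mk <- do.call(rbind, markers)
  cl <- do.call(rbind, calls)
  ord <- order(mk$pos, mk$type)
  mk <- mk[ord, , drop = FALSE]
  cl <- cl[ord, , drop = FALSE]
  if (anyDuplicated(mk$marker_id))
    mk$marker_id <- make.unique(mk$marker_id, sep = "_")
  genotype_panel(mk, lines, cl)
}
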