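#' Read a FASTA file
#'
#' @param path File path.
#' @param type `"AA"` for protein, `"DNA"` for nucleotide.
#' @return Named character vector of sequences (upper case; CRLF and line
#'   wrapping are handled by the underlying Biostrings parser).
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(set)), names(set))
}

#' Write sequences to FASTA
#'
#' @param x Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(is.character(x), !is.null(names(x)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Read an aligned FASTA into a character matrix
#'
#' All rows must have equal length; rows are sequences, columns are
#' alignment columns.
#'
#' @inheritParams read_fasta
#' @return Character matrix (rows named by sequence id).
#' @export
read_alignment_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  seqs <- read_fasta(path, type = if (type == "DNA") "DNA" else "AA")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("alignment rows have unequal lengths (",
         paste(range(lens), collapse = "-"), ")")
  do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}

#' Read/write an expression-style numeric matrix as TSV
#'
#' Rows are genes/transcripts (first column holds row ids), columns are
#' tissues or conditions.
#'
#' @param path File path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tab[[1]]))
    stop("duplicate row ids in ", path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  if (any(!is.finite(m)))
    stop("non-finite values in ", path)
  m
}

#' @rdname read_matrix_tsv
#' @param m Numeric matrix with dimnames.
#' @param id_column Name for the row-id column.
#' @export
write_matrix_tsv <- function(m, path, id_column = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write/read a Newick tree
#'
#' Thin wrappers over ape; support values are carried as internal node
#' labels.
#'
#' @param tree An `ape::phylo` object.
#' @param path File path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a genotype panel as a minimal VCF
#'
#' Emits a VCF 4.2 file with one diploid genotype column per line;
#' dosages 0/1/2 become 0/0, 0/1, 1/1 and missing becomes ./. . Indel
#' markers are written with REF/ALT presence/absence alleles.
#'
#' @param panel A [genotype_panel()].
#' @param path Output path.
#' @export
write_vcf_panel <- function(panel, path) {
  stopifnot(inherits(panel, "zf_panel"))
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=zfatlas",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", panel$lines),
                     collapse = "\t")), con)
  m <- panel$markers
  for (i in seq_len(nrow(m))) {
    calls <- panel$calls[i, ]
    gts <- ifelse(is.na(calls), "./.", gt[calls + 1L])
    ref <- if (m$type[i] == "Indel") "AT" else "A"
    alt <- if (m$type[i] == "Indel") "A" else "G"
    writeLines(paste(c(m$chrom[i], m$pos[i], m$marker_id[i], ref, alt,
                       ".", "PASS",
                       paste0("TYPE=", m$type[i]), "GT", gts),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF into a genotype panel
#'
#' Biallelic sites only; multiallelic records are rejected with a
#' diagnostic (the documented default policy). Genotypes are coded as
#' 0/1/2 alternate-allele dosage with `NA` for missing; marker type is
#' SNP for single-base REF and ALT, Indel otherwise.
#'
#' @param path VCF path.
#' @return A [genotype_panel()].
#' @export
read_vcf_panel <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt, fixed = TRUE)))
    stop("multiallelic VCF records are not supported: ",
         paste(utils::head(vcfR::getID(v)[grepl(",", alt)], 3),
               collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- apply(gt, 2, function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    ifelse(is.na(g) | g == "./.", NA_integer_,
           vapply(strsplit(g, "/", fixed = TRUE),
                  function(al) sum(al == "1"), integer(1)))
  })
  dosage <- matrix(as.integer(dosage), nrow = nrow(gt),
                   dimnames = dimnames(gt))
  ref <- vcfR::getREF(v)
  markers <- data.frame(
    marker_id = vcfR::getID(v),
    chrom = vcfR::getCHROM(v),
    pos = as.integer(vcfR::getPOS(v)),
    type = ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP", "Indel"),
    stringsAsFactors = FALSE)
  genotype_panel(markers, colnames(dosage), dosage)
}

#' Read a HapMap-style genotype table
#'
#' Expects the conventional 11 metadata columns (`rs#`, `alleles`,
#' `chrom`, `pos`, ...) followed by one column per line with two-letter
#' diploid genotype calls (e.g. `AA`, `AG`; `NN` missing). Calls are
#' coded as 0/1/2 dosage of the second allele listed in `alleles`.
#'
#' @param path HapMap TSV path.
#' @return A [genotype_panel()].
#' @export
read_hapmap <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 12)
    stop("HapMap file must have 11 metadata columns plus genotypes")
  alleles <- strsplit(tab[[2]], "/", fixed = TRUE)
  if (any(lengths(alleles) != 2))
    stop("malformed alleles column at row ",
         which(lengths(alleles) != 2)[1])
  geno <- as.matrix(tab[, 12:ncol(tab), drop = FALSE])
  alt <- vapply(alleles, `[`, character(1), 2)
  dosage <- matrix(NA_integer_, nrow(geno), ncol(geno),
                   dimnames = list(NULL, colnames(geno)))
  for (i in seq_len(nrow(geno))) {
    g <- toupper(geno[i, ])
    known <- !is.na(g) & nchar(g) == 2 & !g %in% c("NN", "--")
    counts <- vapply(strsplit(g, "", fixed = TRUE),
                     function(x) sum(x == alt[i]), integer(1))
    dosage[i, known] <- counts[known]
  }
  markers <- data.frame(
    marker_id = tab[[1]], chrom = as.character(tab[[3]]),
    pos = as.integer(tab[[4]]),
    type = ifelse(grepl("[+-]", tab[[2]]), "Indel", "SNP"),
    stringsAsFactors = FALSE)
  genotype_panel(markers, colnames(geno), dosage)
}

#' Write the finger table in export coordinates
#'
#' Emits the annotated finger table with the external convention:
#' 0-based half-open `start`/`end` (internal coordinates are 1-based
#' inclusive).
#'
#' @param profile A `zf_profile`.
#' @param path Output TSV path.
#' @export
write_finger_table <- function(profile, path) {
  f <- profile$fingers
  out <- data.frame(protein_id = f$protein_id, ordinal = f$ordinal,
                    start = f$start - 1L, end = f$end,
                    a = f$a, b = f$b, c = f$cc, label = f$label,
                    truncated = f$truncated,
                    recognition_window = f$recognition_window,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
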