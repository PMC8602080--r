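#' Spacing constraint for a C2H2 finger class
#'
#' A C2H2 zinc finger is written `CX(a)CX(b)HX(c)H`: two zinc-coordinating
#' cysteines separated by `a` residues, `b` residues between the second
#' cysteine and the first histidine, and `c` residues between the two
#' histidines. A spacing constraint records the allowed values of each
#' spacer; truncated finger classes (no terminal histidine) set
#' `h2_required = FALSE`.
#'
#' @param a_allowed,b_allowed,c_allowed Integer vectors of allowed spacer
#'   lengths (all values must be >= 1).
#' @param h2_required Logical; `FALSE` only for finger classes whose
#'   pattern lacks the terminal histidine.
#' @return An object of class `zf_spacing`.
#' @export
spacing_constraint <- function(a_allowed, b_allowed, c_allowed,
                               h2_required = TRUE) {
  a_allowed <- sort(unique(as.integer(a_allowed)))
  b_allowed <- sort(unique(as.integer(b_allowed)))
  c_allowed <- sort(unique(as.integer(c_allowed)))
  stopifnot(length(a_allowed) > 0, length(b_allowed) > 0,
            all(a_allowed >= 1), all(b_allowed >= 1),
            all(c_allowed >= 1), is.logical(h2_required))
  structure(
    list(a_allowed = a_allowed, b_allowed = b_allowed,
         c_allowed = c_allowed, h2_required = isTRUE(h2_required)),
    class = "zf_spacing"
  )
}

# Parse a printed spacing string such as "CX(2)CX(11,12)HX(2,3,4)H" or,
# for truncated classes, "CX(2)CX(12)HX(2)" (no terminal H).
parse_spacing <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1)
  s <- gsub("[[:space:]]", "", spec)
  m <- regmatches(s, regexec(
    "^CX\\(([0-9,]+)\\)CX\\(([0-9,]+)\\)HX\\(([0-9,]+)\\)(H?)$", s))[[1]]
  if (length(m) == 0)
    stop("malformed spacing specification: '", spec, "'")
  nums <- function(x) as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
  spacing_constraint(nums(m[2]), nums(m[3]), nums(m[4]),
                     h2_required = m[5] == "H")
}

#' Load a finger taxonomy
#'
#' Reads a taxonomy table (tab-separated: `class`, `label`, `motif`,
#' `spacing`, optional `reference_count`) describing the finger classes in
#' precedence order: the Q-type (conserved QALGGH recognition motif), its
#' degenerate M-type variants, the Z-type classes carrying other conserved
#' finger-plus-flank motifs, and the motif-free C-type fallback. The file
#' is data, not hard-coded truth: rows may be edited, added or removed.
#'
#' Wildcards (`_`) in a motif match any single residue by default
#' (`wildcard = "any"`); `wildcard = "omission"` instead deletes them so
#' the motif matches the remaining literal residues run together. The
#' any-one-residue reading is the default because it keeps each motif's
#' internal histidines on the spacing its own row prescribes (see the
#' methods vignette).
#'
#' @param path Path to the taxonomy TSV; defaults to the table shipped
#'   with the package.
#' @param wildcard Wildcard semantics, `"any"` (default) or `"omission"`.
#' @param flank_length Residues added on each side of the finger span when
#'   searching for Z-class motifs, which extend into the flanking regions.
#' @return A `zf_taxonomy` object: a data frame with one row per class in
#'   precedence order and the per-row spacing constraints, plus the scan
#'   grammar implied by the union of all rows (see [taxonomy_grammar()]).
#' @export
zf_taxonomy <- function(path = system.file("extdata", "zf_taxonomy.tsv",
                                           package = "zfatlas"),
                        wildcard = c("any", "omission"),
                        flank_length = 6L) {
  wildcard <- match.arg(wildcard)
  stopifnot(file.exists(path), flank_length >= 0)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = NULL)
  required <- c("class", "label", "motif", "spacing")
  if (!all(required %in% names(tab)))
    stop("taxonomy file must have columns: ",
         paste(required, collapse = ", "))
  if (anyDuplicated(tab$label))
    stop("duplicate taxonomy labels: ",
         paste(unique(tab$label[duplicated(tab$label)]), collapse = ", "))
  fallback <- tab$motif == "" | is.na(tab$motif)
  if (sum(fallback) != 1)
    stop("taxonomy must contain exactly one motif-free fallback class")
  if (which(fallback) != nrow(tab))
    stop("the fallback class must be the last (lowest-precedence) row")
  tab$motif[fallback] <- ""
  tab$spacing_parsed <- lapply(tab$spacing, parse_spacing)
  tab$h2_required <- vapply(tab$spacing_parsed, `[[`, logical(1),
                            "h2_required")
  structure(tab, class = c("zf_taxonomy", "data.frame"),
            wildcard = wildcard, flank_length = as.integer(flank_length))
}

#' Scan grammar implied by a taxonomy
#'
#' The default detection grammar is the union of every spacing observed in
#' the taxonomy: a finger candidate is any `C X(a) C X(b) H [X(c) H]` with
#' `a`, `b`, `c` in the unions of the per-class allowed sets. With the
#' shipped table this is a in \{1,2,3,4\}, b in \{10..17, 20\},
#' c in \{1..8\}.
#'
#' @param taxonomy A [zf_taxonomy()] object.
#' @return A `zf_spacing` grammar.
#' @export
taxonomy_grammar <- function(taxonomy = zf_taxonomy()) {
  stopifnot(inherits(taxonomy, "zf_taxonomy"))
  sp <- taxonomy$spacing_parsed
  spacing_constraint(
    sort(unique(unlist(lapply(sp, `[[`, "a_allowed")))),
    sort(unique(unlist(lapply(sp, `[[`, "b_allowed")))),
    sort(unique(unlist(lapply(sp[vapply(sp, `[[`, logical(1),
                                        "h2_required")],
                              `[[`, "c_allowed"))))
  )
}

# Turn a motif string into a regular expression (or literal for omission
# semantics). Returns "" for the fallback class.
motif_pattern <- function(motif, wildcard = "any") {
  if (motif == "") return("")
  if (!grepl("^[A-Z_]+$", motif))
    stop("motif may only contain residue letters and '_': ", motif)
  if (wildcard == "omission") gsub("_", "", motif, fixed = TRUE)
  else gsub("_", ".", motif, fixed = TRUE)
}

motif_matches <- function(window, motif, wildcard = "any") {
  pat <- motif_pattern(motif, wildcard)
  if (pat == "") return(TRUE)
  grepl(pat, window, fixed = wildcard == "omission")
}

#' @export
print.zf_taxonomy <- function(x, ...) {
  cat(sprintf("zf_taxonomy: %d classes (%s wildcard, flank %d)\n",
              nrow(x), attr(x, "wildcard"), attr(x, "flank_length")))
  print.data.frame(x[, c("class", "label", "motif", "spacing")],
                   row.names = FALSE)
  invisible(x)
}
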