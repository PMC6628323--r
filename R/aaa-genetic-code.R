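# Standard nuclear genetic code and the synonymous-family structure shared
# by every statistic in the package.  The code is fixed: anelloviruses such
# as TTSuV are standard-code viruses, so no translation-table option is
# offered.

.BASES <- c("A", "C", "G", "T")

# 64 codons ordered so that codon index = 16*b1 + 4*b2 + b3 (+1), with
# A=0, C=1, G=2, T=3.  count_codons() relies on this ordering.
.CODONS <- local({
  g <- expand.grid(b3 = .BASES, b2 = .BASES, b1 = .BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
})

.AA <- unname(Biostrings::GENETIC_CODE[.CODONS])

.STOP_CODONS <- .CODONS[.AA == "*"]

.GENETIC_CODE_OBJ <- local({
  # Families: synonymous codon sets, excluding Met (ATG only), Trp (TGG
  # only) and the three stop codons -> 18 families over 59 sense codons.
  fam_aa <- sort(setdiff(unique(.AA), c("*", "M", "W")))
  families <- lapply(fam_aa, function(a) .CODONS[.AA == a])
  names(families) <- fam_aa
  degeneracy <- vapply(families, length, integer(1))
  sense <- unlist(families, use.names = FALSE)
  family_of <- rep(names(families), degeneracy)
  names(family_of) <- sense

  structure(list(
    codons = .CODONS,
    amino_acid = stats::setNames(.AA, .CODONS),
    stop_codons = .STOP_CODONS,
    single_codon_aa = c(M = "ATG", W = "TGG"),
    families = families,
    family_of = family_of,
    degeneracy = degeneracy,
    degeneracy_classes = split(names(families), degeneracy),
    sense_codons = sense
  ), class = "cub_genetic_code")
})

# Precomputed lookups used by the fast counting/composition paths.
.SENSE_IDX <- match(.GENETIC_CODE_OBJ$sense_codons, .CODONS)
.THIRD_BASE <- substr(.CODONS, 3, 3)
.FIRST_GC <- substr(.CODONS, 1, 1) %in% c("G", "C")
.SECOND_GC <- substr(.CODONS, 2, 2) %in% c("G", "C")
.THIRD_GC <- .THIRD_BASE %in% c("G", "C")
# number of occurrences of each base within each codon (64 x 4)
.CODON_BASE_COUNT <- local({
  m <- sapply(.BASES, function(b) {
    vapply(strsplit(.CODONS, ""), function(x) sum(x == b), numeric(1))
  })
  rownames(m) <- .CODONS
  m
})

#' The standard genetic code and its synonymous-family structure
#'
#' Returns the codon table used throughout the package: the standard
#' nuclear genetic code with Met, Trp, and the three stop codons excluded
#' from the synonymous machinery, leaving 59 sense codons distributed over
#' 18 synonymous families (nine 2-fold, one 3-fold, five 4-fold, three
#' 6-fold).
#'
#' @return An object of class `cub_genetic_code`: a list with elements
#'   `codons` (all 64), `amino_acid` (named one-letter translation),
#'   `stop_codons`, `families` (named list of 18 synonymous families),
#'   `degeneracy` (family sizes), `degeneracy_classes` (families grouped by
#'   2/3/4/6-fold degeneracy), and `sense_codons` (the 59 codons in family
#'   order).
#' @export
#' @examples
#' code <- genetic_code()
#' length(code$sense_codons)   # 59
#' lengths(code$degeneracy_classes)
genetic_code <- function() .GENETIC_CODE_OBJ

#' @export
print.cub_genetic_code <- function(x, ...) {
  cat("Standard genetic code:", length(x$sense_codons),
      "sense codons in", length(x$families), "synonymous families\n")
  cls <- lengths(x$degeneracy_classes)
  cat("Degeneracy classes:",
      paste(sprintf("%s-fold x %d", names(cls), cls), collapse = ", "), "\n")
  invisible(x)
}
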