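# Wright's effective number of codons and the ENC-plot machinery.
#
#   ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6
#
# where Fk is the average, over synonymous families of degeneracy k, of the
# family homozygosity F = (n*S - 1)/(n - 1) with S = sum_i (n_i/n)^2.
# Families with fewer than 2 codons observed are excluded from their class
# average.  If the single 3-fold family (Ile) is not computable, F3 is
# imputed as the mean of F2 and F4 (Wright's fallback); any other missing
# class makes ENC incomputable.  Sampling noise can push ENC above the
# theoretical maximum of 61; such values are capped at 61 and flagged with
# a "capped" attribute.

.family_F <- function(g) {
  n <- sum(g)
  if (n < 2) return(NA_real_)
  S <- sum((g / n)^2)
  (n * S - 1) / (n - 1)
}

#' Effective number of codons (ENC)
#'
#' @param counts a `cub_codon_counts` (or anything [count_codons()]
#'   accepts).
#' @param code genetic code.
#' @return ENC value in (20, 61]; values capped at 61 carry attribute
#'   `capped = TRUE`.
#' @export
#' @examples
#' # maximal bias: one codon per family -> ENC = 2 + 9 + 1 + 5 + 3 = 20
enc <- function(counts, code = genetic_code()) {
  if (!inherits(counts, "cub_codon_counts")) counts <- count_codons(counts)
  Fv <- vapply(code$families, function(cods)
    .family_F(as.numeric(counts[cods])), numeric(1))
  deg <- code$degeneracy
  Fbar <- vapply(c("2", "4", "6"), function(k) {
    f <- Fv[deg == as.integer(k)]
    f <- f[!is.na(f)]
    if (length(f) == 0L) NA_real_ else mean(f)
  }, numeric(1))
  if (anyNA(Fbar))
    stop("ENC incomputable: no family with >= 2 codons in the ",
         paste(c("2", "4", "6")[is.na(Fbar)], collapse = "/"),
         "-fold degeneracy class")
  f3 <- Fv[deg == 3L]
  F3 <- if (all(is.na(f3))) mean(Fbar[c("2", "4")]) else mean(f3, na.rm = TRUE)
  value <- 2 + 9 / Fbar[["2"]] + 1 / F3 + 5 / Fbar[["4"]] + 3 / Fbar[["6"]]
  if (!is.finite(value) || value > 61) structure(61, capped = TRUE)
  else unname(value)
}

#' Expected ENC under mutation pressure alone
#'
#' Wright's standard curve \eqn{ENC = 2 + s + 29 / (s^2 + (1-s)^2)}
#' evaluated at a silent-site GC content `s` (GC3s).  The curve peaks at
#' 60.5 when s = 0.5; genes lying on it are consistent with codon choice
#' driven purely by mutational GC pressure.
#'
#' @param s GC3s fraction(s) in \[0, 1\].
#' @return expected ENC, vectorized over `s`.
#' @export
#' @examples
#' enc_expected(0.5)  # 60.5
enc_expected <- function(s) {
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1))
    stop("GC3s must lie in [0, 1]")
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Per-sequence ENC records
#'
#' Computes, for each sequence, the (ENC, GC3s, GC12) triple plus the
#' expected ENC at its GC3s and whether it falls below the curve -- the
#' rows of an ENC-plot.
#'
#' @param seqs list of `cub_cds`.
#' @param code genetic code.
#' @return data.frame with columns id, enc, gc3s, gc12, enc_expected,
#'   below_curve.
#' @export
enc_batch <- function(seqs, code = genetic_code()) {
  rows <- lapply(seqs, function(s) {
    counts <- count_codons(s)
    comp <- composition_summary(counts, code)
    e <- tryCatch(as.numeric(enc(counts, code)), error = function(err) {
      warning("ENC not computable for '", s$id, "': ",
              conditionMessage(err), call. = FALSE)
      NA_real_
    })
    data.frame(id = s$id, enc = e, gc3s = comp$GC3s, gc12 = comp$GC12,
               enc_expected = enc_expected(comp$GC3s),
               below_curve = e < enc_expected(comp$GC3s),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), enc = numeric(), gc3s = numeric(),
               gc12 = numeric(), enc_expected = numeric(),
               below_curve = logical())
  rownames(out) <- NULL
  out
}

#' ENC-plot table
#'
#' Normalizes a set of ENC records into plot-ready rows, recomputing the
#' expected curve and the below-curve flag from the stored GC3s.
#'
#' @param records data.frame with at least columns `enc` and `gc3s` (e.g.
#'   from [enc_batch()]).
#' @return data.frame (id, gc3s, enc, enc_expected, below_curve).
#' @export
enc_plot_data <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(id = character(), gc3s = numeric(), enc = numeric(),
                      enc_expected = numeric(), below_curve = logical()))
  stopifnot(all(c("enc", "gc3s") %in% names(records)))
  exp_enc <- enc_expected(records$gc3s)
  data.frame(id = if ("id" %in% names(records)) records$id
             else as.character(seq_len(nrow(records))),
             gc3s = records$gc3s, enc = records$enc,
             enc_expected = exp_enc,
             below_curve = records$enc < exp_enc,
             stringsAsFactors = FALSE)
}
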