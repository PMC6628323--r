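# Nucleotide and codon-position composition statistics feeding the
# ENC-plot and the neutrality regression.
#
# Conventions follow the silent-site definitions of CodonW: A3s/T3s/G3s/C3s
# and GC3s are computed over third positions of synonymous codons only
# (Met, Trp and stops excluded); GC1/GC2 over the first/second positions of
# that same codon set; GC12 = (GC1 + GC2)/2.  GC fractions are kept in
# [0, 1] internally so the ENC expected curve can consume GC3s directly;
# whole-sequence base contents are reported as percentages.

#' Composition summary of a coding sequence
#'
#' @param seq a `cub_cds`, an in-frame nucleotide string, or a
#'   `cub_codon_counts` table.
#' @param code genetic code, see [genetic_code()].
#' @return Object of class `cub_composition`: a list with whole-CDS base
#'   percentages (`pct_A`, `pct_T`, `pct_G`, `pct_C`, `AT_total`,
#'   `GC_total`), silent-site third-position percentages (`A3s`, `T3s`,
#'   `G3s`, `C3s`), and GC fractions by codon position (`GC1`, `GC2`,
#'   `GC3s`, `GC12`).
#' @export
#' @examples
#' composition_summary("GAAGAG")$GC3s  # 0.5: one A, one G at silent sites
composition_summary <- function(seq, code = genetic_code()) {
  counts <- if (inherits(seq, "cub_codon_counts")) seq else count_codons(seq)
  cc <- as.numeric(counts)
  tot_nt <- 3 * sum(cc)
  if (tot_nt == 0)
    stop("composition undefined: no unambiguous codons in '",
         attr(counts, "id") %||% "?", "'")
  base_tot <- as.numeric(cc %*% .CODON_BASE_COUNT)
  names(base_tot) <- .BASES
  pct <- 100 * base_tot / tot_nt

  s <- cc[.SENSE_IDX]
  n_syn <- sum(s)
  if (n_syn == 0)
    stop("composition undefined: no synonymous codons in '",
         attr(counts, "id") %||% "?", "'")
  third <- .THIRD_BASE[.SENSE_IDX]
  third_pct <- vapply(.BASES, function(b) 100 * sum(s[third == b]) / n_syn,
                      numeric(1))
  gc1 <- sum(s[.FIRST_GC[.SENSE_IDX]]) / n_syn
  gc2 <- sum(s[.SECOND_GC[.SENSE_IDX]]) / n_syn
  gc3s <- sum(s[.THIRD_GC[.SENSE_IDX]]) / n_syn

  structure(list(
    id = attr(counts, "id") %||% "?",
    pct_A = unname(pct["A"]), pct_T = unname(pct["T"]),
    pct_G = unname(pct["G"]), pct_C = unname(pct["C"]),
    A3s = unname(third_pct["A"]), T3s = unname(third_pct["T"]),
    G3s = unname(third_pct["G"]), C3s = unname(third_pct["C"]),
    GC1 = gc1, GC2 = gc2, GC3s = gc3s, GC12 = (gc1 + gc2) / 2,
    AT_total = unname((pct["A"] + pct["T"]) / 100),
    GC_total = unname((pct["G"] + pct["C"]) / 100),
    n_synonymous = n_syn
  ), class = "cub_composition")
}

#' @export
print.cub_composition <- function(x, ...) {
  cat(sprintf("<cub_composition> %s\n", x$id))
  cat(sprintf("  A%% %.2f  T%% %.2f  G%% %.2f  C%% %.2f\n",
              x$pct_A, x$pct_T, x$pct_G, x$pct_C))
  cat(sprintf("  GC1 %.4f  GC2 %.4f  GC3s %.4f  GC12 %.4f\n",
              x$GC1, x$GC2, x$GC3s, x$GC12))
  invisible(x)
}

#' Batch composition table
#'
#' Applies [composition_summary()] to each sequence, preserving input
#' order.  Sequences that fail (for example no synonymous codons) become
#' flagged rows rather than errors.
#'
#' @param seqs list of `cub_cds`.
#' @inheritParams composition_summary
#' @return data.frame, one row per input sequence, with `status`/`reason`
#'   columns flagging failures.
#' @export
composition_batch <- function(seqs, code = genetic_code()) {
  fields <- c("pct_A", "pct_T", "pct_G", "pct_C", "A3s", "T3s", "G3s", "C3s",
              "GC1", "GC2", "GC12", "GC3s")
  rows <- lapply(seqs, function(s) {
    res <- tryCatch(composition_summary(s, code), error = function(e) e)
    if (inherits(res, "error")) {
      row <- as.data.frame(as.list(stats::setNames(
        rep(NA_real_, length(fields)), fields)))
      cbind(data.frame(id = if (inherits(s, "cub_cds")) s$id else "?",
                       stringsAsFactors = FALSE),
            row, data.frame(status = "error",
                            reason = conditionMessage(res),
                            stringsAsFactors = FALSE))
    } else {
      cbind(data.frame(id = res$id, stringsAsFactors = FALSE),
            as.data.frame(res[fields]),
            data.frame(status = "ok", reason = "", stringsAsFactors = FALSE))
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(data.frame(id = character()),
          as.data.frame(sapply(fields, function(f) numeric(0),
                               simplify = FALSE)),
          data.frame(status = character(), reason = character()))
  rownames(out) <- NULL
  out
}
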