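# Relative synonymous codon usage: RSCU_i = g_i / mean(g over the family),
# i.e. the observed count divided by the count expected under equal usage
# within the family.  Within each observed family the 2/3/4/6 values sum to
# the family size.  Zero-count codons get RSCU 0 (no pseudo-counts);
# families with zero total are marked unobserved rather than imputed.

.new_rscu <- function(values, source, unobserved = character()) {
  structure(values, source = source, unobserved = unobserved,
            class = "cub_rscu")
}

#' RSCU profile from codon counts
#'
#' @param counts a `cub_codon_counts` table (or anything [count_codons()]
#'   accepts).
#' @param code genetic code.
#' @param source provenance label stored on the profile.
#' @return Object of class `cub_rscu`: a named numeric vector over the 59
#'   sense codons in family order, with attributes `source` and
#'   `unobserved` (amino acids whose family had zero counts; their codons
#'   are `NA`).
#' @export
#' @examples
#' p <- rscu_from_counts(count_codons("GAAGAAGAAGAG"))
#' p[c("GAA", "GAG")]  # 1.5, 0.5
rscu_from_counts <- function(counts, code = genetic_code(),
                             source = "single_sequence") {
  if (!inherits(counts, "cub_codon_counts")) counts <- count_codons(counts)
  vals <- stats::setNames(rep(NA_real_, length(code$sense_codons)),
                          code$sense_codons)
  unobserved <- character()
  for (aa in names(code$families)) {
    cods <- code$families[[aa]]
    g <- as.numeric(counts[cods])
    tot <- sum(g)
    if (tot == 0) {
      unobserved <- c(unobserved, aa)
      next
    }
    vals[cods] <- g * length(cods) / tot
  }
  if (length(unobserved) == length(code$families))
    stop("cannot compute RSCU: no synonymous codons observed")
  .new_rscu(vals, source = source, unobserved = unobserved)
}

#' RSCU profile from an external table of values
#'
#' Wraps a pre-computed 59-codon RSCU vector (for example a published table
#' or a host reference) as a `cub_rscu`.  Codon names may use the RNA
#' alphabet; they are normalized to DNA.
#'
#' @param values named numeric vector covering all 59 sense codons.
#' @param source provenance label, default `"external_table"`.
#' @export
rscu_profile <- function(values, source = "external_table") {
  nm <- chartr("U", "T", toupper(names(values)))
  code <- genetic_code()
  missing <- setdiff(code$sense_codons, nm)
  if (length(missing))
    stop("RSCU table incomplete; missing codons: ",
         paste(missing, collapse = ", "))
  v <- as.numeric(values)[match(code$sense_codons, nm)]
  if (any(is.na(v)) || any(v < 0))
    stop("RSCU values must be non-negative and non-missing")
  .new_rscu(stats::setNames(v, code$sense_codons), source = source)
}

#' @export
print.cub_rscu <- function(x, ...) {
  cat(sprintf("<cub_rscu> source=%s, %d codons", attr(x, "source"), length(x)))
  un <- attr(x, "unobserved")
  if (length(un)) cat(", unobserved families:", paste(un, collapse = ","))
  cat("\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Per-sequence, pooled and mean RSCU
#'
#' `rscu_batch()` computes one profile per sequence; `pooled_rscu()` sums
#' counts over the set first; `mean_rscu()` averages per-sequence (or any)
#' profiles codon-wise.  Group-level codon usage can legitimately be
#' summarized either way, so both are provided and labelled via the
#' `source` attribute.
#'
#' @param seqs list of `cub_cds`.
#' @param profiles list of `cub_rscu` sharing the family structure.
#' @param code genetic code.
#' @return `rscu_batch()`: named list of `cub_rscu`; the others: one
#'   `cub_rscu`.
#' @export
rscu_batch <- function(seqs, code = genetic_code()) {
  stats::setNames(lapply(seqs, rscu_from_counts, code = code),
                  vapply(seqs, `[[`, "", "id"))
}

#' @rdname rscu_batch
#' @export
pooled_rscu <- function(seqs, code = genetic_code()) {
  rscu_from_counts(pool_codon_counts(seqs), code = code,
                   source = "pooled_counts")
}

#' @rdname rscu_batch
#' @export
mean_rscu <- function(profiles) {
  if (length(profiles) == 0L) stop("mean_rscu: empty profile list")
  m <- do.call(rbind, lapply(profiles, unclass))
  .new_rscu(colMeans(m), source = "mean_of_sequences",
            unobserved = sort(unique(unlist(
              lapply(profiles, attr, "unobserved")))))
}

#' Preferred (highest-RSCU) codon of each synonymous family
#'
#' Ties are reported: the scalar `codon` column takes the lexicographically
#' first tied codon and the `tied` column lists all of them.
#'
#' @param profile a `cub_rscu`.
#' @param code genetic code.
#' @return data.frame with columns family, codon, rscu, tie, tied.
#' @export
preferred_codons <- function(profile, code = genetic_code()) {
  rows <- lapply(names(code$families), function(aa) {
    cods <- code$families[[aa]]
    v <- unclass(profile)[cods]
    if (anyNA(v))
      return(data.frame(family = aa, codon = NA_character_, rscu = NA_real_,
                        tie = NA, tied = NA_character_,
                        stringsAsFactors = FALSE))
    mx <- max(v)
    top <- sort(cods[v == mx])
    data.frame(family = aa, codon = top[1L], rscu = mx,
               tie = length(top) > 1L, tied = paste(top, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Third-base census of preferred codons
#'
#' Counts how many of the 18 families prefer an A-, C-, G- or T-ended
#' codon.  Errors if any family is unobserved rather than imputing.
#'
#' @inheritParams preferred_codons
#' @return Named integer vector `c(A=, C=, G=, T=)` summing to 18.
#' @export
ending_census <- function(profile, code = genetic_code()) {
  pref <- preferred_codons(profile, code)
  if (anyNA(pref$codon))
    stop("ending census impossible: unobserved families ",
         paste(pref$family[is.na(pref$codon)], collapse = ", "))
  if (any(pref$tie))
    warning("argmax ties in families ",
            paste(pref$family[pref$tie], collapse = ", "),
            "; lexicographically first codon used")
  ends <- substr(pref$codon, 3, 3)
  vapply(.BASES, function(b) sum(ends == b), integer(1))
}

#' Coincidence/antagonism comparison of virus and host preferred codons
#'
#' For each of the 18 synonymous families, the family is a *coincidence*
#' when virus and host share the same highest-RSCU codon, otherwise an
#' *antagonism*.  The virus profile's preferred-codon ending census is
#' attached.
#'
#' @param virus,host complete `cub_rscu` profiles.
#' @param code genetic code.
#' @return Object of class `cub_coincidence`: list with `per_family`
#'   data.frame, counts `n_coincidence` + `n_antagonism` = 18, and the
#'   virus `ending_census`.
#' @export
coincidence_analysis <- function(virus, host, code = genetic_code()) {
  pv <- preferred_codons(virus, code)
  ph <- preferred_codons(host, code)
  if (anyNA(pv$codon) || anyNA(ph$codon))
    stop("coincidence analysis requires both profiles complete over all families")
  per <- data.frame(
    family = pv$family,
    virus_codon = pv$codon, host_codon = ph$codon,
    verdict = ifelse(pv$codon == ph$codon, "coincidence", "antagonism"),
    stringsAsFactors = FALSE)
  structure(list(
    per_family = per,
    n_coincidence = sum(per$verdict == "coincidence"),
    n_antagonism = sum(per$verdict == "antagonism"),
    ending_census = ending_census(virus, code)
  ), class = "cub_coincidence")
}

#' @export
print.cub_coincidence <- function(x, ...) {
  cat(sprintf("<cub_coincidence> %d coincidence / %d antagonism\n",
              x$n_coincidence, x$n_antagonism))
  cat("Virus preferred-codon endings:",
      paste(names(x$ending_census), x$ending_census, sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

#' Representation calls from RSCU values
#'
#' Thresholds follow the standard convention: RSCU of at least `over`
#' (default 1.6) is over-represented and at most `under` (default 0.6)
#' under-represented; between those bounds, values above 1 are positive
#' usage, below 1 negative, exactly 1 neutral.  The inclusive `over`
#' boundary matters in practice: published tables list codons at exactly
#' 1.60 among the over-represented set.
#'
#' @param profile a `cub_rscu`.
#' @param over,under thresholds.
#' @return Named character vector over the 59 codons; `NA` for codons of
#'   unobserved families.
#' @export
representation_calls <- function(profile, over = 1.6, under = 0.6) {
  v <- unclass(profile)
  out <- rep(NA_character_, length(v))
  names(out) <- names(v)
  ok <- !is.na(v)
  out[ok & v >= over] <- "over"
  out[ok & v <= under] <- "under"
  mid <- ok & is.na(out)
  out[mid & v > 1] <- "positive"
  out[mid & v < 1] <- "negative"
  out[mid & v == 1] <- "neutral"
  out
}
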