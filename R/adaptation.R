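# Host-adaptation statistics: CAI (Sharp & Li geometric-mean form with
# relative adaptiveness w = RSCU / family-max RSCU), RCDI (Puigbo's average
# ratio of within-amino-acid codon frequencies, gene vs host), and the SiD
# cosine distance between 59-dimensional RSCU vectors.
#
# Zero-usage smoothing: a host codon with zero frequency/RSCU would give
# w = 0 and an infinite CAI/RCDI contribution on any gene that uses it.
# Such entries are floored at half the smallest positive value within the
# same family (the analogue of granting half an observation) with a loud
# warning; a family that is zero throughout is an error.

.smooth_zero_family <- function(v, aa, what) {
  if (all(v == 0))
    stop("host reference invalid: family ", aa, " has zero ", what,
         " throughout")
  if (any(v == 0)) {
    warning("host reference: zero ", what, " for codon(s) ",
            paste(names(v)[v == 0], collapse = ","),
            " floored at half the family minimum", call. = FALSE)
    v[v == 0] <- min(v[v > 0]) / 2
  }
  v
}

#' Build a host codon-usage reference
#'
#' Derives, from a host RSCU profile (and optionally per-thousand codon
#' frequencies), the relative-adaptiveness weights `w = RSCU / max family
#' RSCU` used by CAI and the within-amino-acid codon frequencies `cif`
#' used by RCDI.
#'
#' @param rscu a `cub_rscu` (or named numeric vector accepted by
#'   [rscu_profile()]).
#' @param name reference name.
#' @param codon_freq optional named per-thousand frequencies over the 64
#'   codons (kept for round-tripping Kazusa tables; not used by the
#'   statistics, which work family-internally).
#' @return Object of class `cub_host`: list(name, rscu, w, cif,
#'   codon_freq).
#' @export
#' @examples
#' h <- load_host_reference("sus_scrofa")
#' h$w["GAA"]  # 0.72 / 1.28 = 0.5625
host_reference <- function(rscu, name = "host", codon_freq = NULL) {
  if (!inherits(rscu, "cub_rscu")) rscu <- rscu_profile(rscu)
  code <- genetic_code()
  v <- unclass(rscu)
  if (anyNA(v))
    stop("host reference must cover all 59 sense codons")
  w <- cif <- v
  for (aa in names(code$families)) {
    cods <- code$families[[aa]]
    fam <- .smooth_zero_family(v[cods], aa, "RSCU")
    w[cods] <- fam / max(fam)
    cif[cods] <- fam / sum(fam)
  }
  structure(list(name = name, rscu = rscu, w = w, cif = cif,
                 codon_freq = codon_freq), class = "cub_host")
}

#' @export
print.cub_host <- function(x, ...) {
  cat(sprintf("<cub_host> %s: 59-codon reference (w in (0,1], max w = 1 per family)\n",
              x$name))
  invisible(x)
}

#' Load a host reference by name or from a file
#'
#' Accepts: the bundled reference names (`"sus_scrofa"`,
#' `"sus_scrofa_domestica"`); a Kazusa codon usage database text file
#' (`"UUU 17.6 (714298)"`-style triplets, with or without counts); or a
#' two-column codon/RSCU TSV.
#'
#' @param source reference name or file path.
#' @param name override the stored reference name.
#' @return a `cub_host`.
#' @export
load_host_reference <- function(source, name = NULL) {
  builtin <- c("sus_scrofa", "sus_scrofa_domestica")
  if (source %in% builtin) {
    prof <- builtin_rscu_profiles()[[source]]
    return(host_reference(prof, name = name %||% source))
  }
  if (!file.exists(source))
    stop("host reference not found: '", source,
         "' (not a bundled name, not a file)")
  txt <- readChar(source, file.size(source), useBytes = TRUE)
  if (grepl("\\(", txt)) {
    kz <- parse_kazusa(source)
    return(host_reference_from_freq(kz$freq, name = name %||% basename(source)))
  }
  tab <- utils::read.delim(source, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("codon", "rscu") %in% names(tab)))
    stop("RSCU table file must have columns 'codon' and 'rscu'")
  host_reference(stats::setNames(tab$rscu, tab$codon),
                 name = name %||% basename(source))
}

#' Host reference from codon frequencies
#'
#' Converts per-thousand (or any proportional) codon frequencies into an
#' RSCU-based reference: within each family, RSCU_i = freq_i * k / sum of
#' family frequencies.
#'
#' @param freq named numeric vector of codon frequencies (DNA or RNA codon
#'   names; at least the 59 sense codons).
#' @param name reference name.
#' @return a `cub_host`.
#' @export
host_reference_from_freq <- function(freq, name = "host") {
  nm <- chartr("U", "T", toupper(names(freq)))
  names(freq) <- nm
  code <- genetic_code()
  missing <- setdiff(code$sense_codons, nm)
  if (length(missing))
    stop("frequency table incomplete; missing codons: ",
         paste(missing, collapse = ", "))
  vals <- stats::setNames(rep(NA_real_, 59L), code$sense_codons)
  for (aa in names(code$families)) {
    cods <- code$families[[aa]]
    f <- .smooth_zero_family(as.numeric(freq[cods]), aa, "frequency")
    names(f) <- cods
    vals[cods] <- f * length(cods) / sum(f)
  }
  host_reference(rscu_profile(vals), name = name,
                 codon_freq = freq[intersect(genetic_code()$codons, nm)])
}

#' Parse a Kazusa codon usage database table
#'
#' Reads the plain-text format of the Codon Usage Database: whitespace- or
#' newline-separated fields of the form `UUU 17.6 (714298)` (the
#' parenthesized count is optional).
#'
#' @param path text file path.
#' @return list with `freq` (named per-thousand frequencies, DNA codon
#'   names) and `count` (named counts, `NA` when absent).
#' @export
parse_kazusa <- function(path) {
  txt <- readChar(path, file.size(path), useBytes = TRUE)
  m <- gregexpr("([ACGTUacgtu]{3})[[:space:]]+([0-9.]+)([[:space:]]*\\(\\s*([0-9]+)\\s*\\))?",
                txt, perl = TRUE)
  hits <- regmatches(txt, m)[[1L]]
  if (length(hits) == 0L) stop("no codon entries found in '", path, "'")
  codon <- chartr("U", "T", toupper(substr(hits, 1L, 3L)))
  rest <- trimws(substr(hits, 4L, nchar(hits)))
  freq <- as.numeric(sub("[[:space:]].*$|\\(.*$", "", rest))
  count <- ifelse(grepl("\\(", rest),
                  as.numeric(sub("^.*\\(\\s*([0-9]+)\\s*\\).*$", "\\1", rest)),
                  NA_real_)
  dup <- duplicated(codon)
  list(freq = stats::setNames(freq[!dup], codon[!dup]),
       count = stats::setNames(count[!dup], codon[!dup]))
}

#' Write a Kazusa-style codon usage table
#'
#' Emits one `UUU 17.6 (714298)` field per codon (RNA alphabet, counts
#' omitted when unknown) such that [parse_kazusa()] recovers the
#' frequencies exactly.
#'
#' @param freq named numeric frequencies (DNA or RNA codon names).
#' @param path output path.
#' @param count optional named counts.
#' @return `path`, invisibly.
#' @export
write_kazusa <- function(freq, path, count = NULL) {
  rna <- chartr("T", "U", toupper(names(freq)))
  fields <- vapply(seq_along(freq), function(i) {
    base <- paste(rna[i], format(freq[i], digits = 15, scientific = FALSE))
    cnt <- if (!is.null(count)) count[[names(freq)[i]]] else NA
    if (!is.na(cnt)) paste0(base, " (", format(cnt, scientific = FALSE), ")")
    else base
  }, character(1))
  writeLines(paste(fields, collapse = "  "), path)
  invisible(path)
}

.sense_counts <- function(counts) {
  if (!inherits(counts, "cub_codon_counts")) counts <- count_codons(counts)
  n <- as.numeric(counts)[.SENSE_IDX]
  names(n) <- .CODONS[.SENSE_IDX]
  n
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of the host relative-adaptiveness weights over every
#' synonymous codon occurrence of the gene (Met, Trp and stops excluded):
#' \eqn{CAI = \exp(\sum_i n_i \log w_i / \sum_i n_i)}.  1 means the gene
#' uses only host-optimal codons; lower values mean poorer adaptation to
#' the host.
#'
#' @param counts gene codon counts (`cub_codon_counts`, `cub_cds`, or
#'   string).
#' @param host a `cub_host`.
#' @return CAI in (0, 1].
#' @export
#' @examples
#' h <- load_host_reference("sus_scrofa")
#' cai("GAAGAG", h)  # sqrt(0.5625 * 1) = 0.75
cai <- function(counts, host) {
  stopifnot(inherits(host, "cub_host"))
  n <- .sense_counts(counts)
  N <- sum(n)
  if (N == 0) stop("CAI undefined: no synonymous codons")
  use <- n > 0
  exp(sum(n[use] * log(host$w[names(n)[use]])) / N)
}

#' Relative codon deoptimization index (RCDI)
#'
#' Average, over the gene's synonymous codons, of the ratio of
#' within-amino-acid codon frequencies in the gene versus the host:
#' \eqn{RCDI = \frac{1}{N}\sum_i \frac{CiF_{gene,i}}{CiF_{host,i}} n_i}.
#' A gene whose codon usage matches the host's gives exactly 1; larger
#' values indicate deoptimization relative to the host.
#'
#' @inheritParams cai
#' @return RCDI (positive; 1 = matched usage).
#' @export
rcdi <- function(counts, host) {
  stopifnot(inherits(host, "cub_host"))
  n <- .sense_counts(counts)
  N <- sum(n)
  if (N == 0) stop("RCDI undefined: no synonymous codons")
  code <- genetic_code()
  total <- 0
  for (aa in names(code$families)) {
    cods <- code$families[[aa]]
    fam_n <- n[cods]
    fam_tot <- sum(fam_n)
    if (fam_tot == 0) next
    cif_gene <- fam_n / fam_tot
    total <- total + sum(cif_gene / host$cif[cods] * fam_n)
  }
  total / N
}

#' Similarity index (SiD) between virus and host codon usage
#'
#' `R(A,B)` is the cosine similarity of the two 59-dimensional RSCU
#' vectors; the reported distance is `D(A,B) = (1 - R)/2`.  D = 0 means
#' identical codon usage; larger D is read as stronger host selective
#' influence shaping a divergent virus codon usage.  For non-negative RSCU
#' vectors R >= 0, so D cannot exceed 0.5.
#'
#' @param virus a `cub_rscu` (complete over the 59 codons).
#' @param host a `cub_rscu` or `cub_host`.
#' @return list with `R` and `D` (class `cub_sid`).
#' @export
#' @examples
#' p <- builtin_rscu_profiles()
#' sid(p$ttsuv1, p$sus_scrofa)$D  # ~0.094
sid <- function(virus, host) {
  if (inherits(host, "cub_host")) host <- host$rscu
  a <- unclass(virus); b <- unclass(host)
  if (anyNA(a) || anyNA(b))
    stop("SiD requires both profiles complete over the 59 sense codons")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("SiD undefined for a zero-norm RSCU vector")
  R <- sum(a * b) / (na * nb)
  structure(list(R = R, D = (1 - R) / 2), class = "cub_sid")
}

#' @export
print.cub_sid <- function(x, ...) {
  cat(sprintf("<cub_sid> R = %.4f, D = %.4f\n", x$R, x$D))
  invisible(x)
}

#' Per-sequence adaptation scores against one or more hosts
#'
#' @param seqs list of `cub_cds`.
#' @param hosts list of `cub_host` (or character names resolvable by
#'   [load_host_reference()]).
#' @return data.frame (id, host, cai, rcdi).
#' @export
adaptation_batch <- function(seqs, hosts) {
  if (is.character(hosts)) hosts <- lapply(hosts, load_host_reference)
  if (inherits(hosts, "cub_host")) hosts <- list(hosts)
  rows <- list()
  for (h in hosts) {
    for (s in seqs) {
      counts <- count_codons(s)
      rows[[length(rows) + 1L]] <- data.frame(
        id = s$id, host = h$name,
        cai = cai(counts, h), rcdi = rcdi(counts, h),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), host = character(),
               cai = numeric(), rcdi = numeric())
  rownames(out) <- NULL
  out
}
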