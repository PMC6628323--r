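# Reading, validating and codon-izing in-frame coding sequences.

.IUPAC_EXTRA <- "RYSWKMBDHVN"  # ambiguity codes tolerated in input

#' Construct a validated coding sequence
#'
#' Normalizes an input nucleotide string (case-insensitive, RNA `U`
#' converted to `T`), enforces the reading-frame and internal-stop
#' invariants, and splits it into codons.  IUPAC ambiguity codes are
#' accepted; any codon containing one is retained in the codon list but
#' excluded from every downstream count (see [count_codons()]).
#'
#' A trailing stop codon is accepted (complete ORFs end in one) and flagged;
#' a stop codon anywhere before the last position is a validation error.
#'
#' @param nucleotides single character string over the DNA/RNA alphabet.
#' @param id record identifier.
#' @param frame_policy `"strict"` errors when the length is not a multiple
#'   of 3; `"trim_trailing"` drops the 1-2 trailing bases instead.
#' @return An object of class `cub_cds` with fields `id`, `nucleotides`,
#'   `codons`, `n_codons`, `has_terminal_stop`, `n_ambiguous_codons`.
#' @export
#' @examples
#' s <- coding_sequence("ATGGAAGAA")
#' s$n_codons  # 3
coding_sequence <- function(nucleotides, id = "seq1",
                            frame_policy = c("strict", "trim_trailing")) {
  frame_policy <- match.arg(frame_policy)
  if (!is.character(nucleotides) || length(nucleotides) != 1L)
    stop("'nucleotides' must be a single character string")
  nt <- chartr("U", "T", toupper(gsub("[[:space:]]", "", nucleotides)))
  if (!nzchar(nt))
    stop("record '", id, "': empty sequence")
  if (grepl(sprintf("[^ACGT%s]", .IUPAC_EXTRA), nt))
    stop("record '", id, "': non-nucleotide characters in sequence ",
         "(gaps are not supported; supply ungapped CDS)")
  if (nchar(nt) %% 3L != 0L) {
    if (frame_policy == "strict")
      stop("record '", id, "': length ", nchar(nt),
           " is not a multiple of 3 (frame_policy = \"strict\")")
    nt <- substr(nt, 1L, nchar(nt) - nchar(nt) %% 3L)
    if (!nzchar(nt))
      stop("record '", id, "': no complete codon after trimming")
  }
  n <- nchar(nt) %/% 3L
  codons <- substring(nt, seq(1L, by = 3L, length.out = n),
                      seq(3L, by = 3L, length.out = n))
  internal <- codons[-n] %in% .STOP_CODONS
  if (any(internal))
    stop("record '", id, "': internal stop codon at codon position ",
         paste(which(internal), collapse = ", "))
  structure(list(
    id = id,
    nucleotides = nt,
    codons = codons,
    n_codons = n,
    has_terminal_stop = codons[n] %in% .STOP_CODONS,
    n_ambiguous_codons = sum(grepl("[^ACGT]", codons))
  ), class = "cub_cds")
}

#' @export
print.cub_cds <- function(x, ...) {
  cat(sprintf("<cub_cds> %s: %d nt, %d codons%s%s\n", x$id,
              nchar(x$nucleotides), x$n_codons,
              if (x$has_terminal_stop) ", terminal stop" else "",
              if (x$n_ambiguous_codons > 0)
                sprintf(", %d ambiguous codons excluded from counts",
                        x$n_ambiguous_codons) else ""))
  invisible(x)
}

#' Read coding sequences from a FASTA file
#'
#' Parses a (wrapped or unwrapped, multi-record) FASTA file and validates
#' every record with [coding_sequence()].
#'
#' @param path path to a FASTA file.
#' @param frame_policy see [coding_sequence()].
#' @param on_invalid `"error"` (default) stops naming every failing record;
#'   `"skip"` keeps the valid records, attaches the failure table as
#'   attribute `"failures"` and warns.  Records are never silently dropped.
#' @return list of `cub_cds`, named by record id (text before the first
#'   whitespace of each header).
#' @export
read_fasta <- function(path, frame_policy = c("strict", "trim_trailing"),
                       on_invalid = c("error", "skip")) {
  frame_policy <- match.arg(frame_policy)
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse failure for '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA input: ", path)
  ids <- sub("\\s.*$", "", names(set))
  out <- list()
  fails <- list()
  for (i in seq_along(set)) {
    res <- tryCatch(
      coding_sequence(as.character(set[[i]]), id = ids[i],
                      frame_policy = frame_policy),
      error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <-
        data.frame(id = ids[i], reason = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else {
      out[[ids[i]]] <- res
    }
  }
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(id = character(), reason = character(),
               stringsAsFactors = FALSE)
  if (nrow(failures) > 0L) {
    if (on_invalid == "error")
      stop("invalid coding sequence(s) in '", path, "':\n",
           paste0("  ", failures$id, ": ", failures$reason, collapse = "\n"))
    warning(nrow(failures), " record(s) failed validation; see attr(x, \"failures\")")
  }
  attr(out, "failures") <- failures
  out
}

#' Write coding sequences to FASTA
#'
#' @param seqs list of `cub_cds` (or a single one).
#' @param path output path.
#' @param width line-wrap width; `Inf` writes unwrapped records.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "cub_cds")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con)
    nt <- s$nucleotides
    if (is.finite(width) && nchar(nt) > width) {
      starts <- seq(1L, nchar(nt), by = width)
      writeLines(substring(nt, starts, pmin(starts + width - 1L, nchar(nt))), con)
    } else writeLines(nt, con)
  }
  invisible(path)
}

#' Per-record validation table for a FASTA file
#'
#' Backs the `cubkit validate` command-line verb: every record is reported
#' with its status, never dropped.
#'
#' @inheritParams read_fasta
#' @return data.frame with columns id, length, n_codons, status, reason.
#' @export
validate_fasta <- function(path, frame_policy = c("strict", "trim_trailing")) {
  frame_policy <- match.arg(frame_policy)
  seqs <- read_fasta(path, frame_policy = frame_policy, on_invalid = "skip")
  failures <- attr(seqs, "failures")
  ok <- data.frame(
    id = vapply(seqs, `[[`, "", "id"),
    length = vapply(seqs, function(s) nchar(s$nucleotides), numeric(1)),
    n_codons = vapply(seqs, `[[`, numeric(1), "n_codons"),
    status = rep("ok", length(seqs)),
    reason = rep("", length(seqs)),
    stringsAsFactors = FALSE)
  if (nrow(failures) > 0L) {
    bad <- data.frame(id = failures$id, length = NA_real_,
                      n_codons = NA_real_, status = "invalid",
                      reason = failures$reason, stringsAsFactors = FALSE)
    ok <- rbind(ok, bad)
  }
  rownames(ok) <- NULL
  ok
}

# Map an in-frame nucleotide string to codon indices 1..64 (NA for codons
# containing non-ACGT symbols).  Fast path shared by counting and the
# dinucleotide module.
.codon_index <- function(nt) {
  map <- rep(NA_integer_, 256L)
  map[utf8ToInt("A")] <- 0L
  map[utf8ToInt("C")] <- 1L
  map[utf8ToInt("G")] <- 2L
  map[utf8ToInt("T")] <- 3L
  b <- map[utf8ToInt(nt)]
  n <- length(b) %/% 3L
  dim(b) <- c(3L, n)
  16L * b[1L, ] + 4L * b[2L, ] + b[3L, ] + 1L
}

#' Count codon occurrences
#'
#' Tabulates the 64 codons of a coding sequence.  Codons containing
#' ambiguity codes are excluded from the counts and tallied in the
#' `n_excluded` attribute.  Stop/Met/Trp codons are counted here (the
#' table covers all 64 codons) but are ignored by every synonymous-usage
#' statistic downstream.
#'
#' @param seq a `cub_cds`, or an in-frame nucleotide string.
#' @return Named integer vector of length 64 (class `cub_codon_counts`)
#'   with attributes `total`, `n_excluded` and `id`.
#' @export
#' @examples
#' count_codons(coding_sequence("GAAGAAGAG"))[c("GAA", "GAG")]
count_codons <- function(seq) {
  if (is.character(seq)) seq <- coding_sequence(seq)
  if (!inherits(seq, "cub_cds")) stop("'seq' must be a cub_cds or string")
  idx <- .codon_index(seq$nucleotides)
  counts <- tabulate(idx[!is.na(idx)], nbins = 64L)
  structure(stats::setNames(as.integer(counts), .CODONS),
            total = sum(counts), n_excluded = sum(is.na(idx)),
            id = seq$id, class = "cub_codon_counts")
}

#' @export
print.cub_codon_counts <- function(x, ...) {
  cat(sprintf("<cub_codon_counts> %s: %d codons counted (%d excluded)\n",
              attr(x, "id") %||% "?", attr(x, "total"), attr(x, "n_excluded")))
  nz <- x[x > 0]
  print(unclass(nz[order(-nz)][seq_len(min(10L, length(nz)))]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pool codon counts across sequences (plain integer sum).
pool_codon_counts <- function(seqs) {
  tabs <- lapply(seqs, function(s)
    if (inherits(s, "cub_codon_counts")) s else count_codons(s))
  tot <- Reduce(`+`, lapply(tabs, unclass))
  structure(stats::setNames(as.integer(tot), .CODONS),
            total = sum(tot),
            n_excluded = sum(vapply(tabs, attr, numeric(1), "n_excluded")),
            id = "pooled", class = "cub_codon_counts")
}
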