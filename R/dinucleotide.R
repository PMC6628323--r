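# Dinucleotide odds ratios: Pxy = f(xy) / (f(x) * f(y)), with f the
# observed mono- and (overlapping) dinucleotide frequencies.  Pxy > 1.23 is
# called over-represented, < 0.78 under-represented.  Counting is
# all-positions over the CDS as given (codon-bridging pairs included);
# circular mode adds the wrap-around pair for circular genomes.

.DINUCS <- as.vector(t(outer(.BASES, .BASES, paste0)))

#' Dinucleotide odds ratios of one sequence
#'
#' @param seq a `cub_cds` or nucleotide string (ambiguity codes are
#'   skipped: positions/pairs involving them are excluded).
#' @param mode `"linear"` counts the L-1 overlapping pairs; `"circular"`
#'   adds the last-to-first pair.
#' @param over,under representation thresholds.
#' @return Object of class `cub_dinuc`: list with `odds` (16 named
#'   ratios), `call` (over/normal/under), `fx` (base frequencies), `fxy`
#'   (pair frequencies), `counting_mode`.
#' @export
#' @examples
#' d <- dinucleotide_odds(strrep("AC", 50))
#' d$odds[c("AC", "AA")]  # ~2, 0
dinucleotide_odds <- function(seq, mode = c("linear", "circular"),
                              over = 1.23, under = 0.78) {
  mode <- match.arg(mode)
  nt <- if (inherits(seq, "cub_cds")) seq$nucleotides else
    chartr("U", "T", toupper(gsub("[[:space:]]", "", seq)))
  id <- if (inherits(seq, "cub_cds")) seq$id else "seq"
  L <- nchar(nt)
  if (L < 2L) stop("dinucleotide odds require sequence length >= 2")
  map <- rep(NA_integer_, 256L)
  map[utf8ToInt("A")] <- 0L; map[utf8ToInt("C")] <- 1L
  map[utf8ToInt("G")] <- 2L; map[utf8ToInt("T")] <- 3L
  v <- map[utf8ToInt(nt)]
  nv <- sum(!is.na(v))
  if (nv == 0L) stop("no unambiguous bases in sequence")
  fx <- tabulate(v[!is.na(v)] + 1L, 4L) / nv
  names(fx) <- .BASES
  if (mode == "circular") {
    i1 <- v; i2 <- c(v[-1L], v[1L])
  } else {
    i1 <- v[-L]; i2 <- v[-1L]
  }
  ok <- !is.na(i1) & !is.na(i2)
  if (!any(ok)) stop("no unambiguous dinucleotide pairs in sequence")
  fxy <- tabulate(4L * i1[ok] + i2[ok] + 1L, 16L) / sum(ok)
  names(fxy) <- .DINUCS
  expected <- fx[substr(.DINUCS, 1L, 1L)] * fx[substr(.DINUCS, 2L, 2L)]
  odds <- ifelse(expected > 0, fxy / expected,
                 ifelse(fxy > 0, Inf, NA_real_))
  names(odds) <- .DINUCS
  call <- ifelse(is.na(odds), NA_character_,
                 ifelse(odds > over, "over",
                        ifelse(odds < under, "under", "normal")))
  names(call) <- .DINUCS
  structure(list(id = id, odds = odds, call = call, fx = fx, fxy = fxy,
                 counting_mode = mode), class = "cub_dinuc")
}

#' @export
print.cub_dinuc <- function(x, ...) {
  cat(sprintf("<cub_dinuc> %s (%s counting)\n", x$id, x$counting_mode))
  print(round(x$odds, 3))
  flagged <- x$call[!is.na(x$call) & x$call != "normal"]
  if (length(flagged))
    cat("Calls:", paste(names(flagged), flagged, sep = "=",
                        collapse = " "), "\n")
  invisible(x)
}

#' Dinucleotide odds across a batch of sequences
#'
#' Per-sequence odds plus mean and sample-SD (n-1 denominator) summary
#' rows, the usual "mean +/- SD" reporting shape.
#'
#' @param seqs list of `cub_cds` (or strings).
#' @inheritParams dinucleotide_odds
#' @return data.frame with an `id` column and one column per dinucleotide;
#'   the final two rows are `mean` and `sd`.
#' @export
dinucleotide_batch <- function(seqs, mode = c("linear", "circular"),
                               over = 1.23, under = 0.78) {
  mode <- match.arg(mode)
  if (length(seqs) == 0L) stop("dinucleotide_batch: empty input")
  profs <- lapply(seqs, dinucleotide_odds, mode = mode,
                  over = over, under = under)
  m <- do.call(rbind, lapply(profs, `[[`, "odds"))
  per <- data.frame(id = vapply(profs, `[[`, "", "id"),
                    m, stringsAsFactors = FALSE, check.names = FALSE)
  mu <- colMeans(m)
  sdv <- if (nrow(m) > 1L) apply(m, 2L, stats::sd) else
    stats::setNames(rep(0, ncol(m)), colnames(m))
  out <- rbind(per,
               data.frame(id = "mean", t(mu), check.names = FALSE),
               data.frame(id = "sd", t(sdv), check.names = FALSE))
  rownames(out) <- NULL
  attr(out, "call_of_mean") <- ifelse(mu > over, "over",
                                      ifelse(mu < under, "under", "normal"))
  out
}
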