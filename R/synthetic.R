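# Synthetic coding-sequence generator.  Sequences are sampled i.i.d.:
# amino acid ~ aa_weights, codon within family ~ family_codon_weights.
# This is exactly the statistical world the codon-usage statistics assume,
# so every statistic has a ground-truth-bearing input: one-hot family
# weights give ENC = 20, uniform weights approach 61, and in GC3-target
# mode the within-family weights are set so the expected silent-site GC
# equals the target in every family.
#
# Defaults emulate a TTSuV-like ORF1 gene panel: 630 codons (~1.9 kb) and
# amino acids uniform over the 18 synonymous families, so that every codon
# participates in the synonymous statistics.

# Fast constructor for generator output: codons are drawn from sense-codon
# alphabets, so the coding_sequence() validation (alphabet, frame, stops)
# is satisfied by construction and skipped.
.cds_from_codons <- function(codons, id) {
  structure(list(id = id,
                 nucleotides = paste(codons, collapse = ""),
                 codons = codons,
                 n_codons = length(codons),
                 has_terminal_stop = FALSE,
                 n_ambiguous_codons = 0L), class = "cub_cds")
}

.spec_hash <- function(spec) {
  s <- paste(deparse(spec[order(names(spec))]), collapse = "")
  h <- 5381
  for (k in utf8ToInt(s)) h <- (h * 33 + k) %% 16777216
  sprintf("%06x", h)
}

# per-family weights achieving expected third-position GC = target
.gc3_weights <- function(target, code = genetic_code()) {
  lapply(code$families, function(cods) {
    gc3 <- substr(cods, 3, 3) %in% c("G", "C")
    m <- sum(gc3); k <- length(cods)
    if ((m == 0L && target > 0) || (m == k && target < 1))
      stop("gc3_target ", target, " infeasible for family ",
           code$family_of[[cods[1L]]])
    w <- numeric(k)
    if (m > 0L) w[gc3] <- target / m
    if (m < k) w[!gc3] <- (1 - target) / (k - m)
    stats::setNames(w, cods)
  })
}

#' Specify a synthetic coding-sequence generator
#'
#' @param n_sequences number of sequences.
#' @param n_codons codons per sequence (default 630, a TTSuV ORF1-sized
#'   CDS of ~1.9 kb).
#' @param aa_weights named amino-acid sampling weights (one-letter codes
#'   among the 18 synonymous families, plus optionally M/W); default
#'   uniform over the 18 families.
#' @param family_codon_weights named list: per family, a probability
#'   vector over its codons (named by codon).  Mutually exclusive with
#'   `gc3_target`.
#' @param gc3_target silent-site GC target in \[0, 1\]; within each family
#'   the GC-ending codons share probability `gc3_target` and the AT-ending
#'   ones share the remainder (mutation-pressure mode).
#' @param bias_concentration if given (positive), per-family weights are
#'   drawn once per run from a symmetric Dirichlet with this concentration:
#'   small values give sharply biased families, large values near-uniform
#'   usage.
#' @param seed integer seed; fixed seed implies byte-identical output.
#' @return list of class `cub_generator_spec`.
#' @export
generator_spec <- function(n_sequences = 1L, n_codons = 630L,
                           aa_weights = NULL, family_codon_weights = NULL,
                           gc3_target = NULL, bias_concentration = NULL,
                           seed = 1L) {
  if (n_sequences < 1L || n_codons < 1L)
    stop("n_sequences and n_codons must be >= 1")
  if (!is.null(family_codon_weights) && !is.null(gc3_target))
    stop("supply either family_codon_weights or gc3_target, not both")
  if (!is.null(gc3_target) && (gc3_target < 0 || gc3_target > 1))
    stop("gc3_target must lie in [0, 1]")
  if (!is.null(bias_concentration) && bias_concentration <= 0)
    stop("bias_concentration must be positive")
  code <- genetic_code()
  if (is.null(aa_weights)) {
    aa_weights <- stats::setNames(rep(1, length(code$families)),
                                  names(code$families))
  }
  bad <- setdiff(names(aa_weights), c(names(code$families), "M", "W"))
  if (length(bad)) stop("unknown amino acids in aa_weights: ",
                        paste(bad, collapse = ", "))
  if (any(aa_weights < 0) || sum(aa_weights) <= 0)
    stop("aa_weights must be non-negative and not all zero")
  aa_weights <- aa_weights / sum(aa_weights)
  if (!is.null(family_codon_weights)) {
    for (aa in names(family_codon_weights)) {
      w <- family_codon_weights[[aa]]
      cods <- code$families[[aa]]
      if (is.null(cods) || !setequal(names(w), cods))
        stop("family_codon_weights for ", aa,
             " must be named by that family's codons")
      if (any(w < 0) || sum(w) <= 0)
        stop("family_codon_weights for ", aa, " invalid")
      family_codon_weights[[aa]] <- (w / sum(w))[cods]
    }
  }
  structure(list(n_sequences = as.integer(n_sequences),
                 n_codons = as.integer(n_codons),
                 aa_weights = aa_weights,
                 family_codon_weights = family_codon_weights,
                 gc3_target = gc3_target,
                 bias_concentration = bias_concentration,
                 seed = as.integer(seed)),
            class = "cub_generator_spec")
}

#' Generate synthetic coding sequences
#'
#' @param spec a `cub_generator_spec` (see [generator_spec()]).
#' @return list with `sequences` (list of `cub_cds`; never contain stop
#'   codons) and `truth` (the resolved sampling weights, expected GC3, and
#'   spec hash).  Sequence ids encode the spec hash and index.
#' @export
#' @examples
#' g <- generate_cds(generator_spec(n_sequences = 2, n_codons = 100, seed = 7))
#' vapply(g$sequences, `[[`, numeric(1), "n_codons")
generate_cds <- function(spec) {
  stopifnot(inherits(spec, "cub_generator_spec"))
  code <- genetic_code()
  set.seed(spec$seed)
  fam_w <- spec$family_codon_weights
  if (is.null(fam_w)) {
    if (!is.null(spec$gc3_target)) {
      fam_w <- .gc3_weights(spec$gc3_target, code)
    } else if (!is.null(spec$bias_concentration)) {
      fam_w <- lapply(code$families, function(cods) {
        g <- stats::rgamma(length(cods), shape = spec$bias_concentration)
        if (sum(g) == 0) g <- rep(1, length(cods))
        stats::setNames(g / sum(g), cods)
      })
    } else {
      fam_w <- lapply(code$families, function(cods)
        stats::setNames(rep(1 / length(cods), length(cods)), cods))
    }
  }
  aa_pool <- names(spec$aa_weights)
  total <- spec$n_sequences * spec$n_codons
  aa_draw <- sample(aa_pool, total, replace = TRUE, prob = spec$aa_weights)
  codon <- character(total)
  for (aa in aa_pool) {
    i <- which(aa_draw == aa)
    if (!length(i)) next
    if (aa %in% c("M", "W")) {
      codon[i] <- code$single_codon_aa[[aa]]
    } else {
      w <- fam_w[[aa]]
      codon[i] <- names(w)[sample.int(length(w), length(i),
                                      replace = TRUE, prob = w)]
    }
  }
  hash <- .spec_hash(unclass(spec))
  seqs <- lapply(seq_len(spec$n_sequences), function(j) {
    block <- codon[((j - 1L) * spec$n_codons + 1L):(j * spec$n_codons)]
    .cds_from_codons(block, id = sprintf("sim%s_%04d", hash, j))
  })
  expected_gc3 <- if (!is.null(spec$gc3_target)) spec$gc3_target else {
    # expectation over aa_weights of per-family third-position GC
    fam_gc <- vapply(names(code$families), function(aa) {
      w <- fam_w[[aa]]
      sum(w[substr(names(w), 3, 3) %in% c("G", "C")])
    }, numeric(1))
    aw <- spec$aa_weights[names(code$families)[names(code$families) %in%
                                                 names(spec$aa_weights)]]
    sum(aw * fam_gc[names(aw)]) / sum(aw)
  }
  list(sequences = seqs,
       truth = list(aa_weights = spec$aa_weights,
                    family_codon_weights = fam_w,
                    gc3_target = spec$gc3_target,
                    expected_gc3 = expected_gc3,
                    spec_hash = hash, seed = spec$seed,
                    rng = "Mersenne-Twister"))
}

#' Generate a neutrality-plot panel with a known GC12 ~ GC3s slope
#'
#' Builds `n` sequences whose realized (GC3s, GC12) points scatter around
#' the line `gc12 = intercept + slope * gc3s`.  GC12 is steered through
#' the amino-acid mixture (Ala codons GCN contribute GC at positions 1-2,
#' Lys codons AAR contribute AT) and GC3s through the within-family
#' third-base choice, so the two coordinates are controlled independently.
#'
#' @param slope,intercept true regression line.
#' @param n number of sequences.
#' @param gc3_range GC3s targets drawn uniformly from this interval.
#' @param noise_sd Gaussian noise added to each sequence's GC12 target.
#' @param n_codons codons per sequence.
#' @param seed integer seed.
#' @return list with `sequences` and `truth` (data.frame id, gc3_target,
#'   gc12_target).
#' @export
generate_neutrality_panel <- function(slope, intercept, n = 80L,
                                      gc3_range = c(0.25, 0.75),
                                      noise_sd = 0.01, n_codons = 630L,
                                      seed = 1L) {
  stopifnot(n >= 3L, n_codons >= 1L, noise_sd >= 0,
            length(gc3_range) == 2L, gc3_range[1] <= gc3_range[2],
            gc3_range[1] >= 0, gc3_range[2] <= 1)
  mid <- intercept + slope * gc3_range
  if (any(mid < 0.01) || any(mid > 0.99))
    stop("infeasible line: GC12 targets leave (0, 1) over gc3_range")
  set.seed(seed)
  gc3 <- stats::runif(n, gc3_range[1], gc3_range[2])
  gc12 <- pmin(pmax(intercept + slope * gc3 + stats::rnorm(n, 0, noise_sd),
                    0.01), 0.99)
  total <- n * n_codons
  sidx <- rep(seq_len(n), each = n_codons)
  is_ala <- stats::runif(total) < gc12[sidx]
  third_gc <- stats::runif(total) < gc3[sidx]
  u <- stats::runif(total) < 0.5
  codon <- ifelse(is_ala,
                  ifelse(third_gc, ifelse(u, "GCC", "GCG"),
                         ifelse(u, "GCT", "GCA")),
                  ifelse(third_gc, "AAG", "AAA"))
  ids <- sprintf("panel_%04d", seq_len(n))
  seqs <- lapply(seq_len(n), function(j) {
    block <- codon[((j - 1L) * n_codons + 1L):(j * n_codons)]
    .cds_from_codons(block, id = ids[j])
  })
  list(sequences = seqs,
       truth = data.frame(id = ids, gc3_target = gc3, gc12_target = gc12,
                          stringsAsFactors = FALSE))
}
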