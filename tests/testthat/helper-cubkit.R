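# Shared helpers: tiny fixture builders and independently coded oracles.
# The oracles re-derive each statistic by direct enumeration of its
# definition, never by calling the implementation under test.

make_fasta <- function(records, path = tempfile(fileext = ".fasta"),
                       width = Inf) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(records)) {
    writeLines(paste0(">", id), con)
    nt <- records[[id]]
    if (is.finite(width)) {
      starts <- seq(1L, nchar(nt), by = width)
      writeLines(substring(nt, starts, pmin(starts + width - 1L, nchar(nt))),
                 con)
    } else writeLines(nt, con)
  }
  path
}

# random codon count table over all 18 families (n per family <= nmax)
random_count_table <- function(nmax = 50L) {
  code <- genetic_code()
  counts <- setNames(rep(0L, 64L), code$codons)
  for (cods in code$families) {
    n <- sample.int(nmax, 1L) + 1L  # at least 2 so ENC is computable
    counts[cods] <- counts[cods] +
      tabulate(sample.int(length(cods), n, replace = TRUE),
               nbins = length(cods))
  }
  structure(as.integer(counts), names = names(counts), total = sum(counts),
            n_excluded = 0L, id = "random", class = "cub_codon_counts")
}

# Oracle: RSCU by literal evaluation of the definition
# RSCU_i = g_i / ((1/n_i) * sum_j g_j), per synonymous family.
oracle_rscu <- function(counts) {
  code <- genetic_code()
  out <- c()
  for (cods in code$families) {
    g <- as.numeric(counts[cods])
    out[cods] <- if (sum(g) == 0) NA_real_ else g / (sum(g) / length(g))
  }
  out[code$sense_codons]
}

# Oracle: ENC by direct evaluation of S, F and the class averages.
oracle_enc <- function(counts) {
  code <- genetic_code()
  Fs <- list("2" = c(), "3" = c(), "4" = c(), "6" = c())
  for (aa in names(code$families)) {
    g <- as.numeric(counts[code$families[[aa]]])
    n <- sum(g)
    if (n < 2) next
    S <- sum((g / n)^2)
    k <- as.character(length(g))
    Fs[[k]] <- c(Fs[[k]], (n * S - 1) / (n - 1))
  }
  F2 <- mean(Fs[["2"]]); F4 <- mean(Fs[["4"]]); F6 <- mean(Fs[["6"]])
  F3 <- if (length(Fs[["3"]])) mean(Fs[["3"]]) else mean(c(F2, F4))
  val <- 2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6
  min(val, 61)
}

# Oracle: dinucleotide odds by direct substring counting.
oracle_dinuc <- function(nt, mode = "linear") {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(nt, "")[[1]]
  fx <- sapply(bases, function(b) mean(chars == b))
  pairs <- if (mode == "circular")
    paste0(chars, c(chars[-1], chars[1]))
  else paste0(chars[-length(chars)], chars[-1])
  dinucs <- as.vector(t(outer(bases, bases, paste0)))
  fxy <- sapply(dinucs, function(d) mean(pairs == d))
  fxy / (fx[substr(dinucs, 1, 1)] * fx[substr(dinucs, 2, 2)])
}

expect_rscu_complete <- function(profile) {
  expect_length(unclass(profile), 59L)
  expect_false(anyNA(unclass(profile)))
}
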