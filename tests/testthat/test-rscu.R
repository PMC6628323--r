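test_that("RSCU matches the definition on hand-checkable counts", {
  p <- rscu_from_counts(count_codons("GAAGAAGAAGAG"))
  expect_equal(unname(unclass(p)[c("GAA", "GAG")]), c(1.5, 0.5))
  # uniform 4-fold family -> all 1
  p4 <- rscu_from_counts(count_codons(strrep("GGTGGCGGAGGG", 4)))
  expect_equal(unname(unclass(p4)[c("GGT", "GGC", "GGA", "GGG")]),
               rep(1, 4))
  # unobserved families flagged as NA, not fabricated
  expect_true("F" %in% attr(p, "unobserved"))
  expect_true(is.na(unclass(p)["TTT"]))
  expect_error(rscu_from_counts(count_codons("ATGTGG")), "no synonymous")
})

test_that("family sums, scale invariance and the direct-definition oracle", {
  set.seed(101)
  code <- genetic_code()
  for (rep in 1:25) {
    ct <- random_count_table(nmax = 10L)
    p <- rscu_from_counts(ct)
    # oracle equivalence
    expect_equal(unclass(p), oracle_rscu(ct), tolerance = 1e-12,
                 ignore_attr = TRUE)
    # family sums = family size
    for (aa in names(code$families)) {
      cods <- code$families[[aa]]
      expect_equal(sum(unclass(p)[cods]), length(cods), tolerance = 1e-9)
    }
    # scale invariance: RSCU(k * counts) = RSCU(counts)
    k <- sample(2:7, 1)
    scaled <- structure(as.integer(unclass(ct) * k), names = names(ct),
                        total = attr(ct, "total") * k, n_excluded = 0L,
                        id = "scaled", class = "cub_codon_counts")
    expect_equal(unclass(rscu_from_counts(scaled)), unclass(p),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("mean_rscu is idempotent, averages codon-wise, keeps family sums", {
  p <- rscu_from_counts(random_count_table())
  expect_equal(unclass(mean_rscu(list(p, p))), unclass(p),
               ignore_attr = TRUE)
  a <- rscu_profile(setNames(c(2, 0, rep(1, 57)),
                             genetic_code()$sense_codons))
  b <- rscu_profile(setNames(c(0, 2, rep(1, 57)),
                             genetic_code()$sense_codons))
  m <- mean_rscu(list(a, b))
  expect_equal(unname(unclass(m)[1:2]), c(1, 1))
  expect_error(mean_rscu(list()), "empty")
  # family sums preserved vs direct summation
  set.seed(7)
  profs <- replicate(5, rscu_from_counts(random_count_table()),
                     simplify = FALSE)
  mm <- mean_rscu(profs)
  for (cods in genetic_code()$families)
    expect_equal(sum(unclass(mm)[cods]), length(cods), tolerance = 1e-9)
})

test_that("preferred codons, ending census and tie handling", {
  p <- builtin_rscu_profiles()
  census1 <- ending_census(p$ttsuv1)
  expect_equal(census1, c(A = 10L, C = 5L, G = 1L, T = 2L))
  census2 <- ending_census(p$ttsuv2)
  expect_equal(census2, c(A = 8L, C = 4L, G = 0L, T = 6L))
  expect_equal(sum(census1), 18L)
  # constructed G-ending preference: every family that has a G-ending
  # codon prefers it (six 2-fold families have none, so 18 is unattainable)
  code <- genetic_code()
  v <- setNames(rep(0.1, 59), code$sense_codons)
  v[endsWith(code$sense_codons, "G")] <- 3
  pg <- rscu_profile(v)
  n_g_families <- sum(vapply(code$families,
                             function(cods) any(endsWith(cods, "G")),
                             logical(1)))
  expect_equal(unname(suppressWarnings(ending_census(pg))["G"]),
               n_g_families)
  expect_equal(sum(suppressWarnings(ending_census(pg))), 18L)
  # unobserved family errors the census
  part <- rscu_from_counts(count_codons("GAAGAG"))
  expect_error(ending_census(part), "unobserved")
  # exact tie: reported, lexicographic scalar winner
  v2 <- setNames(rep(1, 59), code$sense_codons)
  pref <- preferred_codons(rscu_profile(v2))
  expect_true(all(pref$tie))
  expect_equal(pref$codon[pref$family == "K"], "AAA")
  expect_warning(ending_census(rscu_profile(v2)), "tie")
})

test_that("coincidence/antagonism verdicts per family", {
  p <- builtin_rscu_profiles()
  cr <- coincidence_analysis(p$ttsuv1, p$sus_scrofa)
  expect_equal(cr$n_coincidence, 6L)
  expect_equal(cr$n_antagonism, 12L)
  expect_equal(cr$n_coincidence + cr$n_antagonism, 18L)
  cr2 <- coincidence_analysis(p$ttsuv1, p$sus_scrofa_domestica)
  expect_equal(c(cr2$n_coincidence, cr2$n_antagonism), c(11L, 7L))
  # identity: any complete profile vs itself
  self <- coincidence_analysis(p$ttsuv2, p$ttsuv2)
  expect_equal(self$n_coincidence, 18L)
  expect_error(
    coincidence_analysis(rscu_from_counts(count_codons("GAAGAG")),
                         p$sus_scrofa),
    "complete")
})

test_that("representation thresholds with inclusive boundaries", {
  p <- builtin_rscu_profiles()
  calls <- representation_calls(p$ttsuv1)
  over <- sort(names(calls)[calls == "over"])
  expect_equal(over, sort(c("CTA", "GTA", "AGT", "CCA", "ACA", "GCA",
                            "AGA", "GGA")))
  # GCA sits at exactly 1.60 and must be included
  expect_equal(unname(unclass(p$ttsuv1)["GCA"]), 1.6)
  # all NCG and CGN codons negative (< 1) in both virus profiles
  ncg <- c("TCG", "CCG", "ACG", "GCG", "CGT", "CGC", "CGA", "CGG")
  for (prof in list(p$ttsuv1, p$ttsuv2))
    expect_true(all(representation_calls(prof)[ncg] %in%
                      c("negative", "under")))
  # boundary values
  code <- genetic_code()
  v <- setNames(rep(1, 59), code$sense_codons)
  expect_true(all(representation_calls(rscu_profile(v)) == "neutral"))
})
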