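test_that("host reference weights derive from RSCU", {
  h <- load_host_reference("sus_scrofa")
  # Glu family: w(GAG) = 1, w(GAA) = 0.72/1.28
  expect_equal(unname(h$w["GAG"]), 1)
  expect_equal(unname(h$w["GAA"]), 0.72 / 1.28)
  # within every family max w = 1 and w = RSCU / family max
  code <- genetic_code()
  for (cods in code$families) {
    expect_equal(max(h$w[cods]), 1)
    expect_equal(unname(h$w[cods]),
                 unname(unclass(h$rscu)[cods] / max(unclass(h$rscu)[cods])))
  }
  # uniform reference: all w = 1
  hu <- host_reference(setNames(rep(1, 59), code$sense_codons),
                       name = "uniform")
  expect_true(all(hu$w == 1))
  # incomplete reference rejected
  expect_error(host_reference(setNames(rep(1, 58), code$sense_codons[-1])),
               "missing|incomplete|cover")
})

test_that("Kazusa codon usage tables parse and round-trip", {
  code <- genetic_code()
  set.seed(5)
  freq <- setNames(round(runif(64, 1, 40), 1), code$codons)
  count <- setNames(round(freq * 100), code$codons)
  f <- tempfile(fileext = ".txt")
  write_kazusa(freq, f, count = count)
  kz <- parse_kazusa(f)
  expect_equal(kz$freq[code$codons], freq)
  # re-emit -> re-parse gives identical frequencies
  f2 <- tempfile(fileext = ".txt")
  write_kazusa(kz$freq, f2, count = kz$count)
  expect_equal(parse_kazusa(f2)$freq, kz$freq)
  # a host built from frequencies: within-family RSCU from frequencies
  h <- host_reference_from_freq(freq, name = "kz")
  expect_equal(unname(unclass(h$rscu)["GAA"]),
               unname(freq["GAA"] * 2 / (freq["GAA"] + freq["GAG"])))
  # RNA-alphabet codon names accepted
  names(freq) <- chartr("T", "U", names(freq))
  expect_equal(unclass(host_reference_from_freq(freq)$rscu),
               unclass(h$rscu))
})

test_that("CAI closed forms, bounds and scale invariance", {
  h <- load_host_reference("sus_scrofa")
  # host-optimal-only gene
  expect_equal(cai("GAGGAG", h), 1)
  # {GAA, GAG}: exp((ln 0.5625 + ln 1)/2) = 0.75
  expect_equal(cai("GAAGAG", h), 0.75)
  # uniform host: CAI = 1 for any gene
  hu <- host_reference(setNames(rep(1, 59), genetic_code()$sense_codons))
  expect_equal(cai("GAAGAGAAATTTGGA", hu), 1)
  # scale invariance CAI(k * counts) = CAI(counts)
  s <- "GAAGAGAAATTTGGA"
  expect_equal(cai(strrep(s, 5), h), cai(s, h))
  expect_error(cai("ATGTGG", h), "no synonymous")
})

test_that("RCDI: matched usage gives 1; deoptimized toys in closed form", {
  h <- load_host_reference("sus_scrofa")
  # virus using GAA only: CiF_virus = 1, host CiF(GAA) = 0.72/2 = 0.36
  expect_equal(rcdi("GAAGAA", h), 1 / 0.36, tolerance = 1e-12)
  # virus matching host within-family frequencies exactly -> RCDI = 1:
  # Glu 9:16 mirrors 0.72:1.28
  s <- paste0(strrep("GAA", 9), strrep("GAG", 16))
  expect_equal(rcdi(s, h), 1, tolerance = 1e-12)
  # long gene sampled from host frequencies -> RCDI ~ 1
  code <- genetic_code()
  fam_w <- lapply(code$families, function(cods) {
    v <- unclass(load_host_reference("sus_scrofa")$rscu)[cods]
    setNames(v / sum(v), cods)
  })
  g <- generate_cds(generator_spec(n_sequences = 1, n_codons = 5000,
                                   family_codon_weights = fam_w, seed = 13))
  expect_equal(rcdi(count_codons(g$sequences[[1]]), h), 1, tolerance = 0.05)
  expect_gt(cai(count_codons(g$sequences[[1]]), h), 0.5)
})

test_that("replacing optimal codons with rare ones moves CAI and RCDI monotonically", {
  h <- load_host_reference("sus_scrofa")
  # CAI: every swap of host-optimal CTG (w = 1) for host-rare CTA lowers it
  genes <- sapply(0:6, function(k)
    paste0(strrep("CTA", k), strrep("CTG", 6 - k), strrep("GAAGAG", 3)))
  cais <- vapply(genes, cai, numeric(1), host = h)
  expect_true(all(diff(cais) < 0))
  expect_true(all(cais > 0 & cais <= 1))
  # RCDI: minimized (= 1) exactly at host-matched usage, and monotonically
  # non-decreasing along the path away from it.  Glu host mix is 9:16
  # (0.72 : 1.28); swap GAG -> host-rare GAA one codon at a time.
  rcdis <- vapply(9:25, function(k)
    rcdi(paste0(strrep("GAA", k), strrep("GAG", 25 - k)), h), numeric(1))
  expect_equal(rcdis[1], 1, tolerance = 1e-12)
  expect_true(all(diff(rcdis) > 0))
  expect_true(all(rcdis >= 1))
})

test_that("SiD cosine distance: identity, orthogonality, symmetry, references", {
  p <- builtin_rscu_profiles()
  expect_equal(sid(p$ttsuv1, p$ttsuv1)$D, 0)
  expect_equal(sid(p$ttsuv1, p$ttsuv1)$R, 1)
  # orthogonal non-negative vectors -> R = 0, D = 0.5
  code <- genetic_code()
  a <- setNames(c(rep(2, 30), rep(0, 29)), code$sense_codons)
  b <- setNames(c(rep(0, 30), rep(2, 29)), code$sense_codons)
  s <- sid(rscu_profile(a), rscu_profile(b))
  expect_equal(s$R, 0)
  expect_equal(s$D, 0.5)
  # symmetry
  expect_equal(sid(p$ttsuv1, p$sus_scrofa)$R,
               sid(p$sus_scrofa, p$ttsuv1)$R)
  # the four bundled virus x host reference distances (absolute +/- 0.0015)
  expect_lt(abs(sid(p$ttsuv1, p$sus_scrofa)$D - 0.094), 0.0015)
  expect_lt(abs(sid(p$ttsuv2, p$sus_scrofa)$D - 0.149), 0.0015)
  expect_lt(abs(sid(p$ttsuv1, p$sus_scrofa_domestica)$D - 0.068), 0.0015)
  expect_lt(abs(sid(p$ttsuv2, p$sus_scrofa_domestica)$D - 0.132), 0.0015)
  # D bounded in [0, 0.5] for non-negative profiles
  set.seed(31)
  for (i in 1:10) {
    d <- sid(rscu_from_counts(random_count_table()), p$sus_scrofa)$D
    expect_gte(d, 0); expect_lte(d, 0.5)
  }
  expect_error(sid(rscu_from_counts(count_codons("GAAGAG")), p$sus_scrofa),
               "complete")
})

test_that("zero-usage host codons are floored with a warning", {
  code <- genetic_code()
  v <- setNames(rep(1, 59), code$sense_codons)
  v["GAA"] <- 0
  expect_warning(h <- host_reference(v), "floored")
  expect_gt(h$w[["GAA"]], 0)
  expect_true(is.finite(cai("GAAGAA", h)))
  v2 <- v; v2["GAG"] <- 0
  expect_error(host_reference(v2), "zero RSCU throughout")
})

test_that("adaptation_batch shapes and host resolution by name", {
  seqs <- list(coding_sequence("GAAGAGAAATTTGGATTA", id = "s1"),
               coding_sequence("GAGGAGCTGCTG", id = "s2"))
  tab <- adaptation_batch(seqs, c("sus_scrofa", "sus_scrofa_domestica"))
  expect_equal(nrow(tab), 4L)
  expect_setequal(unique(tab$host), c("sus_scrofa", "sus_scrofa_domestica"))
  expect_true(all(tab$cai > 0 & tab$cai <= 1))
})
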