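test_that("ENC limits: one codon per family gives 20, uniform approaches 61", {
  code <- genetic_code()
  onehot <- lapply(code$families, function(cods)
    setNames(c(1, rep(0, length(cods) - 1L)), cods))
  g <- generate_cds(generator_spec(n_sequences = 1, n_codons = 2000,
                                   family_codon_weights = onehot, seed = 21))
  expect_equal(enc(count_codons(g$sequences[[1]])), 20)
  g2 <- generate_cds(generator_spec(n_sequences = 1, n_codons = 10000,
                                    seed = 22))
  e <- as.numeric(enc(count_codons(g2$sequences[[1]])))
  expect_gte(e, 59.5)
  expect_lte(e, 61)
})

test_that("ENC equals the direct-definition oracle on random tables", {
  set.seed(202)
  for (rep in 1:40) {
    ct <- random_count_table(nmax = 50L)
    expect_equal(as.numeric(enc(ct)), oracle_enc(ct), tolerance = 1e-9)
  }
})

test_that("per-family homozygosity follows Wright's formula (Lys toy)", {
  # {AAA:3, AAG:1}: S = (3/4)^2 + (1/4)^2 = 0.625, F = (4*0.625 - 1)/3 = 0.5.
  # Embedded in a table where every other family uses a single codon (F = 1),
  # so the 2-fold class average is (0.5 + 8*1)/9 and ENC follows in closed
  # form.
  code <- genetic_code()
  ct <- setNames(rep(0L, 64L), code$codons)
  for (cods in code$families) ct[cods[1L]] <- 4L
  ct["AAA"] <- 3L; ct["AAG"] <- 1L
  ct <- structure(as.integer(ct), names = names(ct), total = sum(ct),
                  n_excluded = 0L, id = "toy", class = "cub_codon_counts")
  F2bar <- (0.5 + 8 * 1) / 9
  expect_equal(as.numeric(enc(ct)), 2 + 9 / F2bar + 1 + 5 + 3,
               tolerance = 1e-12)
})

test_that("ENC never increases when synonymous usage gets more skewed", {
  set.seed(303)
  code <- genetic_code()
  for (rep in 1:10) {
    ct <- random_count_table()
    e0 <- as.numeric(enc(ct))
    # move one count from a minority codon to the majority codon of a
    # random family with at least two used codons
    aa <- sample(names(code$families), 1)
    cods <- code$families[[aa]]
    g <- ct[cods]
    if (sum(g > 0) < 2) next
    from <- cods[which(g == min(g[g > 0]) & g > 0)[1]]
    to <- cods[which.max(g)]
    if (from == to) next
    ct[from] <- ct[from] - 1L
    ct[to] <- ct[to] + 1L
    expect_lte(as.numeric(enc(ct)), e0 + 1e-9)
  }
})

test_that("expected-ENC curve closed forms and symmetry", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(1), 32)
  s <- seq(0.05, 0.95, by = 0.05)
  expect_equal(enc_expected(s) - enc_expected(1 - s), 2 * s - 1)
  expect_error(enc_expected(1.2), "0, 1")
})

test_that("ENC-plot rows and the below-curve flag", {
  df <- enc_plot_data(data.frame(id = "x", enc = 45, gc3s = 0.5))
  expect_equal(df$enc_expected, 60.5)
  expect_true(df$below_curve)
  expect_equal(nrow(enc_plot_data(data.frame(enc = numeric(),
                                             gc3s = numeric()))), 0L)
  # selection-free synthetic sequences land on/near the curve
  g <- generate_cds(generator_spec(n_sequences = 5, n_codons = 5000,
                                   gc3_target = 0.35, seed = 44))
  recs <- enc_batch(g$sequences)
  expect_true(all(abs(recs$enc - enc_expected(0.35)) < 1.5))
})

test_that("neutrality regression: pure-mutation and flat-line cases", {
  d <- data.frame(gc3s = c(0.2, 0.4, 0.6, 0.8),
                  gc12 = c(0.2, 0.4, 0.6, 0.8))
  fit <- suppressWarnings(neutrality_fit(d))  # lm warns on a perfect fit
  expect_equal(fit$slope, 1)
  expect_equal(fit$pct_mutation, 100)
  expect_equal(fit$pct_mutation + fit$pct_selection, 100)
  flat <- suppressWarnings(neutrality_fit(c(0.2, 0.5, 0.8), c(0.4, 0.4, 0.4)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$pct_selection, 100)
  expect_error(neutrality_fit(c(0.5, 0.5, 0.5), c(0.1, 0.2, 0.3)),
               "zero variance")
  expect_error(neutrality_fit(c(0.1, 0.2), c(0.1, 0.2)), "at least 3")
})

test_that("noiseless tunable panels give r^2 > 0.99 and slope-1 panels 100%", {
  pan <- generate_neutrality_panel(0.5, 0.2, n = 40, noise_sd = 0,
                                   n_codons = 20000, seed = 7)
  cb <- composition_batch(pan$sequences)
  fit <- neutrality_fit(cb$GC3s, cb$GC12)
  expect_gt(fit$r_squared, 0.99)
  expect_lt(abs(fit$slope - 0.5), 0.05)
  pan1 <- generate_neutrality_panel(1, 0, n = 30, gc3_range = c(0.2, 0.8),
                                    noise_sd = 0, n_codons = 20000, seed = 8)
  cb1 <- composition_batch(pan1$sequences)
  fit1 <- neutrality_fit(cb1$GC3s, cb1$GC12)
  expect_equal(fit1$pct_mutation, 100, tolerance = 2)
})
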