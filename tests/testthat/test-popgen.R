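test_that("genotype tallying partitions calls and ignores allele order", {
  ct <- count_genotypes(c("CC", "CT", "TT", "TT"), c("C", "T"))
  expect_equal(unname(ct$counts), c(1L, 1L, 2L))
  expect_equal(ct$n, 4L)

  ct2 <- count_genotypes(c("TC", "CT"), c("C", "T"))
  expect_equal(unname(ct2$counts), c(0L, 2L, 0L))

  expect_error(count_genotypes(c("CC", "CG"), c("C", "T"), marker = "LEP"),
               "unknown allele symbol.*LEP.*animal index 2")
})

test_that("allele frequencies come from direct gene counting", {
  expect_equal(unname(allele_frequencies(
    genotype_counts(43, 45, 208, c("C", "T")))[1]), 131 / 592)
  expect_equal(unname(allele_frequencies(
    genotype_counts(7, 0, 0, c("A", "G")))), c(1, 0))
  expect_equal(unname(allele_frequencies(
    genotype_counts(70, 226, 0, c("A", "C")))[1]), 366 / 592)
  expect_error(allele_frequencies(
    structure(list(marker = "m", alleles = c("A", "C"),
                   counts = c(hom_first = 0L, het = 0L, hom_second = 0L),
                   n = 0L), class = "genotype_counts")),
    "empty cohort")
})

test_that("diversity indices satisfy their algebraic identities", {
  set.seed(1)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    p <- as.vector(stats::rgamma(k, 1)); p <- p / sum(p)
    di <- diversity_indices(p)
    expect_equal(di$Ho + di$He, 1)
    expect_equal(di$Ne * di$Ho, 1)
    expect_lte(di$PIC, di$He + 1e-12)
    expect_gte(di$PIC, 0)
    expect_lte(di$MAF, 0.5 + 1e-12)
  }
  # biallelic maximum at p = 0.5
  di <- diversity_indices(c(0.5, 0.5))
  expect_equal(di$He, 0.5)
  expect_equal(di$Ne, 2)
  expect_equal(di$PIC, 0.375)
  for (p in seq(0.05, 0.45, by = 0.05)) {
    expect_lt(diversity_indices(c(p, 1 - p))$PIC, 0.375)
  }
})

test_that("diversity indices reproduce the published values at reported
           frequency precision", {
  di <- diversity_indices(c(0.22, 0.78))
  expect_equal(round(di$Ho, 4), 0.6568)
  expect_equal(round(di$He, 4), 0.3432)
  expect_equal(round(di$Ne, 4), 1.5225)
  expect_equal(round(di$PIC, 4), 0.2843)
  expect_equal(round(diversity_indices(c(0.88, 0.12))$PIC, 4), 0.1889)
})

test_that("Hardy-Weinberg chi-square matches hand-checked statistics", {
  hw <- hwe_test(genotype_counts(43, 45, 208, c("C", "T")))
  expect_equal(hw$chi2, 92.452, tolerance = 2e-5)
  expect_equal(hw$df, 1L)
  expect_equal(sum(hw$expected_counts), 296)

  # counts exactly at HW expectations
  hw0 <- hwe_test(genotype_counts(25, 50, 25, c("A", "G")))
  expect_equal(hw0$chi2, 0)
  expect_equal(hw0$p_value, 1)

  # a zero observed class still contributes (0 - E)^2 / E
  hw1 <- hwe_test(genotype_counts(70, 226, 0, c("A", "C")))
  expect_equal(hw1$chi2, 112.861, tolerance = 2e-5)

  expect_error(hwe_test(genotype_counts(12, 0, 0, c("A", "G"))),
               "monomorphic")
})

test_that("the full published diversity table regenerates from genotype
           counts", {
  got <- popgen_summary_from_counts(holstein_genotype_counts(),
                                    freq_digits = 2)
  ref <- read.csv(test_path("fixtures", "diversity_published.csv"),
                  stringsAsFactors = FALSE)
  got <- got[match(ref$marker, got$marker), ]
  # chi-square from exact count-derived frequencies, 3 dp
  expect_lt(max(abs(got$chi2 - ref$chi2)), 1.5e-3)
  # indices from reported-precision frequencies, 4 dp (one source cell is
  # off by a final-digit rounding unit)
  expect_lt(max(abs(got$Ho - ref$Ho)), 1.5e-4)
  expect_lt(max(abs(got$He - ref$He)), 1.5e-4)
  expect_lt(max(abs(got$Ne - ref$Ne)), 1.5e-4)
  expect_lt(max(abs(got$PIC - ref$PIC)), 1.5e-4)
  expect_true(all(got$MAF <= 0.5))
})

test_that("popgen_summary works from raw long-format calls", {
  calls <- data.frame(
    animal_id = rep(sprintf("A%02d", 1:6), 2),
    marker = rep(c("m1", "m2"), each = 6),
    genotype = c("CC", "CT", "TT", "TT", "TC", "CC",
                 "AA", "AG", "GG", "AA", "GA", "AA")
  )
  s <- popgen_summary(calls)
  expect_equal(nrow(s), 2)
  expect_equal(s$n_het[s$marker == "m1"], 2L)
  expect_equal(s$p_first[s$marker == "m2"], 8 / 12)
})

test_that("the Hardy-Weinberg test holds its nominal type-I error", {
  set.seed(424242)
  n <- 296L
  p <- 0.3
  reps <- 1000L
  draws <- stats::rmultinom(reps, n, c(p^2, 2 * p * (1 - p), (1 - p)^2))
  rej <- vapply(seq_len(reps), function(i) {
    hwe_test(genotype_counts(draws[1, i], draws[2, i], draws[3, i],
                             c("A", "B")))$p_value < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
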