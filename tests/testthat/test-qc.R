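test_that("call rate counts non-missing calls", {
  expect_equal(call_rate(rep(1L, 40)), 1.0)
  expect_equal(call_rate(c(rep(0L, 38), NA, NA)), 0.95)
  expect_equal(call_rate(rep(NA_integer_, 5)), 0.0)
})

test_that("minor allele frequency folds to the rarer allele", {
  expect_equal(minor_allele_freq(c(0, 0, 0, 0)), 0)
  expect_equal(minor_allele_freq(c(2, 2, 2, 2)), 0)
  expect_equal(minor_allele_freq(c(0, 1, 1, 2)), 0.5)
  expect_equal(minor_allele_freq(c(0, 1, NA, NA)), 0.25)
  expect_error(minor_allele_freq(c(NA, NA)), "missing")
})

test_that("exact HWE p-value matches hand enumeration on (4, 0, 1)", {
  # support n_AB in {0, 2}: weights 5 and 40, so p = 5/45
  expect_equal(exact_hwe_p(4, 0, 1), 1 / 9, tolerance = 1e-12)
  expect_equal(exact_hwe_p(10, 0, 0), 1.0)
  expect_error(exact_hwe_p(0, 0, 0), "zero")
  expect_error(exact_hwe_p(2, -1, 1), "non-negative")
})

test_that("exact HWE agrees with the enumeration oracle up to n = 50", {
  set.seed(19)
  for (rep in 1:60) {
    n <- sample(2:50, 1)
    counts <- as.vector(stats::rmultinom(1, n, c(0.4, 0.4, 0.2)))
    expect_equal(exact_hwe_p(counts[1], counts[2], counts[3]),
                 oracle_hwe_p(counts[1], counts[2], counts[3]),
                 tolerance = 1e-12)
  }
})

test_that("exact HWE is symmetric in the homozygote counts", {
  set.seed(29)
  for (rep in 1:20) {
    counts <- as.vector(stats::rmultinom(1, sample(3:40, 1), c(0.3, 0.4, 0.3)))
    expect_equal(exact_hwe_p(counts[1], counts[2], counts[3]),
                 exact_hwe_p(counts[3], counts[2], counts[1]),
                 tolerance = 1e-12)
  }
})

test_that("stratified HWE reduces to the plain exact test for one stratum", {
  counts <- c(12, 9, 4)
  expect_equal(stratified_exact_hwe_p(matrix(counts, 1)),
               exact_hwe_p(counts[1], counts[2], counts[3]),
               tolerance = 1e-12)
})

test_that("strata at maximal conditional probability give p = 1", {
  # (1, 2, 1) attains the mode of its conditional distribution
  counts <- rbind(c(1, 2, 1), c(1, 2, 1))
  expect_equal(stratified_exact_hwe_p(counts), 1.0)
})

test_that("stratified HWE matches the two-stratum joint enumeration oracle", {
  set.seed(37)
  for (rep in 1:20) {
    c1 <- as.vector(stats::rmultinom(1, sample(4:10, 1), c(0.35, 0.4, 0.25)))
    c2 <- as.vector(stats::rmultinom(1, sample(4:10, 1), c(0.25, 0.45, 0.3)))
    expect_equal(stratified_exact_hwe_p(rbind(c1, c2)),
                 oracle_stratified_hwe_p(c1, c2),
                 tolerance = 1e-12)
  }
})

test_that("the Monte-Carlo fallback approximates the exact stratified p", {
  c1 <- c(6, 8, 6)
  c2 <- c(5, 9, 6)
  exact <- stratified_exact_hwe_p(rbind(c1, c2))
  mc <- stratified_exact_hwe_p(rbind(c1, c2), max_states = 1, n_mc = 2e5,
                               mc_seed = 5)
  expect_lt(abs(mc - exact), 0.01)
})

test_that("strand ambiguity flags A/T and C/G pairs only", {
  expect_true(flag_ambiguous_strand("A", "T"))
  expect_true(flag_ambiguous_strand("C", "G"))
  expect_false(flag_ambiguous_strand("A", "G"))
  expect_equal(flag_ambiguous_strand(c("G", "T"), c("C", "C")),
               c(TRUE, FALSE))
  expect_error(flag_ambiguous_strand("A", "N"), "alleles")
})

test_that("QC presets carry the documented thresholds", {
  popres <- qc_preset("popres")
  expect_equal(c(popres$min_call_rate, popres$min_maf, popres$min_hwe_p),
               c(0.95, 0.1, 0.01))
  life <- qc_preset("life")
  expect_equal(c(life$min_call_rate, life$min_maf, life$min_hwe_p),
               c(0.995, 0.2, 0.5))
})

test_that("each QC filter excludes exactly the SNP violating it", {
  set.seed(51)
  n <- 40
  good <- function() pmin(2L, stats::rbinom(n, 2, 0.5))
  g <- cbind(good(),                       # passes everything
             replace(good(), 1:3, NA),     # call rate 0.925 < 0.95
             rep(0:1, c(39, 1)),           # MAF 1/80 < 0.1
             rep(c(0L, 2L), each = 20))    # all homozygote: HWE p tiny
  gm <- make_test_gm(g, a0 = c("A", "A", "A", "C"),
                     a1 = c("G", "G", "G", "T"))
  qc <- select_hq_snps(gm, qc_preset("popres"))
  expect_equal(qc$is_hq, c(TRUE, FALSE, FALSE, FALSE))

  amb <- make_test_gm(g[, 1, drop = FALSE], a0 = "A", a1 = "T")
  expect_false(select_hq_snps(amb, qc_preset("popres"))$is_hq)
})

test_that("raising any QC threshold never adds SNPs to the HQ set", {
  set.seed(61)
  g <- matrix(stats::rbinom(40 * 30, 2, rep(runif(30, 0.05, 0.6), each = 40)),
              nrow = 40)
  g[sample(length(g), 40)] <- NA
  gm <- make_test_gm(g)
  base <- select_hq_snps(gm, qc_criteria(0.9, 0.05, 0.01))
  for (crit in list(qc_criteria(0.97, 0.05, 0.01),
                    qc_criteria(0.9, 0.2, 0.01),
                    qc_criteria(0.9, 0.05, 0.2))) {
    stricter <- select_hq_snps(gm, crit)
    expect_true(all(stricter$is_hq <= base$is_hq))
  }
})
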