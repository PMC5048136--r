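test_that("HMM parameter ranges are enforced", {
  expect_error(hmm_params(error_rate = 0), "error_rate")
  expect_error(hmm_params(error_rate = 0.5), "error_rate")
  expect_error(hmm_params(switch_prob = 0), "switch_prob")
  expect_s3_class(hmm_params(0.01, 0.001, "prephased"), "hmm_params")
})

test_that("joint posteriors match the exhaustive path-sum oracle", {
  eps <- 0.05
  rho <- 0.1
  # K = 2, L = 3, middle SNP masked
  H <- matrix(c(0L, 1L, 1L,
                1L, 0L, 1L), 2, 3, byrow = TRUE)
  g <- c(1L, NA, 2L)
  pt <- impute_joint(make_test_gm(matrix(g, 1)), make_test_panel(H),
                     hmm_params(eps, rho))
  for (s in 1:3) {
    expect_equal(posterior_triple(pt, 1, s),
                 oracle_joint_posterior(g, H, eps, rho, s),
                 tolerance = 1e-10)
  }
  # K = 3, L = 5, two masked SNPs, different parameters
  set.seed(77)
  H2 <- matrix(rbinom(15, 1, 0.5), 3, 5)
  g2 <- c(0L, NA, 1L, NA, 2L)
  pt2 <- impute_joint(make_test_gm(matrix(g2, 1)), make_test_panel(H2),
                      hmm_params(0.02, 0.3))
  for (s in c(2, 4)) {
    expect_equal(posterior_triple(pt2, 1, s),
                 oracle_joint_posterior(g2, H2, 0.02, 0.3, s),
                 tolerance = 1e-10)
  }
})

test_that("haploid posteriors match the haploid path-sum oracle", {
  set.seed(78)
  H <- matrix(rbinom(12, 1, 0.5), 2, 6)
  h <- c(0L, NA, 1L, NA, NA, 1L)
  pa <- imputeval:::haploid_fb(h, H, 0.03, 0.2)
  for (s in 1:6) {
    expect_equal(pa[s], oracle_haploid_posterior(h, H, 0.03, 0.2, s),
                 tolerance = 1e-10)
  }
})

test_that("a degenerate panel forces a point-mass posterior", {
  H <- matrix(1L, 4, 3)
  g <- c(2L, NA, 2L)
  pt <- impute_joint(make_test_gm(matrix(g, 1)), make_test_panel(H))
  expect_equal(posterior_triple(pt, 1, 2), c(0, 0, 1))
})

test_that("posterior triples are normalized at every cell", {
  set.seed(91)
  p <- runif(60, 0.2, 0.8)
  panel <- simulate_panel(p, 20, 10, 0.05, seed = 92)
  tg <- simulate_targets(panel, 6, 0.05, seed = 93)
  g <- tg$genotypes
  g[, seq(1, 60, by = 3)] <- NA
  masked <- genotype_matrix(g, tg$snp_info, tg$individual_ids)
  for (pt in list(impute_joint(masked, panel),
                  impute(masked, panel, hmm_params(mode = "prephased")))) {
    sums <- pt$probs[, , 1] + pt$probs[, , 2] + pt$probs[, , 3]
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_true(all(pt$probs >= 0))
  }
})

test_that("joint posteriors are invariant under panel reordering", {
  set.seed(95)
  H <- matrix(rbinom(8 * 12, 1, 0.5), 8, 12)
  g <- matrix(c(rbinom(6, 2, 0.5), NA, NA, rbinom(4, 2, 0.5)), 1)
  pt1 <- impute_joint(make_test_gm(g), make_test_panel(H))
  perm <- sample(8)
  pt2 <- impute_joint(make_test_gm(g), make_test_panel(H[perm, ]))
  expect_equal(pt1$probs, pt2$probs, tolerance = 1e-10)
})

test_that("prephasing recovers unambiguous mosaic haplotypes", {
  set.seed(101)
  p <- runif(120, 0.2, 0.8)
  panel <- simulate_panel(p, 16, 8, 0.02, seed = 102)
  tg <- simulate_targets(panel, 8, 0.005, seed = 103)
  truth <- attr(tg, "true_haplotypes")
  haps <- prephase(tg, panel, hmm_params(0.01, 0.001, "prephased"))
  # haplotypes are recovered up to within-individual swap
  acc <- vapply(1:8, function(i) {
    direct <- mean(haps$h1[i, ] == truth$h1[i, ]) +
      mean(haps$h2[i, ] == truth$h2[i, ])
    swapped <- mean(haps$h1[i, ] == truth$h2[i, ]) +
      mean(haps$h2[i, ] == truth$h1[i, ])
    max(direct, swapped) / 2
  }, numeric(1))
  expect_gt(mean(acc), 0.98)
})

test_that("a fully homozygous target phases into identical haplotypes", {
  H <- rbind(c(0L, 1L, 0L, 1L), c(0L, 1L, 0L, 1L), c(1L, 0L, 1L, 0L))
  g <- matrix(c(0L, 2L, 0L, 2L), 1)
  haps <- prephase(make_test_gm(g), make_test_panel(H))
  expect_identical(haps$h1, haps$h2)
  expect_equal(drop(haps$h1), c(0L, 1L, 0L, 1L))
})

test_that("prephasing and imputation are deterministic", {
  set.seed(111)
  p <- runif(50, 0.3, 0.7)
  panel <- simulate_panel(p, 12, 6, 0.05, seed = 112)
  tg <- simulate_targets(panel, 4, 0.05, seed = 113)
  g <- tg$genotypes
  g[, 1:20] <- NA
  masked <- genotype_matrix(g, tg$snp_info, tg$individual_ids)
  r1 <- impute(masked, panel, hmm_params(mode = "prephased"))
  r2 <- impute(masked, panel, hmm_params(mode = "prephased"))
  expect_identical(r1$probs, r2$probs)
})

test_that("imputer rejects degenerate inputs", {
  H <- matrix(rbinom(10, 1, 0.5), 2, 5)
  panel <- make_test_panel(H)
  all_missing <- make_test_gm(matrix(NA_integer_, 1, 5))
  expect_error(impute_joint(all_missing, panel), "typed")
  one_hap <- make_test_panel(H[1, , drop = FALSE])
  expect_error(impute_joint(make_test_gm(matrix(0L, 1, 5)), one_hap),
               "at least 2")
})
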