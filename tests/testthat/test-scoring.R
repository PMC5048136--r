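test_that("Hellinger score evaluates its closed form", {
  expect_equal(hellinger_score(2, c(0, 0, 1)), 1.0)
  expect_equal(hellinger_score(0, c(0.48650625, 0.51349375, 0)), 0.45,
               tolerance = 1e-9)
  expect_equal(hellinger_score(1, rep(1 / 3, 3)),
               1 - sqrt(1 - sqrt(1 / 3)), tolerance = 1e-12)
  expect_error(hellinger_score(0, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("score cutoff 0.45 calibrates to a 0.49 best-guess posterior", {
  q_min <- hellinger_cutoff_posterior(0.45)
  expect_equal(q_min, 0.48650625, tolerance = 1e-8)
  expect_equal(round(q_min, 2), 0.49)
  # the identity holds from both directions
  expect_gte(hellinger_score(2, c(0, 1 - q_min, q_min)), 0.45)
  expect_lt(hellinger_score(2, c(0, 1 - q_min + 1e-6, q_min - 1e-6)), 0.45)
})

test_that("well-imputed genotypes always carry a confident posterior", {
  set.seed(131)
  for (rep in 1:200) {
    tri <- stats::runif(3)
    tri <- tri / sum(tri)
    g <- sample(0:2, 1)
    if (hellinger_score(g, tri) >= 0.45) {
      expect_gte(best_guess(tri)$prob, 0.48650625)
    }
  }
})

test_that("SEN score compares expected dosages on the scale of 2", {
  expect_equal(sen_score(2, c(0.1, 0.2, 0.7)), 0.8)
  expect_equal(sen_score(1, c(0.25, 0.5, 0.25)), 1.0)
  expect_equal(sen_score(0, c(0, 0, 1)), 0.0)
})

test_that("Hellinger and SEN increase with the true-genotype posterior", {
  qs <- seq(0.05, 0.95, by = 0.05)
  hs <- vapply(qs, function(q) {
    hellinger_score(2, c((1 - q) / 2, (1 - q) / 2, q))
  }, numeric(1))
  sen <- vapply(qs, function(q) {
    sen_score(2, c((1 - q) / 2, (1 - q) / 2, q))
  }, numeric(1))
  expect_true(all(diff(hs) > 0))
  expect_true(all(diff(sen) > 0))
})

test_that("best guess takes the argmax with ties toward the smaller code", {
  expect_equal(best_guess(c(0.5, 0.3, 0.2)), list(genotype = 0L, prob = 0.5))
  expect_equal(best_guess(c(0.4, 0.4, 0.2)), list(genotype = 0L, prob = 0.4))
  set.seed(141)
  for (rep in 1:50) {
    tri <- stats::runif(3)
    tri <- tri / sum(tri)
    expect_equal(best_guess(tri)$genotype,
                 (0:2)[tri == max(tri)][1])
  }
})

test_that("MaCH-Rsq is the dosage variance over the binomial variance", {
  expect_equal(mach_rsq(rep(1.2, 10)), 0)
  expect_equal(mach_rsq(c(0, 1, 1, 2)), 1.0)
  set.seed(151)
  for (rep in 1:20) {
    d <- stats::runif(sample(5:40, 1), 0, 2)
    p <- mean(d) / 2
    expect_equal(mach_rsq(d), (mean(d^2) - mean(d)^2) / (2 * p * (1 - p)),
                 tolerance = 1e-12)
  }
})

test_that("IMPUTE-info matches its formula and handles point masses", {
  n <- 10
  point <- matrix(rep(c(0, 1, 0), each = n), n, 3)
  expect_equal(impute_info(point), 1.0)
  flat <- matrix(1 / 3, 5, 3)
  # e = 1, f = 5/3, theta = 1/2: info = 1 - (5/3 - 1) / (1/2) = -1/3
  expect_equal(impute_info(flat), -1 / 3, tolerance = 1e-12)
  set.seed(161)
  q <- t(apply(matrix(stats::runif(30), 10, 3), 1, function(x) x / sum(x)))
  e <- q[, 2] + 2 * q[, 3]
  f <- q[, 2] + 4 * q[, 3]
  th <- sum(e) / 20
  expect_equal(impute_info(q), 1 - sum(f - e^2) / (20 * th * (1 - th)),
               tolerance = 1e-12)
})

test_that("dosage r-squared behaves like squared Pearson correlation", {
  truth <- c(0, 1, 2, 1, 0, 2)
  expect_equal(dosage_r2(truth, truth), 1.0)
  expect_equal(dosage_r2(truth, 2 - truth), 1.0)
  expect_warning(r <- dosage_r2(rep(1, 5), stats::runif(5)), "constant")
  expect_true(is.na(r))
  set.seed(171)
  g <- stats::rbinom(30, 2, 0.5)
  d <- pmin(2, pmax(0, g + stats::rnorm(30, 0, 0.4)))
  num <- sum((g - mean(g)) * (d - mean(d)))
  den <- sqrt(sum((g - mean(g))^2) * sum((d - mean(d))^2))
  expect_equal(dosage_r2(g, d), (num / den)^2, tolerance = 1e-12)
})

test_that("score records count a constructed mixture correctly", {
  # 3 individuals x 2 masked SNPs with known posteriors
  probs <- array(0, c(3, 2, 3))
  probs[1, 1, ] <- c(1, 0, 0)      # correct point mass
  probs[2, 1, ] <- c(0.2, 0.6, 0.2) # correct but uncertain
  probs[3, 1, ] <- c(0.7, 0.2, 0.1) # wrong best guess
  probs[1, 2, ] <- c(0, 0, 1)
  probs[2, 2, ] <- c(1 / 3, 1 / 3, 1 / 3) # tie -> guess 0, wrong
  probs[3, 2, ] <- c(0.05, 0.9, 0.05)     # wrong (truth 2)
  si <- data.frame(id = c("rsA", "rsB"), pos = c(100, 200),
                   a0 = "A", a1 = "G")
  pt <- posterior_table(probs, si, c("i1", "i2", "i3"))
  truth <- data.frame(individual = rep(c("i1", "i2", "i3"), 2),
                      snp_id = rep(c("rsA", "rsB"), each = 3),
                      true_genotype = c(0L, 1L, 1L, 2L, 2L, 2L))
  rec <- score_imputation(truth, pt, cutoff = 0.45)
  expect_equal(rec$correct, c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  # q_true = 1, .6, .2, 1, 1/3, .05
  expect_equal(rec$hellinger,
               1 - sqrt(1 - sqrt(c(1, 0.6, 0.2, 1, 1 / 3, 0.05))),
               tolerance = 1e-12)
  sm <- summarize_scores(rec)
  expect_equal(sm$n, 6)
  expect_equal(sm$pct_correct_best_guess, 50)
  expect_equal(sm$pct_well_imputed, 100 * mean(rec$hellinger >= 0.45))
  all_correct <- summarize_scores(rec[c(1, 4), ])
  expect_equal(all_correct$pct_well_imputed, 100)
  expect_equal(all_correct$pct_correct_best_guess, 100)
  expect_equal(summarize_scores(rec, cutoff = 0)$pct_well_imputed, 100)
})

test_that("per-SNP software scores track the objective dosage r-squared", {
  set.seed(181)
  p <- runif(300, 0.2, 0.8)
  panel <- simulate_panel(p, 40, 20, 0.02, seed = 182)
  tg <- simulate_targets(panel, 30, 0.02, seed = 183)
  masked_ids <- tg$snp_info$id[seq(1, 300, by = 2)]
  m <- apply_mask(tg, masked_ids)
  pt <- impute_joint(m$masked, panel, hmm_params(0.01, 0.005))
  rec <- score_imputation(m$truth, pt)
  per_snp <- snp_scores(rec, pt)
  keep <- !is.na(per_snp$dosage_r2) & !is.na(per_snp$mach_rsq)
  expect_gte(sum(keep), 100)
  expect_gt(cor(per_snp$mach_rsq[keep], per_snp$dosage_r2[keep],
                method = "spearman"), 0)
})
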