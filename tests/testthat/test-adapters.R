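random_pt <- function(n = 4, L = 6, seed = 301) {
  set.seed(seed)
  probs <- array(stats::runif(n * L * 3), c(n, L, 3))
  sums <- probs[, , 1] + probs[, , 2] + probs[, , 3]
  for (g in 1:3) probs[, , g] <- probs[, , g] / sums
  probs <- round(probs, 4)
  probs[, , 3] <- 1 - probs[, , 1] - probs[, , 2]
  si <- data.frame(id = sprintf("rs%03d", seq_len(L)),
                   pos = seq_len(L) * 1500L, a0 = "A", a1 = "G",
                   stringsAsFactors = FALSE)
  posterior_table(probs, si, sprintf("i%02d", seq_len(n)),
                  source_label = "test")
}

test_that("MaCH files round-trip within write precision", {
  pt <- random_pt()
  prefix <- withr::local_tempfile()
  write_mach(pt, prefix)
  back <- read_mach(paste0(prefix, ".mlprob"), paste0(prefix, ".mlinfo"),
                    snp_info = pt$snp_info)
  expect_equal(back$probs, pt$probs, tolerance = 1e-6)
  expect_equal(back$individual_ids, pt$individual_ids)
  expect_equal(back$snp_quality$rsq,
               unname(round(apply(pt$dosages, 2, mach_rsq), 4)),
               tolerance = 1e-6)
  dose_only <- read_mach(NULL, paste0(prefix, ".mlinfo"),
                         mldose_path = paste0(prefix, ".mldose"),
                         snp_info = pt$snp_info)
  expect_false(dose_only$has_triples)
  expect_equal(dose_only$dosages, pt$dosages, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("the stored mlprob pair implies the complementary third", {
  lines <- c("s1->s1 ML_PROB 0.1000 0.2000",
             "s2->s2 ML_PROB 0.5000 0.5000")
  info <- data.frame(SNP = "rs001", Al1 = "A", Al2 = "G", Freq1 = 0.5,
                     MAF = 0.5, Quality = 1, Rsq = 0.9)
  prob_path <- withr::local_tempfile()
  info_path <- withr::local_tempfile()
  writeLines(lines, prob_path)
  write.table(info, info_path, sep = "\t", quote = FALSE, row.names = FALSE)
  pt <- read_mach(prob_path, info_path)
  expect_equal(posterior_triple(pt, 1, 1), c(0.1, 0.2, 0.7))
  expect_equal(posterior_triple(pt, 2, 1), c(0.5, 0.5, 0.0))
})

test_that("malformed MaCH rows report their line number", {
  lines <- c("s1->s1 ML_PROB 0.1000 0.2000",
             "s2->s2 ML_PROB 0.5000")
  info <- data.frame(SNP = "rs001", Al1 = "A", Al2 = "G", Freq1 = 0.5,
                     MAF = 0.5, Quality = 1, Rsq = 0.9)
  prob_path <- withr::local_tempfile()
  info_path <- withr::local_tempfile()
  writeLines(lines, prob_path)
  write.table(info, info_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_mach(prob_path, info_path), "line 2")
})

test_that("IMPUTE2 .gen files round-trip with their info scores", {
  pt <- random_pt(seed = 311)
  gen <- withr::local_tempfile(fileext = ".gen")
  info <- withr::local_tempfile(fileext = "_info.txt")
  write_impute2(pt, gen, info)
  back <- read_impute2(gen, info, individual_ids = pt$individual_ids)
  expect_equal(back$probs, pt$probs, tolerance = 1e-3)
  expect_equal(back$snp_info$id, pt$snp_info$id)
  expect_equal(back$snp_quality$info,
               round(vapply(seq_len(6), function(j) impute_info(pt$probs[, j, ]),
                            numeric(1)), 4),
               tolerance = 1e-6)
  # malformed row: drop one field
  lines <- readLines(gen)
  lines[3] <- sub(" [0-9.]+$", "", lines[3])
  writeLines(lines, gen)
  expect_error(read_impute2(gen), "line 3")
})

test_that("hap/legend and PLINK ped/map round-trip", {
  set.seed(321)
  p <- runif(12, 0.2, 0.8)
  panel <- simulate_panel(p, 8, 4, 0.1, seed = 322)
  prefix <- withr::local_tempfile()
  write_hap_legend(panel, prefix)
  back <- read_hap_legend(prefix)
  expect_equal(back$haplotypes, panel$haplotypes, ignore_attr = TRUE)
  expect_equal(back$snp_info, panel$snp_info)

  tg <- simulate_targets(panel, 6, 0.1, seed = 323)
  tg$genotypes[2, 3] <- NA
  prefix2 <- withr::local_tempfile()
  write_plink(tg, prefix2)
  back2 <- read_plink(prefix2, snp_info = tg$snp_info)
  expect_equal(back2$genotypes, tg$genotypes, ignore_attr = TRUE)
  expect_equal(back2$individual_ids, tg$individual_ids)
})

test_that("VCF GP fields become posterior triples, DS-only becomes dosage", {
  skip_if_not_installed("vcfR")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Posteriors\">",
              "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2")
  body_gp <- c("22\t100\trs1\tA\tG\t.\tPASS\t.\tGT:GP:DS\t0/0:0.9,0.1,0:0.1\t0/1:0.2,0.5,0.3:1.1",
               "22\t200\trs2\tC\tT\t.\tPASS\t.\tGT:GP:DS\t1/1:0,0.1,0.9:1.9\t0/0:1,0,0:0")
  vcf_path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(header, body_gp), vcf_path)
  pt <- read_vcf_posteriors(vcf_path)
  expect_true(pt$has_triples)
  expect_equal(posterior_triple(pt, "s1", "rs1"), c(0.9, 0.1, 0))
  expect_equal(pt$dosages["s2", "rs1"], 1.1, tolerance = 1e-6)

  body_ds <- c("22\t100\trs1\tA\tG\t.\tPASS\t.\tGT:DS\t0/0:0.3\t0/1:1.3",
               "22\t200\trs2\tC\tT\t.\tPASS\t.\tGT:DS\t1/1:1.8\t0/0:0.2")
  writeLines(c(header[-3], body_ds), vcf_path)
  pt2 <- read_vcf_posteriors(vcf_path)
  expect_false(pt2$has_triples)
  expect_equal(pt2$dosages["s2", "rs1"], 1.3)

  # conflicting GP and DS beyond 1e-3 warns
  body_bad <- c("22\t100\trs1\tA\tG\t.\tPASS\t.\tGT:GP:DS\t0/0:0.9,0.1,0:0.5\t0/1:0.2,0.5,0.3:1.1")
  writeLines(c(header, body_bad), vcf_path)
  expect_warning(read_vcf_posteriors(vcf_path), "disagree")
})

test_that("posterior tables validate and renormalize triples", {
  si <- data.frame(id = "rs1", pos = 1L, a0 = "A", a1 = "G")
  near <- array(c(0.5, 0.3, 0.2005), c(1, 1, 3))
  pt <- posterior_table(near, si, "i1")
  expect_equal(sum(pt$probs[1, 1, ]), 1, tolerance = 1e-12)
  off <- array(c(0.5, 0.3, 0.3), c(1, 1, 3))
  expect_error(posterior_table(off, si, "i1"), "sum 1")
  expect_error(posterior_table(NULL, si, "i1"), "probs or dosages")
})
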