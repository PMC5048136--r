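#' SNP call rate
#'
#' Fraction of non-missing genotype calls in a column.
#'
#' @param genotype_column vector of genotypes (0/1/2/NA).
#' @return fraction in \[0, 1\].
#' @export
call_rate <- function(genotype_column) {
  if (length(genotype_column) < 1) stop("empty genotype column")
  mean(!is.na(genotype_column))
}

#' Minor allele frequency
#'
#' Computed from non-missing calls only: with p the frequency of the counted
#' allele, the MAF is `min(p, 1 - p)`.
#'
#' @param genotype_column vector of genotypes (0/1/2/NA).
#' @return fraction in \[0, 0.5\].
#' @export
minor_allele_freq <- function(genotype_column) {
  g <- genotype_column[!is.na(genotype_column)]
  if (length(g) == 0) stop("cannot compute MAF: all genotypes missing")
  p <- sum(g) / (2 * length(g))
  min(p, 1 - p)
}

# Conditional (Levene-Haldane) distribution of the heterozygote count given
# the sample size and allele counts: P(n_AB) proportional to
# n! / (n_AA! n_AB! n_BB!) * 2^n_AB. Returns the support and normalized
# probabilities.
hwe_conditional <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  n_a <- 2 * n_AA + n_AB          # copies of the first allele
  n_b <- 2 * n_BB + n_AB
  n_min <- min(n_a, n_b)
  support <- seq.int(n_min %% 2, n_min, by = 2)
  log_w <- lgamma(n + 1) - lgamma((n_a - support) / 2 + 1) -
    lgamma(support + 1) - lgamma((n_b - support) / 2 + 1) +
    support * log(2)
  log_w <- log_w - max(log_w)
  probs <- exp(log_w) / sum(exp(log_w))
  list(support = support, probs = probs,
       observed = match(n_AB, support))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the sample size and the allele counts, the
#' heterozygote count follows the Levene-Haldane distribution. The p-value
#' is the total probability of heterozygote counts whose conditional
#' probability does not exceed that of the observed count (probability
#' ordering, two-sided; no mid-p).
#'
#' @param n_AA,n_AB,n_BB non-negative integer genotype counts.
#' @return p-value in (0, 1\].
#' @export
exact_hwe_p <- function(n_AA, n_AB, n_BB) {
  counts <- c(n_AA, n_AB, n_BB)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("all genotype counts are zero")
  cond <- hwe_conditional(n_AA, n_AB, n_BB)
  p_obs <- cond$probs[cond$observed]
  sum(cond$probs[cond$probs <= p_obs * (1 + 1e-9)])
}

#' Exact stratified Hardy-Weinberg equilibrium test
#'
#' Strata (e.g. separate populations typed on the same SNP) are treated as
#' independent, each with its own Levene-Haldane conditional null. The test
#' statistic is the product of within-stratum conditional probabilities of
#' the observed heterozygote counts; the p-value is the null probability of
#' a joint configuration with a product at most as large as observed. The
#' joint null is evaluated by exact convolution while the number of joint
#' configurations stays below `max_states`, and by seeded Monte-Carlo
#' sampling (`n_mc` draws) above it.
#'
#' @param per_stratum_counts matrix with columns (n_AA, n_AB, n_BB), one row
#'   per stratum; or a list of length-3 count vectors.
#' @param max_states largest exactly-enumerated joint state space.
#' @param n_mc Monte-Carlo draws used beyond `max_states`.
#' @param mc_seed seed for the Monte-Carlo fallback.
#' @return p-value in (0, 1\].
#' @export
stratified_exact_hwe_p <- function(per_stratum_counts, max_states = 2e5,
                                   n_mc = 1e5, mc_seed = 1L) {
  if (is.list(per_stratum_counts)) {
    per_stratum_counts <- do.call(rbind, per_stratum_counts)
  }
  per_stratum_counts <- as.matrix(per_stratum_counts)
  if (nrow(per_stratum_counts) == 0) stop("no strata supplied")
  keep <- rowSums(per_stratum_counts) > 0
  if (!any(keep)) stop("all strata are empty")
  per_stratum_counts <- per_stratum_counts[keep, , drop = FALSE]

  conds <- lapply(seq_len(nrow(per_stratum_counts)), function(i) {
    hwe_conditional(per_stratum_counts[i, 1], per_stratum_counts[i, 2],
                    per_stratum_counts[i, 3])
  })
  obs_log <- sum(vapply(conds, function(cn) log(cn$probs[cn$observed]),
                        numeric(1)))
  n_states <- prod(vapply(conds, function(cn) length(cn$support), numeric(1)))

  if (n_states <= max_states) {
    # exact convolution of per-stratum log-probabilities
    atoms_log <- 0
    atoms_p <- 1
    for (cn in conds) {
      atoms_log <- outer(atoms_log, log(cn$probs), `+`)
      atoms_p <- outer(atoms_p, cn$probs)
    }
    sum(atoms_p[atoms_log <= obs_log + 1e-9])
  } else {
    set.seed(mc_seed)
    draws_log <- numeric(n_mc)
    for (cn in conds) {
      idx <- sample.int(length(cn$support), n_mc, replace = TRUE,
                        prob = cn$probs)
      draws_log <- draws_log + log(cn$probs)[idx]
    }
    mean(draws_log <= obs_log + 1e-9)
  }
}

#' Flag strand-ambiguous SNPs
#'
#' A/T and C/G SNPs cannot be strand-matched between platforms and are
#' removed before defining HQ SNPs.
#'
#' @param a0,a1 allele characters (A/C/G/T), vectorized.
#' @return logical vector, `TRUE` for ambiguous pairs.
#' @export
flag_ambiguous_strand <- function(a0, a1) {
  a0 <- toupper(a0); a1 <- toupper(a1)
  if (!all(a0 %in% c("A", "C", "G", "T")) ||
      !all(a1 %in% c("A", "C", "G", "T"))) {
    stop("alleles must be A, C, G or T")
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  unname(comp[a0] == a1)
}

#' QC criteria for defining high-quality SNPs
#'
#' Presets: `"popres"` uses call rate >= 0.95, MAF >= 0.1 and exact HWE
#' p >= 0.01; `"life"` uses call rate >= 0.995, MAF >= 0.2 and exact HWE
#' p >= 0.5.
#'
#' @param min_call_rate,min_maf,min_hwe_p thresholds in \[0, 1\].
#' @param preset_name label carried into reports.
#' @return An object of class `qc_criteria`.
#' @export
qc_criteria <- function(min_call_rate, min_maf, min_hwe_p,
                        preset_name = "custom") {
  vals <- c(min_call_rate, min_maf, min_hwe_p)
  if (any(vals < 0) || any(vals > 1)) stop("thresholds must lie in [0, 1]")
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 min_hwe_p = min_hwe_p, preset_name = preset_name),
            class = "qc_criteria")
}

#' @rdname qc_criteria
#' @param preset `"popres"` or `"life"`.
#' @export
qc_preset <- function(preset = c("popres", "life")) {
  preset <- match.arg(preset)
  switch(preset,
         popres = qc_criteria(0.95, 0.10, 0.01, "popres"),
         life   = qc_criteria(0.995, 0.20, 0.50, "life"))
}

#' Select high-quality SNPs
#'
#' Computes call rate, MAF, exact (optionally stratified) HWE p-value and
#' the strand-ambiguity flag for every SNP, and marks as HQ those SNPs that
#' pass all thresholds and are not strand-ambiguous. HQ SNPs are the ones
#' whose observed genotypes are treated as truth for masking and
#' re-imputation.
#'
#' @param gm a [genotype_matrix()].
#' @param criteria a [qc_criteria()] (see [qc_preset()]).
#' @param strata optional factor of length `nrow(gm$genotypes)` assigning
#'   individuals to populations; when supplied the stratified exact HWE test
#'   is used.
#' @return data.frame with one row per SNP: `snp_id`, `call_rate`, `maf`,
#'   `hwe_p`, `ambiguous_strand`, `is_hq`; filter pass counts in the
#'   `"filter_counts"` attribute.
#' @export
select_hq_snps <- function(gm, criteria = qc_preset("popres"),
                           strata = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(criteria, "qc_criteria"))
  g <- gm$genotypes
  n_snps <- ncol(g)
  cr <- apply(g, 2, call_rate)
  maf <- apply(g, 2, function(col) {
    if (all(is.na(col))) NA_real_ else minor_allele_freq(col)
  })
  hwe <- vapply(seq_len(n_snps), function(j) {
    col <- g[, j]
    if (all(is.na(col))) return(NA_real_)
    if (is.null(strata)) {
      exact_hwe_p(sum(col == 0, na.rm = TRUE), sum(col == 1, na.rm = TRUE),
                  sum(col == 2, na.rm = TRUE))
    } else {
      counts <- t(vapply(split(col, strata), function(x) {
        c(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
          sum(x == 2, na.rm = TRUE))
      }, numeric(3)))
      counts <- counts[rowSums(counts) > 0, , drop = FALSE]
      if (nrow(counts) == 0) return(NA_real_)
      stratified_exact_hwe_p(counts)
    }
  }, numeric(1))
  ambiguous <- flag_ambiguous_strand(gm$snp_info$a0, gm$snp_info$a1)

  pass_cr <- !is.na(cr) & cr >= criteria$min_call_rate
  pass_maf <- !is.na(maf) & maf >= criteria$min_maf
  pass_hwe <- !is.na(hwe) & hwe >= criteria$min_hwe_p
  is_hq <- pass_cr & pass_maf & pass_hwe & !ambiguous

  out <- data.frame(snp_id = gm$snp_info$id, call_rate = cr, maf = maf,
                    hwe_p = hwe, ambiguous_strand = ambiguous, is_hq = is_hq,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "filter_counts") <- c(
    call_rate = sum(pass_cr), maf = sum(pass_maf), hwe = sum(pass_hwe),
    unambiguous = sum(!ambiguous), hq = sum(is_hq)
  )
  attr(out, "criteria") <- criteria
  out
}

#' Write a SNP QC report as TSV
#'
#' @param qc data.frame from [select_hq_snps()].
#' @param path output file path.
#' @export
write_qc_report <- function(qc, path) {
  utils::write.table(qc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
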