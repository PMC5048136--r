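#' Draw subpopulation allele frequencies under the Balding-Nichols model
#'
#' Each subpopulation frequency is drawn from a Beta distribution with mean
#' equal to the ancestral frequency `p` and variance `F p (1 - p)`, i.e.
#' shape parameters `p (1 - F) / F` and `(1 - p)(1 - F) / F`. For two demes
#' drawn independently at drift `F`, the expected multi-locus Nei's G_ST is
#' `(F/2) / (1 - F/2)`, which is how panels at a controlled genetic distance
#' from a target population are produced.
#'
#' @param ancestral_freqs numeric vector of ancestral frequencies, strictly
#'   inside (0, 1).
#' @param divergence_F drift parameter in \[0, 1).
#' @param seed optional integer seed.
#' @return numeric vector of subpopulation frequencies, clipped to
#'   `[1e-6, 1 - 1e-6]`.
#' @export
draw_subpopulation_freqs <- function(ancestral_freqs, divergence_F,
                                     seed = NULL) {
  if (any(ancestral_freqs <= 0) || any(ancestral_freqs >= 1)) {
    stop("ancestral frequencies must lie strictly inside (0, 1)")
  }
  if (divergence_F < 0 || divergence_F >= 1) {
    stop("divergence_F must lie in [0, 1)")
  }
  if (divergence_F == 0) return(ancestral_freqs)
  if (!is.null(seed)) set.seed(seed)
  k <- (1 - divergence_F) / divergence_F
  out <- stats::rbeta(length(ancestral_freqs),
                      shape1 = ancestral_freqs * k,
                      shape2 = (1 - ancestral_freqs) * k)
  pmin(pmax(out, 1e-6), 1 - 1e-6)
}

# One mosaic copying path over n_sources templates: start uniform, switch to
# a uniform template between adjacent SNPs with probability switch_rate.
mosaic_path <- function(n_snps, n_sources, switch_rate) {
  path <- integer(n_snps)
  path[1] <- sample.int(n_sources, 1L)
  if (n_snps > 1L) {
    switches <- stats::runif(n_snps - 1L) < switch_rate
    for (s in 2L:n_snps) {
      path[s] <- if (switches[s - 1L]) sample.int(n_sources, 1L) else path[s - 1L]
    }
  }
  path
}

default_snp_info <- function(n_snps, chrom_length = 35e6, alleles = NULL) {
  pos <- sort(sample.int(chrom_length, n_snps))
  # unambiguous (non A/T, non C/G) pairs by default so strand QC keeps them
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2,
                  byrow = TRUE)
  pick <- sample.int(nrow(pairs), n_snps, replace = TRUE)
  data.frame(id = sprintf("snp%05d", seq_len(n_snps)), pos = pos,
             a0 = pairs[pick, 1], a1 = pairs[pick, 2],
             stringsAsFactors = FALSE)
}

#' Simulate a phased haplotype panel with linkage disequilibrium
#'
#' Founder haplotypes are drawn SNP-wise independently from the population
#' allele frequencies; every panel haplotype is then a mosaic that copies one
#' founder at a time, switching to a uniformly chosen founder between
#' adjacent SNPs with probability `switch_rate`. Small switch rates give the
#' long shared stretches (LD) that copying-model imputation exploits.
#'
#' @param pop_freqs per-SNP alternative-allele frequencies.
#' @param n_haplotypes number of panel haplotypes to emit.
#' @param n_founders number of founder haplotypes (>= 1; LD is degenerate
#'   with a single founder, which is allowed for toy cases).
#' @param switch_rate per-interval mosaic switch probability in \[0, 1\].
#' @param seed optional integer seed; identical seeds give identical panels.
#' @param snp_info optional SNP metadata; generated on a 35-Mb
#'   chromosome-22-like interval when absent.
#' @return A [haplotype_panel()].
#' @export
simulate_panel <- function(pop_freqs, n_haplotypes, n_founders, switch_rate,
                           seed = NULL, snp_info = NULL) {
  if (n_founders < 1) stop("n_founders must be at least 1")
  if (switch_rate < 0 || switch_rate > 1) {
    stop("switch_rate must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  n_snps <- length(pop_freqs)
  if (is.null(snp_info)) snp_info <- default_snp_info(n_snps)
  founders <- matrix(
    stats::rbinom(n_founders * n_snps, 1L,
                  rep(pop_freqs, each = n_founders)),
    nrow = n_founders, ncol = n_snps
  )
  haps <- matrix(0L, n_haplotypes, n_snps)
  for (h in seq_len(n_haplotypes)) {
    path <- mosaic_path(n_snps, n_founders, switch_rate)
    haps[h, ] <- founders[cbind(path, seq_len(n_snps))]
  }
  haplotype_panel(haps, snp_info)
}

#' Simulate diploid target individuals as mosaics of a panel
#'
#' Each individual receives two haplotypes built as copying mosaics of the
#' panel haplotypes (same switch mechanism as [simulate_panel()]); the
#' genotype is their sum. The true haplotypes are retained in the
#' `"true_haplotypes"` attribute so downstream phasing/imputation can be
#' checked against a known truth.
#'
#' @param panel a [haplotype_panel()].
#' @param n_individuals number of diploid individuals (>= 1).
#' @param switch_rate per-interval mosaic switch probability.
#' @param seed optional integer seed.
#' @return A [genotype_matrix()] with attribute `true_haplotypes`, a list of
#'   two `n_individuals x L` binary matrices.
#' @export
simulate_targets <- function(panel, n_individuals, switch_rate, seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (nrow(panel$haplotypes) < 1) stop("panel is empty")
  if (n_individuals < 1) stop("n_individuals must be at least 1")
  if (switch_rate < 0 || switch_rate > 1) {
    stop("switch_rate must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  n_snps <- ncol(panel$haplotypes)
  k <- nrow(panel$haplotypes)
  h1 <- matrix(0L, n_individuals, n_snps)
  h2 <- matrix(0L, n_individuals, n_snps)
  for (i in seq_len(n_individuals)) {
    h1[i, ] <- panel$haplotypes[cbind(mosaic_path(n_snps, k, switch_rate),
                                      seq_len(n_snps))]
    h2[i, ] <- panel$haplotypes[cbind(mosaic_path(n_snps, k, switch_rate),
                                      seq_len(n_snps))]
  }
  gm <- genotype_matrix(h1 + h2, panel$snp_info)
  attr(gm, "true_haplotypes") <- list(h1 = h1, h2 = h2)
  gm
}

#' Pairwise LD (r-squared) between SNP columns
#'
#' Squared Pearson correlation between columns of a haplotype or genotype
#' matrix; monomorphic columns yield `NA`.
#'
#' @param mat haplotypes (0/1) or genotypes (0/1/2) in columns.
#' @return symmetric matrix of r-squared values.
#' @export
ld_r2 <- function(mat) {
  suppressWarnings(r <- stats::cor(mat, use = "pairwise.complete.obs"))
  r^2
}

#' Mean r-squared by SNP lag
#'
#' Used to check the LD decay of simulated panels: with a mosaic copying
#' model, nearby SNPs share founders more often than distant ones, so mean
#' r-squared decreases with lag.
#'
#' @param mat matrix of haplotypes/genotypes in columns.
#' @param lags integer vector of column lags.
#' @return named numeric vector of mean r-squared per lag.
#' @export
ld_decay <- function(mat, lags = c(1, 5, 20, 100)) {
  r2 <- ld_r2(mat)
  n <- ncol(mat)
  vapply(lags, function(l) {
    if (l >= n) return(NA_real_)
    idx <- seq_len(n - l)
    mean(r2[cbind(idx, idx + l)], na.rm = TRUE)
  }, numeric(1)) |> stats::setNames(paste0("lag", lags))
}
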