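#' Nei's G_ST between two populations
#'
#' Relative reduction of heterozygosity due to population subdivision. Per
#' locus, with equal population weights, `pbar = (p_a + p_b) / 2`,
#' `H_T = 2 pbar (1 - pbar)` and
#' `H_S = (2 p_a (1 - p_a) + 2 p_b (1 - p_b)) / 2`; the multi-locus value
#' is the ratio of sums `sum(H_T - H_S) / sum(H_T)` (Nei's recommended
#' aggregation). Loci with `H_T = 0` are uninformative and excluded.
#' Plug-in heterozygosity estimators are used, without small-sample
#' correction.
#'
#' @param freqs_a,freqs_b equal-length allele-frequency vectors in \[0, 1\].
#' @return An object of class `gst_result`: list with `gst`, per-locus
#'   `h_s` and `h_t`, and the number of informative loci.
#' @export
nei_gst <- function(freqs_a, freqs_b) {
  if (length(freqs_a) != length(freqs_b)) {
    stop("frequency vectors must have equal length")
  }
  if (any(freqs_a < 0 | freqs_a > 1) || any(freqs_b < 0 | freqs_b > 1)) {
    stop("frequencies must lie in [0, 1]")
  }
  pbar <- (freqs_a + freqs_b) / 2
  h_t <- 2 * pbar * (1 - pbar)
  h_s <- (2 * freqs_a * (1 - freqs_a) + 2 * freqs_b * (1 - freqs_b)) / 2
  keep <- h_t > 0
  if (!any(keep)) stop("no informative loci (all H_T are zero)")
  gst <- sum(h_t[keep] - h_s[keep]) / sum(h_t[keep])
  structure(list(gst = gst, h_s = h_s, h_t = h_t,
                 n_informative = sum(keep)),
            class = "gst_result")
}

#' @export
print.gst_result <- function(x, ...) {
  cat(sprintf("<gst_result> G_ST = %.5f over %d informative loci\n",
              x$gst, x$n_informative))
  invisible(x)
}

#' Allele frequencies of a genotype matrix or haplotype panel
#'
#' Frequency of the counted (alternative) allele per SNP, from non-missing
#' calls.
#'
#' @param x a [genotype_matrix()] or [haplotype_panel()].
#' @return numeric vector of per-SNP frequencies.
#' @export
allele_freqs <- function(x) {
  if (inherits(x, "genotype_matrix")) {
    colMeans(x$genotypes, na.rm = TRUE) / 2
  } else if (inherits(x, "haplotype_panel")) {
    colMeans(x$haplotypes)
  } else {
    stop("x must be a genotype_matrix or haplotype_panel")
  }
}

#' Select the best-matched reference panel by Nei's G_ST
#'
#' Computes Nei's G_ST between the target population (sample frequencies
#' from its genotypes) and every candidate panel (haplotype frequencies) on
#' the shared SNP grid, ranks the candidates, and flags whether the best
#' match is close enough to count as well matched (G_ST at most `cutoff`,
#' default 0.010 — the rough decision rule for preferring a specific over
#' an admixed reference).
#'
#' @param target a [genotype_matrix()].
#' @param candidate_panels named list of [haplotype_panel()] objects.
#' @param cutoff well-matched threshold on G_ST (default 0.010).
#' @return list with `ranking` (data.frame of panel, gst, n_snps in
#'   ascending G_ST order), `best` (panel name) and `well_matched` flag.
#'   Ties are broken by candidate order with a warning.
#' @export
select_reference <- function(target, candidate_panels, cutoff = 0.010) {
  stopifnot(inherits(target, "genotype_matrix"), length(candidate_panels) >= 1)
  if (is.null(names(candidate_panels))) {
    names(candidate_panels) <- sprintf("panel%d", seq_along(candidate_panels))
  }
  res <- lapply(names(candidate_panels), function(nm) {
    panel <- candidate_panels[[nm]]
    shared <- intersect(target$snp_info$id, panel$snp_info$id)
    if (length(shared) == 0) stop("no overlapping SNPs with panel ", nm)
    ft <- allele_freqs(target)[match(shared, target$snp_info$id)]
    fp <- allele_freqs(panel)[match(shared, panel$snp_info$id)]
    ok <- !is.na(ft) & !is.na(fp)
    data.frame(panel = nm, gst = nei_gst(ft[ok], fp[ok])$gst,
               n_snps = sum(ok), stringsAsFactors = FALSE)
  })
  ranking <- do.call(rbind, res)
  if (anyDuplicated(signif(ranking$gst, 12)) &&
      sum(ranking$gst == min(ranking$gst)) > 1) {
    warning("tied G_ST values; ties broken by candidate order")
  }
  ranking <- ranking[order(ranking$gst), , drop = FALSE]
  rownames(ranking) <- NULL
  list(ranking = ranking, best = ranking$panel[1],
       well_matched = ranking$gst[1] <= cutoff)
}
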