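#' Genotype matrix container
#'
#' Bundles an individuals-by-SNPs matrix of allele-count genotypes with SNP
#' metadata. Genotypes count copies of the alternative allele (`a1`), so each
#' entry is 0, 1, 2 or `NA` (missing / masked).
#'
#' @param genotypes integer or numeric matrix, individuals in rows, SNPs in
#'   columns; entries in \{0, 1, 2, NA\}.
#' @param snp_info data.frame with one row per SNP and columns `id`, `pos`
#'   (1-based bp, strictly increasing), `a0` (reference allele) and `a1`
#'   (alternative / counted allele).
#' @param individual_ids optional character vector of row labels.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, snp_info, individual_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  if (!all(is.na(genotypes) | genotypes %in% 0:2)) {
    stop("genotypes must be 0, 1, 2 or NA")
  }
  snp_info <- validate_snp_info(snp_info, ncol(genotypes))
  if (is.null(individual_ids)) {
    individual_ids <- sprintf("ind%04d", seq_len(nrow(genotypes)))
  }
  if (length(individual_ids) != nrow(genotypes)) {
    stop("individual_ids length must equal the number of rows")
  }
  storage.mode(genotypes) <- "integer"
  dimnames(genotypes) <- list(individual_ids, snp_info$id)
  structure(
    list(genotypes = genotypes, snp_info = snp_info,
         individual_ids = individual_ids),
    class = "genotype_matrix"
  )
}

#' Phased reference haplotype panel
#'
#' @param haplotypes binary matrix, haplotypes in rows, SNPs in columns.
#' @param snp_info as in [genotype_matrix()].
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haplotypes, snp_info) {
  haplotypes <- as.matrix(haplotypes)
  if (!all(haplotypes %in% 0:1)) stop("haplotype entries must be 0 or 1")
  snp_info <- validate_snp_info(snp_info, ncol(haplotypes))
  storage.mode(haplotypes) <- "integer"
  colnames(haplotypes) <- snp_info$id
  structure(
    list(haplotypes = haplotypes, snp_info = snp_info),
    class = "haplotype_panel"
  )
}

validate_snp_info <- function(snp_info, n_snps) {
  required <- c("id", "pos", "a0", "a1")
  if (!is.data.frame(snp_info) || !all(required %in% names(snp_info))) {
    stop("snp_info must be a data.frame with columns id, pos, a0, a1")
  }
  if (nrow(snp_info) != n_snps) {
    stop("snp_info rows must match the number of SNP columns")
  }
  if (anyDuplicated(snp_info$id)) stop("duplicate SNP ids")
  if (n_snps > 1 && any(diff(snp_info$pos) <= 0)) {
    stop("positions must be strictly increasing")
  }
  snp_info$id <- as.character(snp_info$id)
  rownames(snp_info) <- NULL
  snp_info
}

#' Genotype posterior table
#'
#' Holds per-(individual, SNP) genotype posterior triples (q0, q1, q2) —
#' probabilities of carrying 0, 1 or 2 copies of the counted allele — and the
#' derived allele dosages q1 + 2 q2. Some sources (MaCH `.mldose`, VCF `DS`)
#' provide dosages only; then `probs` is `NULL` and `has_triples` is `FALSE`.
#'
#' Triples whose sum deviates from 1 by at most `tol` are renormalized;
#' larger deviations are an error.
#'
#' @param probs numeric array `N x L x 3`, or `NULL` for dosage-only sources.
#' @param snp_info SNP metadata (see [genotype_matrix()]).
#' @param individual_ids character vector of length `N`.
#' @param dosages optional `N x L` matrix; computed from `probs` when absent.
#' @param source_label name of the producing framework or file.
#' @param snp_quality optional data.frame of per-SNP software scores
#'   (e.g. MaCH-Rsq, IMPUTE-info), one row per SNP.
#' @param tol renormalization tolerance for triple sums (default 1e-3).
#' @return An object of class `posterior_table`.
#' @export
posterior_table <- function(probs, snp_info, individual_ids,
                            dosages = NULL, source_label = "unknown",
                            snp_quality = NULL, tol = 1e-3) {
  if (!is.null(probs)) {
    probs <- unname(probs)
    if (length(dim(probs)) != 3L || dim(probs)[3] != 3L) {
      stop("probs must be an N x L x 3 array")
    }
    if (any(probs < -tol) || any(probs > 1 + tol)) {
      stop("posterior probabilities outside [0, 1] beyond tolerance")
    }
    sums <- probs[, , 1] + probs[, , 2] + probs[, , 3]
    if (any(abs(sums - 1) > tol)) {
      stop("posterior triples deviate from sum 1 by more than ", tol)
    }
    probs <- pmin(pmax(probs, 0), 1)
    sums <- probs[, , 1] + probs[, , 2] + probs[, , 3]
    for (g in 1:3) probs[, , g] <- probs[, , g] / sums
    if (is.null(dosages)) {
      dosages <- matrix(probs[, , 2] + 2 * probs[, , 3],
                        nrow = dim(probs)[1], ncol = dim(probs)[2])
    }
  } else if (is.null(dosages)) {
    stop("either probs or dosages must be supplied")
  }
  dosages <- as.matrix(dosages)
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE)) {
    stop("dosages must lie in [0, 2]")
  }
  snp_info <- validate_snp_info(snp_info, ncol(dosages))
  if (length(individual_ids) != nrow(dosages)) {
    stop("individual_ids length must equal the number of individuals")
  }
  dimnames(dosages) <- list(individual_ids, snp_info$id)
  structure(
    list(probs = probs, dosages = dosages, snp_info = snp_info,
         individual_ids = as.character(individual_ids),
         source_label = source_label, snp_quality = snp_quality,
         has_triples = !is.null(probs)),
    class = "posterior_table"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs (%.1f%% missing)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              100 * mean(is.na(x$genotypes))))
  invisible(x)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d haplotypes x %d SNPs\n",
              nrow(x$haplotypes), ncol(x$haplotypes)))
  invisible(x)
}

#' @export
print.posterior_table <- function(x, ...) {
  cat(sprintf("<posterior_table> %d individuals x %d SNPs, source '%s'%s\n",
              nrow(x$dosages), ncol(x$dosages), x$source_label,
              if (x$has_triples) "" else " (dosage-only)"))
  invisible(x)
}

#' Extract a posterior triple
#'
#' @param pt a [posterior_table()].
#' @param individual individual index or id.
#' @param snp SNP index or id.
#' @return numeric vector (q0, q1, q2).
#' @export
posterior_triple <- function(pt, individual, snp) {
  stopifnot(inherits(pt, "posterior_table"))
  if (!pt$has_triples) stop("table carries dosages only")
  if (is.character(individual)) {
    individual <- match(individual, pt$individual_ids)
  }
  if (is.character(snp)) snp <- match(snp, pt$snp_info$id)
  as.numeric(pt$probs[individual, snp, ])
}
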