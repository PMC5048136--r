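#' One-sided McNemar test on paired binary indicators
#'
#' Tests whether framework A's success rate exceeds framework B's using the
#' discordant pairs only: `b` counts units where only A succeeded, `c`
#' units where only B succeeded. The exact one-sided p-value is
#' `P(X >= b)` under `X ~ Binomial(b + c, 1/2)` when `b + c <= exact_max`;
#' above that a one-sided normal approximation
#' `p = 1 - Phi((b - c) / sqrt(b + c))` is used (no continuity
#' correction). `b + c = 0` gives p = 1.
#'
#' @param indicator_a,indicator_b equal-length logical/0-1 vectors, paired
#'   by unit (individual x masked SNP).
#' @param exact_max largest discordant count handled exactly (default 100).
#' @return list with `p_value`, `b`, `c` and `method`.
#' @export
mcnemar_one_sided <- function(indicator_a, indicator_b, exact_max = 100) {
  if (length(indicator_a) != length(indicator_b)) {
    stop("paired vectors must have equal length")
  }
  a <- as.logical(indicator_a)
  bb <- as.logical(indicator_b)
  keep <- !is.na(a) & !is.na(bb)
  b <- sum(a[keep] & !bb[keep])
  cc <- sum(!a[keep] & bb[keep])
  n <- b + cc
  if (n == 0) {
    return(list(p_value = 1, b = b, c = cc, method = "degenerate"))
  }
  if (n <= exact_max) {
    p <- stats::pbinom(b - 1, n, 0.5, lower.tail = FALSE)
    method <- "exact binomial"
  } else {
    p <- stats::pnorm((b - cc) / sqrt(n), lower.tail = FALSE)
    method <- "normal approximation"
  }
  list(p_value = p, b = b, c = cc, method = method)
}

#' One-sided Wilcoxon signed-rank test on paired scores
#'
#' Tests whether scores under A tend to exceed those under B. Zero
#' differences are dropped. The exact signed-rank null is used for at most
#' `exact_max` non-zero differences without ties in their absolute values;
#' otherwise the normal approximation with tie correction (and continuity
#' correction) is used.
#'
#' @param scores_a,scores_b equal-length paired numeric vectors.
#' @param exact_max largest exact sample size (default 25).
#' @return list with `p_value`, `n_nonzero` and `method`.
#' @export
wilcoxon_one_sided <- function(scores_a, scores_b, exact_max = 25) {
  if (length(scores_a) != length(scores_b)) {
    stop("paired vectors must have equal length")
  }
  d <- scores_a - scores_b
  d <- d[!is.na(d)]
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all paired differences are zero")
    return(list(p_value = 1, n_nonzero = 0L, method = "degenerate"))
  }
  use_exact <- length(d) <= exact_max && !anyDuplicated(abs(d))
  ht <- suppressWarnings(
    stats::wilcox.test(d, alternative = "greater", exact = use_exact,
                       correct = TRUE)
  )
  list(p_value = unname(ht$p.value), n_nonzero = length(d),
       method = if (use_exact) "exact" else "normal approximation")
}

#' Pairwise framework comparison against the best framework
#'
#' For one scenario (one population at one missingness level), takes the
#' per-genotype score records of two or more frameworks aligned on the
#' same (individual, masked SNP) units, summarizes each framework, marks
#' the best one, and tests every other framework one-sided against the
#' best: McNemar on the well-imputed indicators when
#' `metric = "well_imputed"` or `"correct"`, Wilcoxon signed-rank on the
#' raw scores otherwise. Significance is flagged at `alpha` without
#' multiplicity correction. Treating the masked genotypes as independent
#' units presumes weak LD among HQ SNPs; pass `ld_fraction` (share of HQ
#' SNP pairs with r-squared at least 0.1) to record that alongside.
#'
#' @param score_tables named list (length >= 2) of data.frames from
#'   [score_imputation()], one per framework, with identical unit order.
#' @param metric `"well_imputed"`, `"correct"`, `"hellinger"` or `"sen"`.
#' @param alpha significance threshold (default 0.05).
#' @param ld_fraction optional fraction of HQ SNP pairs in LD, recorded in
#'   the output attribute.
#' @return An object of class `comparison_report`: data.frame with one row
#'   per framework (`framework`, `summary`, `is_best`, `p_vs_best`,
#'   `significant`), ties flagged via the `"tied_best"` attribute.
#' @export
build_comparison_table <- function(score_tables,
                                   metric = c("well_imputed", "correct",
                                              "hellinger", "sen"),
                                   alpha = 0.05, ld_fraction = NULL) {
  metric <- match.arg(metric)
  if (length(score_tables) < 1) stop("need at least one framework")
  if (is.null(names(score_tables))) {
    names(score_tables) <- sprintf("framework%d", seq_along(score_tables))
  }
  units <- paste(score_tables[[1]]$individual, score_tables[[1]]$snp_id)
  for (tab in score_tables) {
    if (!identical(paste(tab$individual, tab$snp_id), units)) {
      stop("score tables must be aligned on the same units")
    }
  }
  binary <- metric %in% c("well_imputed", "correct")
  vals <- lapply(score_tables, function(tab) tab[[metric]])
  summaries <- vapply(vals, function(v) {
    if (binary) 100 * mean(v) else mean(v)
  }, numeric(1))
  best_val <- max(summaries)
  best_idx <- which(summaries == best_val)
  tied <- length(best_idx) > 1
  if (tied) warning("tied best frameworks; first in order flagged")
  best <- best_idx[1]
  p <- rep(NA_real_, length(vals))
  for (k in seq_along(vals)) {
    if (k == best) next
    p[k] <- if (binary) {
      mcnemar_one_sided(vals[[best]], vals[[k]])$p_value
    } else {
      wilcoxon_one_sided(vals[[best]], vals[[k]])$p_value
    }
  }
  out <- data.frame(framework = names(score_tables),
                    summary = unname(summaries),
                    is_best = seq_along(vals) == best,
                    p_vs_best = p,
                    significant = !is.na(p) & p < alpha,
                    stringsAsFactors = FALSE)
  attr(out, "metric") <- metric
  attr(out, "alpha") <- alpha
  attr(out, "tied_best") <- tied
  attr(out, "ld_fraction") <- ld_fraction
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' Fraction of HQ SNP pairs in linkage disequilibrium
#'
#' Share of HQ SNP pairs whose genotype r-squared is at least `threshold`;
#' the quantity used to justify treating masked genotypes as independent
#' units in the paired tests.
#'
#' @param gm a [genotype_matrix()].
#' @param hq_ids SNP ids of the HQ set.
#' @param threshold r-squared threshold (default 0.1).
#' @return fraction in \[0, 1\].
#' @export
hq_ld_fraction <- function(gm, hq_ids, threshold = 0.1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  cols <- match(hq_ids, gm$snp_info$id)
  if (anyNA(cols)) stop("unknown HQ SNP id")
  r2 <- ld_r2(gm$genotypes[, cols, drop = FALSE])
  up <- r2[upper.tri(r2)]
  mean(up >= threshold, na.rm = TRUE)
}

#' Render a comparison report as a Markdown table
#'
#' Best framework marked in bold italics, significantly worse frameworks
#' with an asterisk — mirroring the usual benchmark-table layout.
#'
#' @param report a [build_comparison_table()] result.
#' @return character vector of Markdown lines.
#' @export
format_comparison_md <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  fmt <- function(i) {
    v <- sprintf("%.2f", report$summary[i])
    if (report$is_best[i]) v <- paste0("***", v, "***")
    if (report$significant[i]) v <- paste0(v, "*")
    v
  }
  c(paste0("| Framework | ", attr(report, "metric"), " |"),
    "| --- | --- |",
    vapply(seq_len(nrow(report)), function(i) {
      paste0("| ", report$framework[i], " | ", fmt(i), " |")
    }, character(1)))
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> metric '%s', alpha %.2f\n",
              attr(x, "metric"), attr(x, "alpha")))
  print.data.frame(x, ...)
  invisible(x)
}
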