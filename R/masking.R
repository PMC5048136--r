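#' Plan nested masked-SNP sets
#'
#' Draws one seeded uniform permutation of the HQ SNP ids; the masked set at
#' fraction `f` is the first `round(f * |HQ|)` entries (round half up), so
#' the set at a smaller fraction is contained in every larger one by
#' construction. Nesting keeps scenarios with different missingness directly
#' comparable: every genotype masked at 50% is also masked at 70% and 100%.
#'
#' @param hq_snp_ids character vector of HQ SNP ids (no duplicates).
#' @param fractions ascending fractions in (0, 1\]; default `c(0.5, 0.7, 1)`.
#' @param seed integer seed for the permutation.
#' @return An object of class `mask_plan`: list with `hq_snp_ids`,
#'   `fractions`, `masked_sets` (one id vector per fraction) and `seed`.
#' @export
plan_masks <- function(hq_snp_ids, fractions = c(0.5, 0.7, 1.0), seed = 1L) {
  if (anyDuplicated(hq_snp_ids)) stop("duplicate SNP ids in HQ set")
  if (length(fractions) == 0 || any(fractions <= 0) || any(fractions > 1)) {
    stop("fractions must lie in (0, 1]")
  }
  if (is.unsorted(fractions, strictly = TRUE)) {
    stop("fractions must be strictly ascending")
  }
  set.seed(seed)
  perm <- sample(hq_snp_ids)
  sizes <- floor(fractions * length(hq_snp_ids) + 0.5)  # round half up
  masked_sets <- lapply(sizes, function(k) perm[seq_len(k)])
  names(masked_sets) <- sprintf("%g", fractions)
  structure(list(hq_snp_ids = hq_snp_ids, fractions = fractions,
                 masked_sets = masked_sets, seed = seed),
            class = "mask_plan")
}

#' Apply a masked-SNP set to a genotype matrix
#'
#' Masked SNPs are set missing for all individuals. Genotypes that were
#' already missing before masking are excluded from the truth table and
#' hence from all scoring denominators.
#'
#' @param gm a [genotype_matrix()].
#' @param masked_set character vector of SNP ids to mask (must all be known).
#' @return list with `masked` (the genotype matrix with masked entries
#'   `NA`) and `truth` (data.frame `individual`, `snp_id`, `true_genotype`
#'   for every masked, originally-called genotype).
#' @export
apply_mask <- function(gm, masked_set) {
  stopifnot(inherits(gm, "genotype_matrix"))
  unknown <- setdiff(masked_set, gm$snp_info$id)
  if (length(unknown) > 0) {
    stop("unknown SNP id(s) in masked set: ", paste(unknown, collapse = ", "))
  }
  g <- gm$genotypes
  cols <- match(masked_set, gm$snp_info$id)
  truth <- do.call(rbind, lapply(cols, function(j) {
    called <- which(!is.na(g[, j]))
    if (length(called) == 0) return(NULL)
    data.frame(individual = gm$individual_ids[called],
               snp_id = gm$snp_info$id[j],
               true_genotype = g[called, j],
               stringsAsFactors = FALSE)
  }))
  if (is.null(truth)) {
    truth <- data.frame(individual = character(), snp_id = character(),
                        true_genotype = integer())
  }
  g[, cols] <- NA_integer_
  masked <- genotype_matrix(g, gm$snp_info, gm$individual_ids)
  list(masked = masked, truth = truth)
}

#' Serialize / restore a mask plan as JSON
#'
#' @param plan a [plan_masks()] result.
#' @param path file path.
#' @export
write_mask_plan <- function(plan, path) {
  stopifnot(inherits(plan, "mask_plan"))
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_plan
#' @export
read_mask_plan <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(hq_snp_ids = as.character(raw$hq_snp_ids),
                 fractions = as.numeric(raw$fractions),
                 masked_sets = lapply(raw$masked_sets, as.character),
                 seed = as.integer(raw$seed)),
            class = "mask_plan")
}
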