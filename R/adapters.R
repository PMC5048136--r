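#' Write / read PLINK text pedigree files
#'
#' `.ped`: one row per individual — family id, individual id, paternal and
#' maternal ids (0), sex (0), phenotype (-9), then two allele characters
#' per SNP (`0 0` for missing). `.map`: chromosome, SNP id, genetic
#' distance (0), bp position. Genotypes are coded as counts of the `a1`
#' allele from the SNP metadata.
#'
#' @param gm a [genotype_matrix()].
#' @param prefix path prefix; `.ped` and `.map` are appended.
#' @param chrom chromosome label written to the `.map` (default 22).
#' @return the prefix, invisibly.
#' @export
write_plink <- function(gm, prefix, chrom = 22) {
  stopifnot(inherits(gm, "genotype_matrix"))
  si <- gm$snp_info
  map <- data.frame(chrom, si$id, 0, si$pos)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  g <- gm$genotypes
  allele_strings <- vapply(seq_len(nrow(g)), function(i) {
    gi <- g[i, ]
    al1 <- ifelse(is.na(gi), "0", ifelse(gi >= 1, si$a1, si$a0))
    al2 <- ifelse(is.na(gi), "0", ifelse(gi == 2, si$a1, si$a0))
    paste(rbind(al1, al2), collapse = " ")
  }, character(1))
  lines <- paste(gm$individual_ids, gm$individual_ids, 0, 0, 0, -9,
                 allele_strings)
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' @rdname write_plink
#' @param snp_info optional SNP metadata fixing the allele coding (columns
#'   `id`, `pos`, `a0`, `a1`). Without it, alleles are inferred per SNP
#'   from the data: the major allele becomes `a0` (ties broken
#'   alphabetically).
#' @export
read_plink <- function(prefix, snp_info = NULL) {
  map <- utils::read.table(paste0(prefix, ".map"), header = FALSE,
                           stringsAsFactors = FALSE)
  ped <- utils::read.table(paste0(prefix, ".ped"), header = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  n_snps <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_snps) {
    stop("ped/map mismatch: expected ", 6 + 2 * n_snps,
         " columns, found ", ncol(ped))
  }
  ids <- ped[[2]]
  al1 <- as.matrix(ped[, 6 + 2 * seq_len(n_snps) - 1])
  al2 <- as.matrix(ped[, 6 + 2 * seq_len(n_snps)])
  if (is.null(snp_info)) {
    a0 <- character(n_snps)
    a1 <- character(n_snps)
    for (j in seq_len(n_snps)) {
      obs <- c(al1[, j], al2[, j])
      obs <- obs[obs != "0"]
      tab <- sort(table(obs), decreasing = TRUE)
      alleles <- names(tab)
      if (length(alleles) == 1) alleles <- c(alleles, setdiff(c("A", "C", "G", "T"), alleles)[1])
      if (length(alleles) == 2 && tab[1] == tab[2]) alleles <- sort(alleles)
      a0[j] <- alleles[1]
      a1[j] <- alleles[2]
    }
    snp_info <- data.frame(id = map[[2]], pos = map[[4]], a0 = a0, a1 = a1,
                           stringsAsFactors = FALSE)
  } else {
    if (!identical(as.character(snp_info$id), as.character(map[[2]]))) {
      stop("snp_info ids do not match the .map file")
    }
  }
  g <- matrix(NA_integer_, nrow(ped), n_snps)
  for (j in seq_len(n_snps)) {
    ok <- al1[, j] != "0" & al2[, j] != "0"
    g[ok, j] <- (al1[ok, j] == snp_info$a1[j]) + (al2[ok, j] == snp_info$a1[j])
  }
  genotype_matrix(g, snp_info, ids)
}

#' Write / read IMPUTE2-style .hap / .legend reference files
#'
#' `.hap`: one SNP per row, space-separated 0/1 alleles, one column per
#' haplotype. `.legend`: header `id position allele0 allele1`, one SNP per
#' row.
#'
#' @param panel a [haplotype_panel()].
#' @param prefix path prefix; `.hap` and `.legend` are appended.
#' @return the prefix, invisibly.
#' @export
write_hap_legend <- function(panel, prefix) {
  stopifnot(inherits(panel, "haplotype_panel"))
  hap_rows <- apply(t(panel$haplotypes), 1, paste, collapse = " ")
  writeLines(hap_rows, paste0(prefix, ".hap"))
  leg <- data.frame(id = panel$snp_info$id, position = panel$snp_info$pos,
                    allele0 = panel$snp_info$a0, allele1 = panel$snp_info$a1)
  utils::write.table(leg, paste0(prefix, ".legend"), sep = " ",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_hap_legend
#' @export
read_hap_legend <- function(prefix) {
  leg <- utils::read.table(paste0(prefix, ".legend"), header = TRUE,
                           stringsAsFactors = FALSE)
  hap_lines <- readLines(paste0(prefix, ".hap"))
  if (length(hap_lines) != nrow(leg)) {
    stop(".hap rows (", length(hap_lines), ") do not match .legend rows (",
         nrow(leg), ")")
  }
  tokens <- strsplit(trimws(hap_lines), "\\s+")
  n_haps <- length(tokens[[1]])
  bad <- which(lengths(tokens) != n_haps)
  if (length(bad) > 0) {
    stop("malformed .hap row at line ", bad[1])
  }
  haps_by_snp <- matrix(as.integer(unlist(tokens)), nrow = n_haps)
  snp_info <- data.frame(id = leg$id, pos = leg$position, a0 = leg$allele0,
                         a1 = leg$allele1, stringsAsFactors = FALSE)
  haplotype_panel(haps_by_snp, snp_info)
}

prob_fmt <- function(x) sprintf("%.4f", x)

#' Write MaCH-style imputation output
#'
#' `.mlprob`: one row per individual — `id->id ML_PROB` followed by two
#' probabilities per SNP (0 and 1 copies of the counted allele; the third
#' follows as the complement). `.mldose`: `id->id ML_DOSE` followed by one
#' dosage per SNP. `.mlinfo`: header
#' `SNP Al1 Al2 Freq1 MAF Quality Rsq`, one row per SNP. Probabilities are
#' written with 4 decimals.
#'
#' @param pt a [posterior_table()] with triples.
#' @param prefix path prefix; `.mlprob`, `.mldose`, `.mlinfo` appended.
#' @return the prefix, invisibly.
#' @export
write_mach <- function(pt, prefix) {
  stopifnot(inherits(pt, "posterior_table"))
  if (!pt$has_triples) stop("writing .mlprob requires posterior triples")
  n <- nrow(pt$dosages)
  L <- ncol(pt$dosages)
  ml_lines <- vapply(seq_len(n), function(i) {
    pq <- rbind(prob_fmt(pt$probs[i, , 1]), prob_fmt(pt$probs[i, , 2]))
    paste(c(paste0(pt$individual_ids[i], "->", pt$individual_ids[i]),
            "ML_PROB", pq), collapse = " ")
  }, character(1))
  writeLines(ml_lines, paste0(prefix, ".mlprob"))
  dose_lines <- vapply(seq_len(n), function(i) {
    paste(c(paste0(pt$individual_ids[i], "->", pt$individual_ids[i]),
            "ML_DOSE", prob_fmt(pt$dosages[i, ])), collapse = " ")
  }, character(1))
  writeLines(dose_lines, paste0(prefix, ".mldose"))
  freq1 <- colMeans(pt$dosages) / 2
  rsq <- apply(pt$dosages, 2, function(d) {
    if (length(d) >= 2) mach_rsq(d) else NA_real_
  })
  info <- data.frame(SNP = pt$snp_info$id, Al1 = pt$snp_info$a0,
                     Al2 = pt$snp_info$a1, Freq1 = prob_fmt(1 - freq1),
                     MAF = prob_fmt(pmin(freq1, 1 - freq1)),
                     Quality = prob_fmt(rep(1, L)), Rsq = prob_fmt(rsq))
  utils::write.table(info, paste0(prefix, ".mlinfo"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

parse_mach_line <- function(line, lineno, tag, n_values) {
  fields <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(fields) != 2 + n_values) {
    stop("malformed ", tag, " row at line ", lineno, ": expected ",
         2 + n_values, " fields, found ", length(fields))
  }
  vals <- suppressWarnings(as.numeric(fields[-(1:2)]))
  if (anyNA(vals)) stop("non-numeric value in ", tag, " at line ", lineno)
  list(id = sub("->.*$", "", fields[1]), values = vals)
}

#' Read MaCH-style imputation output
#'
#' Builds a [posterior_table()] from `.mlprob` (posterior triples; the
#' third probability is the complement of the two stored ones) or, when
#' only `.mldose` is given, a dosage-only table. The per-SNP Rsq column of
#' `.mlinfo` is attached as `snp_quality`.
#'
#' @param mlprob_path path to `.mlprob`, or `NULL`.
#' @param mlinfo_path path to `.mlinfo`.
#' @param mldose_path path to `.mldose`, used when `mlprob_path` is `NULL`.
#' @param snp_info optional SNP metadata; reconstructed from `.mlinfo`
#'   (with placeholder positions) when absent.
#' @param tol probability tolerance (default 1e-3).
#' @return A [posterior_table()] with source label `"mach"`.
#' @export
read_mach <- function(mlprob_path = NULL, mlinfo_path, mldose_path = NULL,
                      snp_info = NULL, tol = 1e-3) {
  info <- utils::read.table(mlinfo_path, header = TRUE,
                            stringsAsFactors = FALSE)
  L <- nrow(info)
  if (is.null(snp_info)) {
    snp_info <- data.frame(id = info$SNP, pos = seq_len(L), a0 = info$Al1,
                           a1 = info$Al2, stringsAsFactors = FALSE)
  }
  if (!is.null(mlprob_path)) {
    lines <- readLines(mlprob_path)
    rows <- lapply(seq_along(lines), function(i) {
      parse_mach_line(lines[i], i, ".mlprob", 2 * L)
    })
    ids <- vapply(rows, `[[`, character(1), "id")
    probs <- array(0, c(length(rows), L, 3))
    for (i in seq_along(rows)) {
      v <- rows[[i]]$values
      q0 <- v[2 * seq_len(L) - 1]
      q1 <- v[2 * seq_len(L)]
      if (any(q0 < -tol | q0 > 1 + tol | q1 < -tol | q1 > 1 + tol |
                q0 + q1 > 1 + tol)) {
        stop("probabilities outside [0, 1] beyond tolerance at line ", i)
      }
      probs[i, , 1] <- q0
      probs[i, , 2] <- q1
      probs[i, , 3] <- pmax(0, 1 - q0 - q1)
    }
    pt <- posterior_table(probs, snp_info, ids, source_label = "mach",
                          snp_quality = data.frame(snp_id = info$SNP,
                                                   rsq = as.numeric(info$Rsq)),
                          tol = tol)
  } else {
    if (is.null(mldose_path)) stop("need mlprob_path or mldose_path")
    lines <- readLines(mldose_path)
    rows <- lapply(seq_along(lines), function(i) {
      parse_mach_line(lines[i], i, ".mldose", L)
    })
    ids <- vapply(rows, `[[`, character(1), "id")
    dosages <- do.call(rbind, lapply(rows, `[[`, "values"))
    pt <- posterior_table(NULL, snp_info, ids, dosages = dosages,
                          source_label = "mach",
                          snp_quality = data.frame(snp_id = info$SNP,
                                                   rsq = as.numeric(info$Rsq)))
  }
  pt
}

#' Write IMPUTE2-style .gen output with an info file
#'
#' `.gen`: one row per SNP — chromosome, SNP id, position, alleles, then
#' three probabilities (0/1/2 copies of allele1) per individual, 4
#' decimals. The info file carries the per-SNP IMPUTE-info score.
#'
#' @param pt a [posterior_table()] with triples.
#' @param gen_path path for the `.gen` file.
#' @param info_path path for the info file.
#' @param chrom chromosome label (default 22).
#' @return `gen_path`, invisibly.
#' @export
write_impute2 <- function(pt, gen_path, info_path = NULL, chrom = 22) {
  stopifnot(inherits(pt, "posterior_table"))
  if (!pt$has_triples) stop("writing .gen requires posterior triples")
  L <- ncol(pt$dosages)
  lines <- vapply(seq_len(L), function(j) {
    tri <- rbind(prob_fmt(pt$probs[, j, 1]), prob_fmt(pt$probs[, j, 2]),
                 prob_fmt(pt$probs[, j, 3]))
    paste(c(chrom, pt$snp_info$id[j], pt$snp_info$pos[j],
            pt$snp_info$a0[j], pt$snp_info$a1[j], tri), collapse = " ")
  }, character(1))
  writeLines(lines, gen_path)
  if (!is.null(info_path)) {
    info_score <- vapply(seq_len(L), function(j) {
      impute_info(pt$probs[, j, ])
    }, numeric(1))
    info <- data.frame(snp_id = pt$snp_info$id,
                       rs_id = pt$snp_info$id,
                       position = pt$snp_info$pos,
                       exp_freq_a1 = prob_fmt(colMeans(pt$dosages) / 2),
                       info = prob_fmt(info_score))
    utils::write.table(info, info_path, sep = " ", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(gen_path)
}

#' Read IMPUTE2-style .gen output
#'
#' @param gen_path path to the `.gen` file (three probabilities per
#'   individual per SNP row).
#' @param info_path optional info file; its `info` column is attached as
#'   `snp_quality`.
#' @param individual_ids optional ids (generated when absent).
#' @param tol probability tolerance (default 1e-3).
#' @return A [posterior_table()] with source label `"impute2"`.
#' @export
read_impute2 <- function(gen_path, info_path = NULL, individual_ids = NULL,
                         tol = 1e-3) {
  lines <- readLines(gen_path)
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if ((length(first) - 5) %% 3 != 0) {
    stop("malformed .gen row at line 1: probability fields not a multiple of 3")
  }
  n <- (length(first) - 5) %/% 3
  L <- length(lines)
  probs <- array(0, c(n, L, 3))
  snp_info <- data.frame(id = character(L), pos = numeric(L),
                         a0 = character(L), a1 = character(L),
                         stringsAsFactors = FALSE)
  for (j in seq_len(L)) {
    fields <- strsplit(trimws(lines[j]), "\\s+")[[1]]
    if (length(fields) != 5 + 3 * n) {
      stop("malformed .gen row at line ", j, ": expected ", 5 + 3 * n,
           " fields, found ", length(fields))
    }
    snp_info$id[j] <- fields[2]
    snp_info$pos[j] <- as.numeric(fields[3])
    snp_info$a0[j] <- fields[4]
    snp_info$a1[j] <- fields[5]
    vals <- suppressWarnings(as.numeric(fields[-(1:5)]))
    if (anyNA(vals)) stop("non-numeric probability in .gen at line ", j)
    probs[, j, 1] <- vals[3 * seq_len(n) - 2]
    probs[, j, 2] <- vals[3 * seq_len(n) - 1]
    probs[, j, 3] <- vals[3 * seq_len(n)]
  }
  if (is.null(individual_ids)) individual_ids <- sprintf("ind%04d", seq_len(n))
  quality <- NULL
  if (!is.null(info_path)) {
    info <- utils::read.table(info_path, header = TRUE,
                              stringsAsFactors = FALSE)
    quality <- data.frame(snp_id = info$snp_id,
                          info = as.numeric(info$info))
  }
  posterior_table(probs, snp_info, individual_ids, source_label = "impute2",
                  snp_quality = quality, tol = tol)
}

#' Read genotype posteriors from a VCF (GP / DS FORMAT fields)
#'
#' GP triples are preferred; files carrying only DS yield a dosage-only
#' table (`has_triples = FALSE`). When both are present, GP-derived
#' dosages are cross-checked against DS and disagreements beyond `1e-3`
#' trigger a warning. Requires the `vcfR` package.
#'
#' @param vcf_path path to an uncompressed or bgzipped VCF.
#' @return A [posterior_table()] with source label `"vcf"`.
#' @export
read_vcf_posteriors <- function(vcf_path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcfR package is required to read VCF posteriors")
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  fmt <- strsplit(unname(v@gt[1, "FORMAT"]), ":")[[1]]
  has_gp <- "GP" %in% fmt
  has_ds <- "DS" %in% fmt
  if (!has_gp && !has_ds) stop("VCF carries neither GP nor DS FORMAT fields")
  L <- nrow(v@gt)
  snp_info <- data.frame(id = fix[, "ID"], pos = as.numeric(fix[, "POS"]),
                         a0 = fix[, "REF"], a1 = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  ds <- NULL
  if (has_ds) {
    ds_raw <- vcfR::extract.gt(v, element = "DS")
    ds <- t(matrix(as.numeric(ds_raw), nrow = L))
    individual_ids <- colnames(ds_raw)
  }
  if (has_gp) {
    gp_raw <- vcfR::extract.gt(v, element = "GP")
    individual_ids <- colnames(gp_raw)
    n <- ncol(gp_raw)
    probs <- array(0, c(n, L, 3))
    for (j in seq_len(L)) {
      triples <- strsplit(gp_raw[j, ], ",")
      for (i in seq_len(n)) {
        probs[i, j, ] <- as.numeric(triples[[i]])
      }
    }
    pt <- posterior_table(probs, snp_info, individual_ids,
                          source_label = "vcf")
    if (has_ds && any(abs(pt$dosages - ds) > 1e-3, na.rm = TRUE)) {
      warning("GP-derived dosages disagree with DS beyond 1e-3")
    }
    pt
  } else {
    posterior_table(NULL, snp_info, individual_ids, dosages = ds,
                    source_label = "vcf")
  }
}

#' Write a JSON run manifest
#'
#' Records seeds and parameters of a simulation or pipeline run for
#' provenance.
#'
#' @param params named list of parameters (seeds included).
#' @param path output path.
#' @export
write_manifest <- function(params, path) {
  params$imputeval_version <- as.character(utils::packageVersion("imputeval"))
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
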