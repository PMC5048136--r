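#' Parameters of the haplotype-copying imputation HMM
#'
#' The imputer is a Li-Stephens-style copying model: each target chromosome
#' is modelled as a mosaic of the reference-panel haplotypes. `switch_prob`
#' is the per-interval probability that the copied haplotype changes
#' (uniformly over the panel), playing the role of a recombination rate;
#' `error_rate` is the per-allele probability that the observed allele
#' differs from the copied one.
#'
#' @param error_rate per-allele copying error, strictly inside (0, 0.5).
#' @param switch_prob per-interval switch probability, strictly inside (0, 1).
#' @param mode `"joint"` (diploid forward-backward, no pre-phasing) or
#'   `"prephased"` (Viterbi phasing followed by haploid imputation).
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(error_rate = 0.01, switch_prob = 0.001,
                       mode = c("joint", "prephased")) {
  mode <- match.arg(mode)
  if (error_rate <= 0 || error_rate >= 0.5) {
    stop("error_rate must lie strictly inside (0, 0.5)")
  }
  if (switch_prob <= 0 || switch_prob >= 1) {
    stop("switch_prob must lie strictly inside (0, 1)")
  }
  structure(list(error_rate = error_rate, switch_prob = switch_prob,
                 mode = mode), class = "hmm_params")
}

# Diploid transition operator applied to a K x K table over ordered
# haplotype pairs: each chromosome independently switches with probability
# rho to a uniform panel haplotype. Linearity in the table lets the O(K^4)
# sum collapse to O(K^2) via row/column marginals.
pair_transition <- function(m, rho, K) {
  rs <- rowSums(m)
  cs <- colSums(m)
  (1 - rho)^2 * m +
    ((1 - rho) * rho / K) *
    (matrix(rs, K, K) + matrix(cs, K, K, byrow = TRUE)) +
    (rho / K)^2 * sum(rs)
}

# Emission table over ordered pairs for an observed genotype, from
# per-haplotype allele emission columns u0, u1 (P(observed allele | copied
# haplotype)).
pair_emission <- function(gobs, u0, u1) {
  if (gobs == 0L) outer(u0, u0)
  else if (gobs == 1L) outer(u0, u1) + outer(u1, u0)
  else outer(u1, u1)
}

# Scaled forward-backward for one individual over the diploid copying HMM.
# Emissions are applied at typed SNPs only; the reported posterior at every
# SNP is the posterior distribution of the *copied* genotype (sum of the two
# copied panel alleles), so a degenerate panel yields an exact point mass.
joint_fb_individual <- function(g, H, eps, rho) {
  K <- nrow(H)
  L <- ncol(H)
  U0 <- matrix(ifelse(H == 1L, eps, 1 - eps), K, L)
  U1 <- 1 - U0
  alpha <- array(0, c(K, K, L))
  a <- matrix(1 / (K * K), K, K)
  for (s in seq_len(L)) {
    if (s > 1) a <- pair_transition(a, rho, K)
    if (!is.na(g[s])) a <- a * pair_emission(g[s], U0[, s], U1[, s])
    tot <- sum(a)
    if (tot <= 0) stop("forward probability underflow at SNP ", s)
    a <- a / tot
    alpha[, , s] <- a
  }
  probs <- matrix(0, L, 3)
  b <- matrix(1, K, K)
  for (s in L:1) {
    gam <- alpha[, , s] * b
    gam <- gam / sum(gam)
    carriers <- H[, s] == 1L
    p2 <- sum(gam[carriers, carriers])
    p0 <- sum(gam[!carriers, !carriers])
    p1 <- max(0, 1 - p0 - p2)
    probs[s, ] <- c(p0, p1, p2) / (p0 + p1 + p2)
    if (s > 1) {
      m <- b
      if (!is.na(g[s])) m <- m * pair_emission(g[s], U0[, s], U1[, s])
      b <- pair_transition(m, rho, K)
      b <- b / sum(b)
    }
  }
  probs
}

check_imputer_inputs <- function(gm, panel) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(panel, "haplotype_panel"))
  if (!identical(gm$snp_info$id, panel$snp_info$id)) {
    stop("target and panel must share the same SNP grid")
  }
  if (nrow(panel$haplotypes) < 2) stop("panel must hold at least 2 haplotypes")
  if (all(is.na(gm$genotypes))) stop("no typed SNPs in the target")
}

#' Joint (no pre-phasing) diploid imputation
#'
#' Runs the diploid copying HMM over ordered pairs of panel haplotypes
#' (K^2 states) with a scaled forward-backward pass per individual, and
#' returns the genotype posterior at every SNP. Typed SNPs anchor the
#' copying path through their emission probabilities; masked or missing
#' SNPs receive a model posterior.
#'
#' @param gm a [genotype_matrix()] with masked entries set `NA`.
#' @param panel a [haplotype_panel()] on the same SNP grid.
#' @param params an [hmm_params()].
#' @return A [posterior_table()] with source label `"joint"`.
#' @export
impute_joint <- function(gm, panel, params = hmm_params()) {
  check_imputer_inputs(gm, panel)
  n <- nrow(gm$genotypes)
  L <- ncol(gm$genotypes)
  probs <- array(0, c(n, L, 3))
  for (i in seq_len(n)) {
    gi <- gm$genotypes[i, ]
    if (all(is.na(gi))) stop("individual ", i, " has no typed SNPs")
    probs[i, , ] <- joint_fb_individual(gi, panel$haplotypes,
                                        params$error_rate,
                                        params$switch_prob)
  }
  posterior_table(probs, gm$snp_info, gm$individual_ids,
                  source_label = "joint")
}

# Viterbi decoding of the diploid copying HMM restricted to typed SNPs.
# Transitions across a gap of d intervals use the compound kernel
# (1-rho)^d * delta + (1 - (1-rho)^d)/K (after >= 1 switch the copied
# haplotype is uniform). Ties prefer staying on the current haplotypes.
viterbi_pair <- function(g, H, eps, rho) {
  typed <- which(!is.na(g))
  Tn <- length(typed)
  K <- nrow(H)
  U0 <- matrix(ifelse(H[, typed, drop = FALSE] == 1L, eps, 1 - eps), K, Tn)
  U1 <- 1 - U0
  lemit <- function(i, gobs) log(pair_emission(gobs, U0[, i], U1[, i]))

  la <- lemit(1, g[typed[1]]) - 2 * log(K)
  codes <- array(1L, c(K, K, Tn))
  rowarg <- matrix(1L, K, Tn)
  colarg <- matrix(1L, K, Tn)
  glob <- matrix(1L, 2, Tn)
  if (Tn > 1) {
    for (i in 2:Tn) {
      d <- typed[i] - typed[i - 1]
      stay <- (1 - rho)^d
      lA <- log(stay + (1 - stay) / K)
      lB <- log((1 - stay) / K)
      rw <- max.col(la, ties.method = "first")
      rmax <- la[cbind(seq_len(K), rw)]
      cw <- max.col(t(la), ties.method = "first")
      cmax <- la[cbind(cw, seq_len(K))]
      gi <- arrayInd(which.max(la), c(K, K))
      c1 <- la + 2 * lA
      c2 <- matrix(rmax, K, K) + lA + lB
      c3 <- matrix(cmax, K, K, byrow = TRUE) + lA + lB
      c4 <- max(la) + 2 * lB
      best <- pmax(c1, c2, c3, c4)
      code <- ifelse(c1 >= best, 1L,
                     ifelse(c2 >= best, 2L, ifelse(c3 >= best, 3L, 4L)))
      codes[, , i] <- code
      rowarg[, i] <- rw
      colarg[, i] <- cw
      glob[, i] <- as.integer(gi[1, ])
      la <- best + lemit(i, g[typed[i]])
    }
  }
  end <- arrayInd(which.max(la), c(K, K))
  path <- matrix(0L, Tn, 2)
  path[Tn, ] <- as.integer(end[1, ])
  if (Tn > 1) {
    for (i in Tn:2) {
      j <- path[i, 1]
      l <- path[i, 2]
      path[i - 1, ] <- switch(codes[j, l, i],
                              c(j, l),
                              c(j, rowarg[j, i]),
                              c(colarg[l, i], l),
                              glob[, i])
    }
  }
  h1 <- rep(NA_integer_, length(g))
  h2 <- rep(NA_integer_, length(g))
  h1[typed] <- H[cbind(path[, 1], typed)]
  h2[typed] <- H[cbind(path[, 2], typed)]
  list(h1 = h1, h2 = h2)
}

#' Pre-phase target individuals against a panel
#'
#' Viterbi best state path of the diploid copying HMM restricted to typed
#' SNPs; the emitted haplotypes are the copied panel alleles along the
#' path. Deterministic given its inputs (no randomness; ties prefer the
#' current haplotype pair).
#'
#' @inheritParams impute_joint
#' @return list of two `N x L` matrices `h1`, `h2` (`NA` at untyped SNPs).
#' @export
prephase <- function(gm, panel, params = hmm_params(mode = "prephased")) {
  check_imputer_inputs(gm, panel)
  n <- nrow(gm$genotypes)
  L <- ncol(gm$genotypes)
  h1 <- matrix(NA_integer_, n, L)
  h2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    gi <- gm$genotypes[i, ]
    if (all(is.na(gi))) stop("individual ", i, " has no typed SNPs")
    ph <- viterbi_pair(gi, panel$haplotypes, params$error_rate,
                       params$switch_prob)
    h1[i, ] <- ph$h1
    h2[i, ] <- ph$h2
  }
  list(h1 = h1, h2 = h2)
}

# Haploid scaled forward-backward: returns P(copied allele = 1) per SNP.
haploid_fb <- function(h, H, eps, rho) {
  K <- nrow(H)
  L <- ncol(H)
  alpha <- matrix(0, K, L)
  a <- rep(1 / K, K)
  for (s in seq_len(L)) {
    if (s > 1) a <- (1 - rho) * a + rho / K * sum(a)
    if (!is.na(h[s])) {
      match_prob <- ifelse(H[, s] == h[s], 1 - eps, eps)
      a <- a * match_prob
    }
    a <- a / sum(a)
    alpha[, s] <- a
  }
  pa1 <- numeric(L)
  b <- rep(1, K)
  for (s in L:1) {
    gam <- alpha[, s] * b
    gam <- gam / sum(gam)
    pa1[s] <- sum(gam[H[, s] == 1L])
    if (s > 1) {
      m <- b
      if (!is.na(h[s])) m <- m * ifelse(H[, s] == h[s], 1 - eps, eps)
      b <- (1 - rho) * m + rho / K * sum(m)
      b <- b / sum(b)
    }
  }
  pa1
}

#' Impute from pre-phased haplotypes
#'
#' Each phased haplotype is imputed independently with a haploid copying
#' HMM (K states); the genotype posterior is the convolution of the two
#' allele posteriors. This is the step where pre-phasing discards phase
#' uncertainty: phasing errors at typed SNPs propagate into both haploid
#' passes.
#'
#' @param haps list of matrices `h1`, `h2` from [prephase()].
#' @param panel a [haplotype_panel()] on the same SNP grid.
#' @param params an [hmm_params()].
#' @param snp_info,individual_ids metadata for the output table; defaults
#'   come from the panel / row count.
#' @return A [posterior_table()] with source label `"prephased"`.
#' @export
impute_prephased <- function(haps, panel, params = hmm_params(mode = "prephased"),
                             snp_info = panel$snp_info,
                             individual_ids = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (nrow(panel$haplotypes) < 2) stop("panel must hold at least 2 haplotypes")
  h1 <- as.matrix(haps$h1)
  h2 <- as.matrix(haps$h2)
  n <- nrow(h1)
  L <- ncol(h1)
  if (L != ncol(panel$haplotypes)) {
    stop("haplotypes and panel must share the same SNP grid")
  }
  if (is.null(individual_ids)) individual_ids <- sprintf("ind%04d", seq_len(n))
  probs <- array(0, c(n, L, 3))
  for (i in seq_len(n)) {
    if (all(is.na(h1[i, ])) || all(is.na(h2[i, ]))) {
      stop("individual ", i, " has no typed SNPs")
    }
    pa <- haploid_fb(h1[i, ], panel$haplotypes, params$error_rate,
                     params$switch_prob)
    pb <- haploid_fb(h2[i, ], panel$haplotypes, params$error_rate,
                     params$switch_prob)
    probs[i, , 1] <- (1 - pa) * (1 - pb)
    probs[i, , 2] <- pa * (1 - pb) + (1 - pa) * pb
    probs[i, , 3] <- pa * pb
  }
  posterior_table(probs, snp_info, individual_ids,
                  source_label = "prephased")
}

#' One-call imputation in either mode
#'
#' @inheritParams impute_joint
#' @return A [posterior_table()].
#' @export
impute <- function(gm, panel, params = hmm_params()) {
  if (params$mode == "joint") {
    impute_joint(gm, panel, params)
  } else {
    haps <- prephase(gm, panel, params)
    impute_prephased(haps, panel, params, snp_info = gm$snp_info,
                     individual_ids = gm$individual_ids)
  }
}
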