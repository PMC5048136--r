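# Independent brute-force oracles used to validate the analytic
# implementations. These deliberately use naive enumeration and direct
# factorial arithmetic rather than the package's own code paths.

# Exact HWE: enumerate every heterozygote count compatible with the allele
# counts and accumulate the probability of tables as or less probable than
# the observed one.
oracle_hwe_p <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  n_a <- 2 * n_AA + n_AB
  n_b <- 2 * n_BB + n_AB
  support <- seq(min(n_a, n_b) %% 2, min(n_a, n_b), by = 2)
  weight <- vapply(support, function(h) {
    aa <- (n_a - h) / 2
    bb <- (n_b - h) / 2
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2))
  }, numeric(1))
  prob <- weight / sum(weight)
  p_obs <- prob[support == n_AB]
  sum(prob[prob <= p_obs * (1 + 1e-9)])
}

# Stratified HWE for exactly two strata: direct double loop over the two
# conditional supports.
oracle_stratified_hwe_p <- function(counts1, counts2) {
  dist_of <- function(cn) {
    n <- sum(cn)
    n_a <- 2 * cn[1] + cn[2]
    n_b <- 2 * cn[3] + cn[2]
    support <- seq(min(n_a, n_b) %% 2, min(n_a, n_b), by = 2)
    weight <- vapply(support, function(h) {
      exp(lfactorial(n) - lfactorial((n_a - h) / 2) - lfactorial(h) -
            lfactorial((n_b - h) / 2) + h * log(2))
    }, numeric(1))
    list(support = support, prob = weight / sum(weight))
  }
  d1 <- dist_of(counts1)
  d2 <- dist_of(counts2)
  obs <- d1$prob[d1$support == counts1[2]] * d2$prob[d2$support == counts2[2]]
  total <- 0
  for (i in seq_along(d1$support)) {
    for (j in seq_along(d2$support)) {
      stat <- d1$prob[i] * d2$prob[j]
      if (stat <= obs * (1 + 1e-9)) total <- total + d1$prob[i] * d2$prob[j]
    }
  }
  total
}

# Exhaustive path-sum over all ordered-pair state sequences of the diploid
# copying HMM. Returns the genotype posterior triple at SNP `target`.
oracle_joint_posterior <- function(g, H, eps, rho, target) {
  K <- nrow(H)
  L <- ncol(H)
  trans1 <- function(a, b) (1 - rho) * (a == b) + rho / K
  emit <- function(gobs, x, y) {
    p <- function(obs, h) if (obs == h) 1 - eps else eps
    if (gobs == 0) p(0, x) * p(0, y)
    else if (gobs == 2) p(1, x) * p(1, y)
    else p(0, x) * p(1, y) + p(1, x) * p(0, y)
  }
  states <- expand.grid(j = seq_len(K), l = seq_len(K))
  n_states <- nrow(states)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n_states)), L)))
  post <- c(0, 0, 0)
  total <- 0
  for (r in seq_len(nrow(paths))) {
    prob <- 1 / n_states
    for (s in seq_len(L)) {
      st <- paths[r, s]
      j <- states$j[st]
      l <- states$l[st]
      if (s > 1) {
        pj <- states$j[paths[r, s - 1]]
        pl <- states$l[paths[r, s - 1]]
        prob <- prob * trans1(pj, j) * trans1(pl, l)
      }
      if (!is.na(g[s])) prob <- prob * emit(g[s], H[j, s], H[l, s])
    }
    st <- paths[r, target]
    copied <- H[states$j[st], target] + H[states$l[st], target]
    post[copied + 1] <- post[copied + 1] + prob
    total <- total + prob
  }
  unname(post / total)
}

# Exhaustive path-sum for the haploid copying HMM: P(copied allele = 1)
# at SNP `target`.
oracle_haploid_posterior <- function(h, H, eps, rho, target) {
  K <- nrow(H)
  L <- ncol(H)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  num <- 0
  total <- 0
  for (r in seq_len(nrow(paths))) {
    prob <- 1 / K
    for (s in seq_len(L)) {
      k <- paths[r, s]
      if (s > 1) {
        prev <- paths[r, s - 1]
        prob <- prob * ((1 - rho) * (prev == k) + rho / K)
      }
      if (!is.na(h[s])) {
        prob <- prob * (if (H[k, s] == h[s]) 1 - eps else eps)
      }
    }
    if (H[paths[r, target], target] == 1) num <- num + prob
    total <- total + prob
  }
  unname(num / total)
}

# One-sided McNemar by full enumeration of the 2^n equally likely
# allocations of n discordant pairs.
oracle_mcnemar_p <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  signs <- as.matrix(expand.grid(rep(list(0:1), n)))
  mean(rowSums(signs) >= b)
}

# One-sided Wilcoxon signed-rank by enumeration of all 2^n sign
# assignments (requires untied absolute differences).
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(0:1), n)))
  w_all <- signs %*% rk
  mean(w_all >= w_obs)
}

# Small deterministic genotype fixture on a handful of SNPs.
make_test_gm <- function(genotypes, a0 = NULL, a1 = NULL) {
  n_snps <- ncol(genotypes)
  if (is.null(a0)) a0 <- rep("A", n_snps)
  if (is.null(a1)) a1 <- rep("G", n_snps)
  genotype_matrix(genotypes,
                  data.frame(id = sprintf("rs%03d", seq_len(n_snps)),
                             pos = seq_len(n_snps) * 1000L,
                             a0 = a0, a1 = a1, stringsAsFactors = FALSE))
}

make_test_panel <- function(haplotypes) {
  n_snps <- ncol(haplotypes)
  haplotype_panel(haplotypes,
                  data.frame(id = sprintf("rs%03d", seq_len(n_snps)),
                             pos = seq_len(n_snps) * 1000L,
                             a0 = rep("A", n_snps), a1 = rep("G", n_snps),
                             stringsAsFactors = FALSE))
}
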