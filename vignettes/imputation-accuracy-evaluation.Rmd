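---
title: "Methods: evaluating genotype-imputation accuracy by masking and re-imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating genotype-imputation accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imputeval)
```

# The evaluation problem

Imputation tools output, for every untyped SNP of every individual, a
posterior distribution $(q_0, q_1, q_2)$ over the three genotypes. Each
tool also reports a proprietary per-SNP quality score, which cannot be
compared across tools and — worse — depends on how well the reference
panel matches the target. The objective alternative is to *mask* SNPs
whose genotypes are known with high confidence, re-impute them, and score
the posteriors against the held-out truth. `imputeval` implements that
loop end to end, together with a synthetic-data generator and a built-in
copying-model imputer so that every stage can be exercised, tested and
seeded on a desktop without access to controlled genotype data or
external imputation binaries.

# Scores

With $g$ the true genotype and $q_g$ its posterior probability, the
Hellinger affinity between the point-mass truth and the posterior is
$\sqrt{q_g}$, so the Hellinger distance is $\sqrt{1 - \sqrt{q_g}}$ and
the score is

$$\mathrm{HS} = 1 - \sqrt{1 - \sqrt{q_g}}.$$

$\mathrm{HS} = 1$ holds exactly when the posterior is a point mass on the
truth. The well-imputed cutoff is $\mathrm{HS} \ge 0.45$; inverting the
formula gives the smallest compatible $q_g$:

$$q_g \ge \left(1 - 0.55^2\right)^2 = 0.48650625 \approx 0.49,$$

i.e. a well-imputed genotype always carries a best-guess posterior of at
least 0.49. This calibration identity is enforced as a test
(`hellinger_cutoff_posterior(0.45)`), and it fixes the score formula: any
other scaling would break the 0.45 ↔ 0.49 correspondence.

The SEN (scaled Euclidean norm) score compares expectations instead of
distributions: $\mathrm{SEN} = 1 - |g - d|/2$ with dosage
$d = q_1 + 2 q_2$; the divisor 2 is the largest possible expectation
error. Whether the 0.45 rule keys on the posterior of the *true* or the
*best-guess* genotype is immaterial in practice — whenever
$\mathrm{HS} \ge 0.45$ the two coincide except in pathological cases —
but both are reported per genotype (`q`-columns and `best_guess_prob`).

The per-SNP software-style measures are included for comparison:
MaCH-Rsq is the ratio of the empirical (maximum-likelihood) dosage
variance to $2\hat p(1-\hat p)$; IMPUTE-info is
$1 - \sum_i (f_i - e_i^2) / (2N\hat\theta(1-\hat\theta))$ with
$e_i = q_1 + 2q_2$, $f_i = q_1 + 4q_2$; and the squared dosage–truth
correlation is the software-independent analogue. IMPUTE-info can be
negative for very uninformative posteriors (all-uniform triples give
$-1/3$); it is reported as computed, not clipped.

# Quality control and masking

HQ SNPs are defined by call rate, minor allele frequency, and an exact
Hardy–Weinberg test, with strand-ambiguous (A/T, C/G) SNPs removed. Two
presets are built in: `"popres"` (CR ≥ 0.95, MAF ≥ 0.1, p ≥ 0.01) for
small multi-population panels and `"life"` (CR ≥ 0.995, MAF ≥ 0.2,
p ≥ 0.5) for large single-population cohorts.

The within-stratum exact HWE test uses the Levene–Haldane conditional
distribution of the heterozygote count given the allele counts, with the
two-sided probability-ordering definition of "as or more extreme" (no
mid-p) — the common convention for exact HWE tests. The stratified
extension treats strata as independent and uses the *product* of
within-stratum conditional probabilities as the test statistic; its null
distribution is evaluated by exact convolution while the joint state
space stays below `max_states` (default $2 \times 10^5$ configurations)
and by seeded Monte-Carlo sampling ($10^5$ draws by default) above it.
The product rule is this package's choice of a natural exact combination;
ties in the statistic are resolved with a relative tolerance of $10^{-9}$
so that floating-point noise cannot drop configurations that are exactly
as extreme. Missing genotypes are excluded from MAF and HWE counts.

Masking draws *one* seeded uniform permutation of the HQ SNP ids; the set
at fraction $f$ is the first $\lfloor f\,|HQ| + 0.5\rfloor$ entries
(round half up — 50% of 457 SNPs masks 229), which makes the sets nested
by construction: every genotype masked at 50% is also masked at 70% and
100%, keeping the missingness scenarios directly comparable. Masking is
SNP-wise across all individuals; genotypes that were missing before
masking never enter a scoring denominator. One permutation is drawn per
masking plan (per population), with the seed recorded in the plan.

# The synthetic-data generator

The generator's job is to produce target populations and candidate
reference panels at *controlled genetic distance* with enough linkage
disequilibrium for copying-model imputation to work — the two properties
the evaluation actually depends on.

- **Divergence**: subpopulation allele frequencies follow the
  Balding–Nichols model — Beta with mean $p$ and variance $F p(1-p)$.
  For two demes drawn at drift $F$, the expected multi-locus Nei's G_ST
  is $(F/2)/(1-F/2)$, which makes $F$ a dial for reference distance and
  gives a closed form for parameter-recovery tests. $F = 0.004$
  reproduces a well-matched reference (G_ST ≈ 0.002) and $F = 0.04$ a
  clearly mismatched one (G_ST ≈ 0.02), bracketing the 0.010 decision
  cutoff from both sides with the same spread as observed reference
  panels (roughly 0.008–0.033).
- **LD**: founder haplotypes are drawn SNP-wise independently from the
  population frequencies; panel and target haplotypes are mosaics copying
  one founder at a time with per-interval switch probability 0.01
  (default). Shared founders induce LD that decays with distance; a
  coalescent simulator would add realism the evaluation does not need.
- **Defaults** mirror a small-cohort benchmark: 20–40 target individuals,
  one chromosome of a few hundred to a few thousand SNPs with positions
  uniform on a 35-Mb chromosome-22-like interval, panels of 60
  haplotypes, ancestral frequencies uniform on (0.15, 0.85) so most SNPs
  are common. Frequencies are clipped to $[10^{-6}, 1-10^{-6}]$ to keep
  heterozygosities finite.

What the generator does **not** emulate: realistic demography or
recombination maps, rare-variant site-frequency spectra, genotyping
error, strand misannotation, or admixture. Passing tests therefore show
that the evaluation machinery is correct and that directional findings
(e.g. the pre-phasing penalty) emerge under controlled conditions — not
that any particular accuracy percentage transfers to real cohorts.

# The built-in imputer

The imputer is a deliberately plain Li–Stephens copying model, *not* a
re-implementation of MaCH, IMPUTE2, SHAPEIT or Minimac:

- **Joint mode** (no pre-phasing): forward–backward over ordered pairs of
  panel haplotypes ($K^2$ states). Each chromosome switches independently
  with probability $\rho$ per interval to a uniformly chosen haplotype;
  emissions at typed SNPs multiply per-allele $(1-\varepsilon)$ /
  $\varepsilon$ terms summed over allele assignments. The transition
  update factorizes through row/column marginals, so a forward step costs
  $O(K^2)$ rather than $O(K^4)$.
- **Pre-phased mode**: Viterbi best path of the same diploid HMM
  restricted to typed SNPs (compound transitions across gaps use the
  closed form $(1-\rho)^d\delta + (1-(1-\rho)^d)/K$), emitting the copied
  panel alleles as haplotypes; then each haplotype is imputed
  independently with the haploid $K$-state HMM and the genotype posterior
  is the convolution of the two allele posteriors. This is exactly where
  phase uncertainty is discarded, which is the mechanism behind the
  pre-phasing accuracy penalty the evaluation detects.

Numerical choices: the forward–backward passes use per-step scaling
(normalizing each state table and tracking only ratios), which is the
standard stable alternative to log-space sums and keeps the inner loop
vectorized; the Viterbi pass is in log space. Viterbi ties prefer staying
on the current haplotype pair, making pre-phasing fully deterministic.
The reported posterior at every SNP is the posterior of the *copied*
genotype — the indicator that the copied pair of panel alleles sums to
$g$ — so a panel that is monomorphic at a masked SNP yields an exact
point mass; $\varepsilon$ enters only through the emissions of observed
data. Defaults $\varepsilon = 0.01$, $\rho = 0.001$ are typical
magnitudes for dense SNP-array data and are configurable; both must be
strictly interior to their ranges so every path keeps positive
probability.

# Reference matching

Nei's G_ST is computed per locus from $H_T$ at the unweighted mean
frequency and the unweighted mean within-population heterozygosity
$H_S$, aggregated as a ratio of sums (Nei's recommended multi-locus
form). Equal population weights are used because targets (tens of
individuals) and panels (tens to hundreds of haplotypes) differ greatly
in size, and plug-in (biased) heterozygosity estimators are used without
small-sample correction, matching the measure's descriptive role. Loci
with $H_T = 0$ carry no information about differentiation and are
excluded. A best match with G_ST ≤ 0.010 is flagged `well_matched` — the
rough decision rule for preferring a population-specific over an admixed
reference.

# Framework comparison

Frameworks are compared pairwise against the best one per scenario:
one-sided exact McNemar on the paired well-imputed indicators
($p = P(X \ge b)$, $X \sim \mathrm{Bin}(b+c, 1/2)$, switching to the
one-sided normal approximation above 100 discordant pairs) and one-sided
Wilcoxon signed-rank on raw scores (exact for ≤ 25 untied non-zero
differences, normal approximation with tie correction otherwise; the
switch points are implementation choices). Significance is declared at
5% without multiplicity correction, matching the descriptive
best-vs-rest layout of benchmark tables. The pairing unit is the
(individual, masked SNP) genotype. Treating those units as independent
presumes weak LD among HQ SNPs; `hq_ld_fraction()` reports the share of
HQ pairs with $r^2 \ge 0.1$ and the comparison report records it.

# Problem sizes and test design

The test suite validates every exact procedure against an independent
brute-force oracle: full enumeration for the exact and stratified HWE
tests (n ≤ 50; two-stratum joint enumeration), all $2^n$ sign
assignments for McNemar and Wilcoxon (n ≤ 12), and exhaustive path sums
over all state sequences of the copying HMM (K ≤ 3, L ≤ 6), all at
$10^{-10}$ tolerance. Stochastic properties run at deliberately modest
sizes chosen to finish in minutes on one core while keeping Monte-Carlo
error well inside the asserted margins: Balding–Nichols moment and G_ST
recovery at $L = 5{,}000$ loci (relative sampling error ≈ 2%, asserted
within 10%), reference selection over 50 replicates at $L = 2{,}000$,
the pre-phasing comparison over 30 paired replicates of $N = 40$
individuals × 500 SNPs with 60-haplotype panels and 50% masking, and the
null calibration of the McNemar machinery over 2,000 replicates of 1,000
paired units (expected rejection ≈ 5%, asserted within [3%, 7%]).

# Known limitations

- The imputer is a stand-in: it demonstrates and tests the evaluation
  machinery and reproduces directional phenomena (pre-phasing penalty,
  reference-distance effects), but its absolute accuracies are not those
  of production tools; score distributions from real tools should be
  ingested through the MaCH/IMPUTE2/VCF adapters.
- The G_ST-based matching uses sample frequencies only; it does not
  perform IBS-segment or piecewise reference selection as
  admixed-reference tools do internally.
- Exact stratified HWE beyond the enumeration bound falls back to
  Monte-Carlo with a fixed internal seed: p-values are then reproducible
  estimates, not exact values.
- The comparison tests assume exchangeable units; strong residual LD
  among HQ SNPs would make the McNemar test anti-conservative, which is
  why the HQ-pair LD fraction is reported alongside.
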