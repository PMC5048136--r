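Package: imputeval
Title: Evaluating Genotype Imputation Accuracy by Masking and Re-Imputation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking genotype-imputation frameworks by masking
    high-quality SNPs and scoring the re-imputed genotype posteriors with
    platform-independent measures (Hellinger and SEN scores, best-guess
    concordance) alongside the software-specific MaCH-Rsq and IMPUTE-info
    scores. Includes SNP quality control with an exact (optionally stratified)
    Hardy-Weinberg test, nested masking plans, Nei's G_ST reference-panel
    matching, paired one-sided McNemar and Wilcoxon framework comparisons, a
    seedable population-genetic simulator (Balding-Nichols divergence with a
    mosaic haplotype-copying LD model), and a Li-Stephens-style copying-model
    imputer with joint and pre-phased modes so the whole evaluation pipeline
    runs on synthetic data. Readers and writers are provided for PLINK
    ped/map, IMPUTE2 gen/hap/legend/info, MaCH mldose/mlprob/mlinfo and VCF
    GP/DS formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
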