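#' Configuration for an end-to-end evaluation run
#'
#' Bundles simulation, QC, masking, imputation and scoring settings with a
#' master seed. All stage seeds are derived deterministically from `seed`,
#' so a rerun with the same configuration reproduces every artifact.
#'
#' @param n_snps SNPs per chromosome (default 500).
#' @param n_individuals target individuals (default 40).
#' @param panel_haplotypes haplotypes per reference panel (default 60).
#' @param n_founders founder haplotypes in the mosaic simulator (default 30).
#' @param divergence_close,divergence_far Balding-Nichols drift of the
#'   matched and mismatched candidate reference populations (defaults
#'   0.004 and 0.04, spanning the well-matched cutoff G_ST = 0.010).
#' @param panel_switch_rate,target_switch_rate mosaic switch rates used
#'   when simulating panels and targets (default 0.01).
#' @param qc_preset `"popres"` or `"life"` (see [qc_preset()]).
#' @param mask_fractions ascending missingness fractions
#'   (default `c(0.5, 0.7, 1)`).
#' @param modes imputer modes to run (default joint and prephased).
#' @param error_rate,switch_prob HMM parameters (see [hmm_params()]).
#' @param cutoff Hellinger well-imputed cutoff in (0, 1) (default 0.45).
#' @param seed master integer seed.
#' @param outdir output directory, or `NULL` to skip writing artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_snps = 500, n_individuals = 40,
                       panel_haplotypes = 60, n_founders = 30,
                       divergence_close = 0.004, divergence_far = 0.04,
                       panel_switch_rate = 0.01, target_switch_rate = 0.01,
                       qc_preset = "popres",
                       mask_fractions = c(0.5, 0.7, 1.0),
                       modes = c("joint", "prephased"),
                       error_rate = 0.01, switch_prob = 0.001,
                       cutoff = 0.45, seed = 1L, outdir = NULL) {
  if (is.unsorted(mask_fractions, strictly = TRUE) ||
      any(mask_fractions <= 0) || any(mask_fractions > 1)) {
    stop("mask_fractions must be strictly ascending and lie in (0, 1]")
  }
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  modes <- match.arg(modes, c("joint", "prephased"), several.ok = TRUE)
  structure(list(n_snps = n_snps, n_individuals = n_individuals,
                 panel_haplotypes = panel_haplotypes,
                 n_founders = n_founders,
                 divergence_close = divergence_close,
                 divergence_far = divergence_far,
                 panel_switch_rate = panel_switch_rate,
                 target_switch_rate = target_switch_rate,
                 qc_preset = qc_preset, mask_fractions = mask_fractions,
                 modes = modes, error_rate = error_rate,
                 switch_prob = switch_prob, cutoff = cutoff,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; absent keys keep their
#' defaults.
#'
#' @param path YAML file path.
#' @param ... overrides applied on top of the file.
#' @return An object of class `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

stage_seed <- function(config, offset) {
  (config$seed * 97L + offset * 1009L) %% .Machine$integer.max
}

pipeline_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Run the full evaluation pipeline
#'
#' Orchestrates simulate, QC, mask, reference matching, imputation in each
#' configured mode, scoring and framework comparison, deterministically
#' under the configured seed:
#' \enumerate{
#'   \item simulate an ancestral population, a target population at
#'     `divergence_close`, and two candidate reference panels — one from
#'     the target's own population, one from a population at
#'     `divergence_far`;
#'   \item select HQ SNPs with the configured QC preset;
#'   \item draw a nested mask plan over the HQ SNPs and apply each
#'     fraction;
#'   \item choose the reference panel minimizing Nei's G_ST;
#'   \item impute every masked scenario in each mode and score against the
#'     masked truth;
#'   \item compare modes one-sided against the best per scenario.
#' }
#' When `config$outdir` is set, every stage writes its artifact (panels as
#' `.hap`/`.legend`, targets as `.ped`/`.map`, QC report, mask plan JSON,
#' imputations as `.mlprob`/`.mldose`/`.mlinfo`, score TSVs, comparison
#' TSV and Markdown, and a JSON manifest).
#'
#' @param config a [run_config()].
#' @param quiet suppress stage messages (default `FALSE`).
#' @return list with `qc`, `hq_ids`, `mask_plan`, `reference`,
#'   `summaries` (per scenario x mode), `comparisons` (per scenario) and
#'   `records` (per scenario x mode score tables).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$outdir
  if (!is.null(out) && !dir.exists(out)) {
    dir.create(out, recursive = TRUE)
  }
  save_path <- function(...) if (is.null(out)) NULL else file.path(out, ...)

  # --- simulate -----------------------------------------------------------
  pipeline_log(quiet, "[simulate] L=%d SNPs, N=%d individuals, seed=%d",
               config$n_snps, config$n_individuals, config$seed)
  set.seed(stage_seed(config, 1L))
  ancestral <- stats::runif(config$n_snps, 0.15, 0.85)
  target_freqs <- draw_subpopulation_freqs(ancestral, config$divergence_close)
  far_freqs <- draw_subpopulation_freqs(ancestral, config$divergence_far)
  # targets are mosaics of the close panel, so a well-matched reference with
  # shared haplotype structure exists; the far panel shares only ancestry
  close_panel <- simulate_panel(target_freqs, config$panel_haplotypes,
                                config$n_founders, config$panel_switch_rate,
                                seed = stage_seed(config, 3L))
  far_panel <- simulate_panel(far_freqs, config$panel_haplotypes,
                              config$n_founders, config$panel_switch_rate,
                              seed = stage_seed(config, 4L),
                              snp_info = close_panel$snp_info)
  targets <- simulate_targets(close_panel, config$n_individuals,
                              config$target_switch_rate,
                              seed = stage_seed(config, 5L))
  if (!is.null(out)) {
    write_hap_legend(close_panel, save_path("panel_close"))
    write_hap_legend(far_panel, save_path("panel_far"))
    write_plink(targets, save_path("targets"))
  }

  # --- qc -----------------------------------------------------------------
  criteria <- qc_preset(config$qc_preset)
  qc <- select_hq_snps(targets, criteria)
  hq_ids <- qc$snp_id[qc$is_hq]
  pipeline_log(quiet, "[qc] preset '%s': %d of %d SNPs are HQ",
               criteria$preset_name, length(hq_ids), nrow(qc))
  if (length(hq_ids) < 2) stop("[qc] fewer than 2 HQ SNPs; nothing to mask")
  if (!is.null(out)) write_qc_report(qc, save_path("qc_report.tsv"))

  # --- mask ---------------------------------------------------------------
  plan <- plan_masks(hq_ids, config$mask_fractions,
                     seed = stage_seed(config, 6L))
  pipeline_log(quiet, "[mask] nested sets of sizes %s",
               paste(lengths(plan$masked_sets), collapse = "/"))
  if (!is.null(out)) write_mask_plan(plan, save_path("mask_plan.json"))

  # --- reference matching -------------------------------------------------
  ref <- select_reference(targets,
                          list(close = close_panel, far = far_panel))
  pipeline_log(quiet,
               "[match] best reference '%s' (G_ST=%.4f, well_matched=%s)",
               ref$best, ref$ranking$gst[1], ref$well_matched)
  panel <- if (ref$best == "close") close_panel else far_panel
  if (!is.null(out)) {
    utils::write.table(ref$ranking, save_path("reference_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- impute and score ---------------------------------------------------
  records <- list()
  summaries <- list()
  comparisons <- list()
  ld_frac <- hq_ld_fraction(targets, hq_ids)
  for (fr in names(plan$masked_sets)) {
    masked <- apply_mask(targets, plan$masked_sets[[fr]])
    scenario <- paste0("mask", fr)
    per_mode <- list()
    for (mode in config$modes) {
      pipeline_log(quiet, "[impute] scenario %s, mode %s", scenario, mode)
      params <- hmm_params(config$error_rate, config$switch_prob, mode)
      pt <- impute(masked$masked, panel, params)
      rec <- score_imputation(masked$truth, pt, config$cutoff)
      per_mode[[mode]] <- rec
      summaries[[paste(scenario, mode, sep = ".")]] <-
        c(list(scenario = scenario, mode = mode),
          summarize_scores(rec, config$cutoff)[
            c("n", "pct_well_imputed", "pct_correct_best_guess",
              "mean_hellinger", "mean_sen")])
      if (!is.null(out)) {
        write_mach(pt, save_path(paste0("imputed_", scenario, "_", mode)))
        write_scores(rec, save_path(paste0("scores_", scenario, "_", mode,
                                           ".tsv")))
      }
    }
    records[[scenario]] <- per_mode
    if (length(per_mode) >= 2) {
      cmp <- build_comparison_table(per_mode, metric = "well_imputed",
                                    ld_fraction = ld_frac)
      comparisons[[scenario]] <- cmp
      if (!is.null(out)) {
        utils::write.table(cbind(scenario = scenario, cmp),
                           save_path(paste0("comparison_", scenario, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeLines(format_comparison_md(cmp),
                   save_path(paste0("comparison_", scenario, ".md")))
      }
    }
  }
  summary_df <- do.call(rbind, lapply(summaries, function(s) {
    as.data.frame(s, stringsAsFactors = FALSE)
  }))
  rownames(summary_df) <- NULL
  if (!is.null(out)) {
    utils::write.table(summary_df, save_path("summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_manifest(c(unclass(config)[setdiff(names(unclass(config)),
                                             "outdir")],
                     list(hq_snps = length(hq_ids),
                          best_reference = ref$best,
                          hq_ld_fraction = ld_frac)),
                   save_path("manifest.json"))
  }
  list(qc = qc, hq_ids = hq_ids, mask_plan = plan, reference = ref,
       hq_ld_fraction = ld_frac, summaries = summary_df,
       comparisons = comparisons, records = records)
}
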