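#' Run the whole design-and-evaluation pipeline on synthetic data
#'
#' Drives every stage from a single [sim_config()]: generate a genome, plant
#' a candidate pool, run the reduction cascade, select the array content
#' with a [selection_plan()], simulate genotyping of the selected markers,
#' and classify marker performance. Used for desk-scale end-to-end checks.
#'
#' @param config a [sim_config()].
#' @param thresholds a [filter_thresholds()].
#' @param plan a [selection_plan()]; spacings far above the synthetic
#'   genome's extent would empty the array, so pass a desk-scale plan (the
#'   default here spaces every category at 100-2000 bp).
#' @param call_rate_threshold threshold for performance classification.
#' @return list with `genome`, `candidates`, `truth`, `filtered`,
#'   `stage_report`, `selected`, `genotypes` (a [genotype_matrix()]),
#'   `performance`, `summary` (an [eval_summary()]), and `array_total`.
#' @export
run_design_pipeline <- function(config = sim_config(),
                                thresholds = filter_thresholds(),
                                plan = NULL,
                                call_rate_threshold = 0.95) {
  set.seed(config$seed)
  g <- config$genome
  genome0 <- gen_genome(g$n_chroms, g$chrom_length, g$n_scaffolds,
                        g$scaffold_length, g$gc_fraction)
  v <- config$variants
  planted <- plant_variants(genome0, density_per_kb = v$density_per_kb,
                            category_props = v$category_props,
                            frac_run_violation = v$frac_run_violation,
                            frac_gc_violation = v$frac_gc_violation,
                            frac_dup_flank = v$frac_dup_flank,
                            frac_proximity = v$frac_proximity,
                            thresholds = thresholds)
  cascade <- run_filter_cascade(planted$records, planted$genome, thresholds)
  if (is.null(plan))
    plan <- selection_plan(list(
      category_spec("nonsyn",           1, 100),
      category_spec("utr3",             2, 100),
      category_spec("utr5",             3, 100),
      category_spec("transcript_other", 4, 500),
      category_spec("strain_shared",    5, 1000),
      category_spec("strain_specific",  6, 2000)))
  selected <- greedy_select(cascade$records, plan)
  gt <- config$genotypes
  sim <- gen_genotypes(selected, n_populations = gt$n_populations,
                       n_per_pop = gt$n_per_pop,
                       divergence = gt$divergence,
                       families = gt$families, ld_rho = gt$ld_rho,
                       missing_rate = gt$missing_rate,
                       error_rate = gt$error_rate,
                       error_mode = gt$error_mode)
  perf <- snp_performance(sim$gm, call_rate_threshold)
  array_total <- nrow(selected)
  summ <- eval_summary(perf, array_total, call_rate_threshold)
  list(genome = planted$genome, candidates = planted$records,
       truth = planted$truth, filtered = cascade$records,
       stage_report = cascade$report, selected = selected,
       genotypes = sim$gm, genotype_truth = sim$truth,
       performance = perf, summary = summ, array_total = array_total)
}
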