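#' Published design counts for the 250K common carp array
#'
#' The per-stage and per-class counts printed for the first high-density
#' common carp (*Cyprinus carpio*) genotyping array, shipped as plain-text
#' tables so the package's accounting operations can be exercised against
#' real design numbers:
#'
#' * `coverage` — genome re-sequencing of the 18 founder accessions (raw and
#'   mapped gigabases, mapping and coverage rates, depth).
#' * `strain_counts` — SNPs called per strain and the strain-specific
#'   subsets.
#' * `design_stages` — candidates surviving each reduction stage, per SNP
#'   category (input to [design_summary()]).
#' * `array_evaluation` — performance-class counts for the carp samples and
#'   for related Cyprinid species.
#' * `headline` — standalone printed counts (non-redundant pool, shared-by-
#'   all-strains count, array size, related-species polymorphic count,
#'   call-rate-passing count).
#'
#' @return named list of data.frames as described above.
#' @export
design_reference_tables <- function() {
  rd <- function(f) read.table(
    system.file("extdata", f, package = "arrayforge", mustWork = TRUE),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  list(coverage = rd("resequencing_coverage.tsv"),
       strain_counts = rd("strain_snp_counts.tsv"),
       design_stages = rd("design_stage_counts.tsv"),
       array_evaluation = rd("array_evaluation_counts.tsv"),
       headline = rd("evaluation_headline_counts.tsv"))
}
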