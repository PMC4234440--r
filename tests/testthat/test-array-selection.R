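tmap_default <- c(nonsyn = 100, utr3 = 100, utr5 = 100,
                  transcript_other = 1800, strain_shared = 10000,
                  strain_specific = 17000)

test_that("greedy selection honours per-category spacing thresholds", {
  one <- snp_records("chr1", 500, "A", "G", qual = 40,
                     category = "nonsyn")
  expect_identical(nrow(greedy_select(one)), 1L)

  # two strain-specific SNPs 16,999 bp apart: only the better one fits
  two <- snp_records("chr1", c(20000, 36999), "A", "G", qual = c(30, 50),
                     category = "strain_specific")
  sel <- greedy_select(two)
  expect_identical(sel$pos, 36999L)

  # a transcript SNP 2,000 bp from a selected transcript SNP is acceptable
  tr <- snp_records("chr1", c(10000, 12000), "A", "G", qual = c(50, 40),
                    category = "transcript_other")
  expect_identical(nrow(greedy_select(tr)), 2L)

  bad <- snp_records("chr1", 100, "A", "G", qual = 10)
  bad$category <- "mystery"
  expect_error(greedy_select(bad), "not covered")
})

make_pool <- function(n, seed, span = 1e6, chroms = 10) {
  set.seed(seed)
  data.frame(chrom = sample(paste0("chr", seq_len(chroms)), n, TRUE),
             pos = sample.int(span, n), ref = "A", alt = "G",
             category = sample(names(tmap_default), n, TRUE),
             qual = round(runif(n, 20, 60), 2),
             stringsAsFactors = FALSE)
}

test_that("greedy selection is deterministic, spacing-valid and maximal", {
  cand <- make_pool(10000, seed = 101)
  sel <- greedy_select(cand)
  expect_true(oracle_spacing_ok(sel, tmap_default))
  expect_true(oracle_greedy_maximal(cand, sel, tmap_default))
  sel2 <- greedy_select(cand)
  expect_identical(sel, sel2)
})

test_that("higher-priority selections are unaffected by lower categories", {
  cand <- make_pool(3000, seed = 7)
  plan_full <- selection_plan()
  sel_full <- greedy_select(cand, plan_full)
  cand_hi <- cand[cand$category != "strain_specific", ]
  plan_hi <- selection_plan(list(
    category_spec("nonsyn", 1, 100), category_spec("utr3", 2, 100),
    category_spec("utr5", 3, 100),
    category_spec("transcript_other", 4, 1800),
    category_spec("strain_shared", 5, 10000)))
  sel_hi <- greedy_select(cand_hi, plan_hi)
  hi <- sel_full[sel_full$category != "strain_specific", ]
  expect_identical(marker_ids(hi), marker_ids(sel_hi))
})

test_that("quotas and the overall target cap selection size", {
  cand <- make_pool(2000, seed = 8, span = 1e7)
  plan <- selection_plan(list(
    category_spec("nonsyn", 1, 100, quota = 5),
    category_spec("utr3", 2, 100, quota = 5),
    category_spec("utr5", 3, 100, quota = 5),
    category_spec("transcript_other", 4, 100, quota = 5),
    category_spec("strain_shared", 5, 100, quota = 5),
    category_spec("strain_specific", 6, 100, quota = 5)),
    target_total = 20)
  sel <- greedy_select(cand, plan)
  expect_identical(nrow(sel), 20L)
  expect_true(all(attr(sel, "category_counts") <= 5))
})

test_that("interval statistics are computed within chromosomes only", {
  sel <- data.frame(chrom = "chr1", pos = c(1000, 4000, 9000))
  ih <- interval_histogram(sel)
  expect_identical(ih$intervals$interval, c(3000, 5000))
  expect_identical(ih$mean_interval, 4000)

  two <- data.frame(chrom = c("chr1", "chr2"), pos = c(100, 100))
  ih2 <- interval_histogram(two)
  expect_identical(nrow(ih2$intervals), 0L)
  expect_true(is.na(ih2$mean_interval))

  grid <- data.frame(chrom = "chr1", pos = seq(5000, 50000, by = 5000))
  ih3 <- interval_histogram(grid)
  expect_true(all(ih3$intervals$interval == 5000))
  expect_identical(ih3$mean_interval, 5000)
  expect_identical(sum(ih3$histogram$n), nrow(grid) - 1L)
})

test_that("density report covers chromosomes and the pseudo-scaffold P", {
  g <- genome(c(chr1 = strrep("A", 100), scaffold1 = strrep("A", 60),
                scaffold2 = strrep("A", 40)))
  g$lengths <- c(chr1 = 2e6, scaffold1 = 5e5, scaffold2 = 5e5)  # virtual
  sel <- data.frame(
    chrom = c(rep("chr1", 300), rep("scaffold1", 40), rep("scaffold2", 21)),
    pos = c(sample.int(2e6, 300), sample.int(5e5, 40), sample.int(5e5, 21)))
  dr <- density_report(sel, g)
  expect_identical(dr$density$density_per_mb[dr$density$chrom == "chr1"],
                   150)
  expect_identical(dr$density$density_per_mb[dr$density$chrom == "P"], 61)
  none <- density_report(sel[sel$chrom == "chr1", ], g)
  expect_identical(none$density$n_snps[none$density$chrom == "P"], 0L)
})

test_that("design summary reproduces published stage totals", {
  tabs <- design_reference_tables()
  ds <- design_summary(tabs$design_stages)
  expect_equal(unname(ds$totals["original"]), 15366108)
  expect_equal(unname(ds$totals["final"]), 250000)
  final <- ds$counts[, "final"]
  expect_equal(unname(sum(final[c("nonsyn", "utr3", "utr5",
                                  "transcript_other")])), 147026)
  expect_equal(unname(sum(final[c("utr3", "utr5")])), 5219)

  zero <- design_summary(matrix(0, 2, 3))
  expect_true(all(zero$totals == 0))

  bad <- tabs$design_stages
  bad$gc[1] <- bad$runs[1] + 1
  expect_error(design_summary(bad), "increases at stage 'gc'")
})
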