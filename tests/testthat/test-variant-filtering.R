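th <- filter_thresholds()

test_that("primary filter applies the call-statistic thresholds", {
  rec <- snp_records("chr1", c(100, 200, 300, 400), "A", "G",
                     qual = c(30, 30, 19, 30), depth = c(9, 15, 15, 15),
                     mac = c(3, 1, 3, 3), maf = c(0.2, 0.04, 0.2, 0.2))
  out <- filter_primary(rec, th)
  expect_identical(out$records$pos, 400L)   # depth 9, mac 1, qual 19 all fail
  expect_identical(out$report$removed_count, 3L)

  rec$maf[1] <- NA
  expect_error(filter_primary(rec, th), "missing field 'maf'")

  empty <- filter_primary(rec[0, ], th)
  expect_identical(empty$report$input_count, 0L)
  expect_identical(empty$report$removed_count, 0L)
})

test_that("flank extraction returns centred context and flags edges", {
  seqs <- paste(sample(c("A", "C", "G", "T"), 71, TRUE), collapse = "")
  g <- genome(c(chr1 = seqs))
  fl <- extract_flank(g, "chr1", 36)
  expect_identical(fl, seqs)                       # exact fit
  expect_true(isTRUE(attr(extract_flank(g, "chr1", 10), "edge")))
  ref_at_36 <- substr(seqs, 36, 36)
  wrong <- setdiff(c("A", "C", "G", "T"), ref_at_36)[1]
  expect_error(extract_flank(g, "chr1", 36, ref = wrong), "record says")
})

test_that("homopolymer screen matches its spelled-out boundary cases", {
  # splice the probe between a T and a C so neighbours never extend a run
  mk <- function(insert)
    paste0(strrep("ACGT", 8), insert,
           substr(strrep("CGTA", 10), 1, 39 - nchar(insert)))
  expect_false(flank_run_filter(mk("GGGGG"), th)$pass)   # run of 5 G
  expect_identical(flank_run_filter(mk("GGGGG"), th)$reason, "gc_run")
  ok <- mk("GGGG")                                       # run of exactly 4
  ok2 <- mk("AAAAAA")                                    # run of exactly 6
  expect_true(flank_run_filter(ok, th)$pass)
  expect_true(flank_run_filter(ok2, th)$pass)
  expect_false(flank_run_filter(mk("AAAAAAA"), th)$pass) # run of 7 A
  expect_false(flank_run_filter(mk("N"), th)$pass)
  expect_identical(flank_run_filter(mk("N"), th)$reason, "N")
})

test_that("homopolymer screen agrees with a brute-force scanner", {
  set.seed(42)
  flanks <- replicate(1000, random_flank(allow_n = runif(1) < 0.3))
  got <- flank_run_filter(flanks, th)$pass
  want <- vapply(flanks, oracle_run_scan, logical(1), USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("base-class run mode counts runs over {G,C} and {A,T}", {
  fl <- paste0("GCGCG", substr(strrep("ACGT", 17), 1, 66))
  expect_true(flank_run_filter(fl, th)$pass)       # no same-base run
  th2 <- filter_thresholds(run_mode = "base_class")
  expect_false(flank_run_filter(fl, th2)$pass)     # 5 consecutive S bases
})

test_that("GC screen is inclusive at both bounds", {
  mk_gc <- function(n_gc) paste0(strrep("G", n_gc), strrep("A", 71 - n_gc))
  th_norun <- filter_thresholds(max_gc_run = 71, max_at_run = 71)
  expect_false(gc_filter(mk_gc(0), th_norun))       # all-A extreme
  expect_false(gc_filter(mk_gc(21), th_norun))      # 21/71 = 29.6%
  expect_true(gc_filter(mk_gc(22), th_norun))       # 22/71 = 31.0%
  expect_true(gc_filter(mk_gc(49), th_norun))       # 49/71 = 69.0%
  expect_false(gc_filter(mk_gc(50), th_norun))      # 50/71 = 70.4%
})

test_that("uniqueness filter counts both strands and planted duplicates", {
  set.seed(5)
  g <- gen_genome(1, 30000, 0, gc_fraction = 0.45, seed = 5)
  pv <- plant_variants(g, n_variants = 8, seed = 6)
  rec <- extract_flanks(pv$records, pv$genome)
  idx <- build_uniqueness_index(pv$genome)
  out <- uniqueness_filter(rec, idx)
  expect_identical(nrow(out$records), nrow(rec))    # random genome: unique

  # duplicate a 200-bp block containing the first SNP
  s <- pv$genome$sequences[["chr1"]]
  block <- substr(s, rec$pos[1] - 100, rec$pos[1] + 99)
  g2 <- genome(c(chr1 = paste0(s, block)))
  out2 <- uniqueness_filter(rec, build_uniqueness_index(g2))
  expect_false(rec$pos[1] %in% out2$records$pos)

  # appending the reverse complement is also a second hit
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(block)))
  g3 <- genome(c(chr1 = paste0(s, rc)))
  out3 <- uniqueness_filter(rec, build_uniqueness_index(g3))
  expect_false(rec$pos[1] %in% out3$records$pos)

  rec$flank[2] <- NA
  expect_error(uniqueness_filter(rec, idx), "flank absent")
})

test_that("proximity filter reproduces its documented examples", {
  mk <- function(pos) snp_records("chr1", pos, "A", "G")
  expect_identical(nrow(proximity_filter(mk(c(100, 108)), th)$records), 0L)
  expect_identical(nrow(proximity_filter(mk(c(100, 120, 130)), th)$records),
                   0L)
  out <- proximity_filter(mk(c(100, 150, 200)), th)
  expect_identical(out$records$pos, c(100L, 150L, 200L))
})

test_that("proximity filter agrees with the O(n^2) oracle", {
  set.seed(99)
  for (rep in 1:4) {
    pos <- sort(sample.int(if (rep %% 2) 20000L else 4000L, 500L))
    rec <- snp_records("chr1", pos, "A", "G")
    out <- proximity_filter(rec, th)
    removed <- oracle_proximity_removed(pos)
    expect_identical(out$records$pos, pos[!removed])
  }
})

test_that("conversion-score threshold is inclusive and mode-aware", {
  rec <- snp_records("chr1", c(100, 200, 300), "A", "G")
  sc <- data.frame(marker_id = c("chr1:100", "chr1:200", "chr1:300"),
                   pconvert_forward = c(0.60, 0.57, 0.58),
                   pconvert_reverse = c(0.10, 0.57, 0.00))
  out <- pconvert_filter(rec, sc, th)
  expect_identical(out$records$pos, c(100L, 300L))
  th_both <- filter_thresholds(pconvert_mode = "both")
  expect_identical(nrow(pconvert_filter(rec, sc, th_both)$records), 0L)
  expect_error(pconvert_filter(rec, sc[-1, ], th), "chr1:100")
})

test_that("filters are idempotent and reports conserve counts", {
  set.seed(12)
  pos <- sort(sample.int(30000L, 300L))
  rec <- snp_records("chr1", pos, "A", "G", qual = runif(300, 10, 60),
                     depth = 5L + rpois(300, 10), mac = 2L, maf = 0.2)
  p1 <- filter_primary(rec, th)
  p2 <- filter_primary(p1$records, th)
  expect_identical(p2$records, p1$records)
  x1 <- proximity_filter(rec, th)
  x2 <- proximity_filter(x1$records, th)
  expect_identical(x2$records, x1$records)
  for (r in list(p1$report, x1$report))
    expect_identical(r$input_count, r$output_count + r$removed_count)
})

test_that("cascade attrition is monotone and runs/GC order is immaterial", {
  g <- gen_genome(3, 60000, 1, 20000, gc_fraction = 0.42, seed = 21)
  pv <- plant_variants(g, n_variants = 150, frac_run_violation = 0.1,
                       frac_gc_violation = 0.1, frac_proximity = 0.1,
                       seed = 22)
  cc <- run_filter_cascade(pv$records, pv$genome, th)
  expect_true(all(diff(cc$report$output_count) <= 0))
  expect_true(all(cc$report$input_count ==
                    cc$report$output_count + cc$report$removed_count))
  expect_identical(cc$report$input_count[-1],
                   cc$report$output_count[-nrow(cc$report)])

  # per-record predicates: applying GC before runs keeps the same survivors
  rec <- extract_flanks(filter_primary(pv$records, th)$records, pv$genome)
  ab <- rec[flank_run_filter(rec$flank, th)$pass & !rec$edge, ]
  ab <- ab[gc_filter(ab$flank, th), ]
  ba <- rec[gc_filter(rec$flank, th) & !rec$edge, ]
  ba <- ba[flank_run_filter(ba$flank, th)$pass, ]
  expect_identical(marker_ids(ab), marker_ids(ba))
})
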