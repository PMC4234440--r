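test_that("read_fasta handles minimal, empty and invalid inputs", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "acgt"), f)
  g <- read_fasta(f)
  expect_identical(unname(g$lengths), 4L)
  expect_identical(unname(g$sequences[["chr1"]]), "ACGT")

  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  expect_identical(length(read_fasta(empty)), 0L)

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT", ">chr1", "GGCC"), dup)
  expect_error(read_fasta(dup), "duplicate")
})

test_that("fasta headers are tokenised and scaffolds classified", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 assembled chromosome", "ACGTN",
               ">scaffold7 leftover", "TTTT"), f)
  g <- read_fasta(f)
  expect_identical(names(g$sequences), c("chr1", "scaffold7"))
  expect_identical(g$placed_names, "chr1")
  expect_identical(g$unplaced_names, "scaffold7")
})

test_that("read_vcf keeps only valid biallelic SNPs and counts skips", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tA\tG\t30\tPASS\tDP=15;MAC=3;MAF=0.2",
    "chr1\t200\t.\tA\tAT\t30\tPASS\tDP=15;MAC=3;MAF=0.2",
    "chr1\t300\t.\tA\tG,T\t30\tPASS\tDP=15;MAC=3;MAF=0.2"), f)
  rec <- read_vcf(f)
  expect_identical(nrow(rec), 1L)
  expect_identical(attr(rec, "n_skipped"), 2L)
  expect_identical(rec$pos, 100L)
  expect_identical(rec$qual, 30)
  expect_identical(rec$depth, 15L)

  g <- genome(c(chr1 = "ACGT"))  # position 100 beyond length 4
  expect_error(read_vcf(f, g), "beyond chromosome length")
})

test_that("vcf round-trip preserves candidate records", {
  set.seed(1)
  g <- gen_genome(2, 20000, 0, gc_fraction = 0.4, seed = 2)
  pv <- plant_variants(g, n_variants = 10, seed = 3)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(pv$records, f)
  back <- read_vcf(f, pv$genome)
  for (col in c("chrom", "pos", "ref", "alt", "depth", "mac", "maf",
                "category"))
    expect_identical(back[[col]], pv$records[[col]])
})

test_that("ped/map dosage conversion follows the allele conventions", {
  ped <- withr::local_tempfile(); map <- withr::local_tempfile()
  writeLines(c("F1 S1 0 0 0 -9 A A A G 0 0",
               "F1 S2 0 0 0 -9 A G G G A A"), ped)
  writeLines(c("1\tm1\t0\t100", "1\tm2\t0\t200", "1\tm3\t0\t300"), map)
  gm <- read_pedmap(ped, map)
  expect_identical(unname(gm$calls[1, ]), c(0L, 1L, NA_integer_))
  # m3 shows a single allele, which becomes the alt by the lexicographic
  # rule; an allele table is needed to orient monomorphic markers
  expect_identical(unname(gm$calls[2, ]), c(1L, 2L, 2L))

  badmap <- withr::local_tempfile()
  writeLines(c("1\tm1\t0\t100", "1\tm2\t0\t200"), badmap)
  expect_error(read_pedmap(ped, badmap), "allele columns")
})

test_that("ped/map round-trip is lossless including pedigree and missing", {
  sim <- gen_genotypes(gen_markers(8, 2, 500), n_populations = 1,
                       n_per_pop = 3,
                       families = list(list(population = 1,
                                            n_offspring = 2)),
                       missing_rate = 0.15, error_rate = 0, seed = 9)
  ped <- withr::local_tempfile(); map <- withr::local_tempfile()
  write_pedmap(sim$gm, ped, map)
  al <- data.frame(marker_id = sim$gm$marker_map$marker_id,
                   ref = "A", alt = "C")
  back <- read_pedmap(ped, map, alleles = al)
  expect_identical(back$calls, sim$gm$calls)
  expect_identical(back$sample_meta$father_id, sim$gm$sample_meta$father_id)
  expect_identical(back$marker_map$pos, sim$gm$marker_map$pos)
})

test_that("snp table round-trips field-for-field, including empty tables", {
  g <- gen_genome(1, 20000, 0, gc_fraction = 0.45, seed = 7)
  pv <- plant_variants(g, n_variants = 10, seed = 8)
  rec <- extract_flanks(pv$records, pv$genome)[, 1:11]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_snp_table(rec, f)
  back <- read_snp_table(f)
  expect_equal(back, rec, ignore_attr = TRUE)

  write_snp_table(rec[0, ], f)
  expect_identical(nrow(read_snp_table(f)), 0L)
})

test_that("record validation enforces the candidate invariants", {
  expect_error(snp_records("chr1", 5, "A", "A"), "identical")
  expect_error(snp_records("chr1", 5, "A", "N"), "single bases")
  expect_error(snp_records("chr1", 5, "A", "G", maf = 0.7), "MAF")
  g <- genome(c(chr1 = "ACGTACGT"))
  expect_error(snp_records("chr1", 9, "A", "G", genome = g), "beyond")
  expect_silent(validate_snp_records(
    snp_records("chr1", 3, "G", "A", maf = 0.3, genome = g), g))
})
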