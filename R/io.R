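#' @importFrom utils read.table write.table head
NULL

#' Recognised SNP functional/source categories
#'
#' Candidate SNPs are classed by their annotation source: non-synonymous
#' coding changes, 3'/5' UTR variants, other transcript variants, and
#' re-sequencing variants either shared between strains or private to one.
#' Category drives selection priority and spacing (see [selection_plan()]).
#' @export
SNP_CATEGORIES <- c("nonsyn", "utr3", "utr5", "transcript_other",
                    "strain_shared", "strain_specific")

SNP_TABLE_COLS <- c("chrom", "pos", "ref", "alt", "qual", "depth",
                    "mac", "maf", "category", "strain", "flank")

#' Candidate SNP table constructor
#'
#' Builds and validates the canonical candidate-SNP data.frame used across the
#' package: one row per biallelic SNP with position, alleles, call statistics
#' (quality, depth, minor-allele count and frequency), category and an
#' optional 71-bp flanking sequence centred on the reference base.
#'
#' @param chrom,pos,ref,alt,qual,depth,mac,maf,category,strain,flank vectors,
#'   recycled to a common length. `strain` and `flank` may be `NA`.
#' @param genome optional [genome()]; when given, positions are validated
#'   against sequence lengths.
#' @return data.frame with columns
#'   `chrom, pos, ref, alt, qual, depth, mac, maf, category, strain, flank`.
#' @export
snp_records <- function(chrom, pos, ref, alt, qual = NA_real_,
                        depth = NA_integer_, mac = NA_integer_,
                        maf = NA_real_, category = NA_character_,
                        strain = NA_character_, flank = NA_character_,
                        genome = NULL) {
  rec <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                    ref = as.character(ref), alt = as.character(alt),
                    qual = as.numeric(qual), depth = as.integer(depth),
                    mac = as.integer(mac), maf = as.numeric(maf),
                    category = as.character(category),
                    strain = as.character(strain),
                    flank = as.character(flank),
                    stringsAsFactors = FALSE)
  validate_snp_records(rec, genome)
  rec
}

#' Validate a candidate SNP table
#'
#' Checks the invariants of the candidate table: single-base distinct
#' ref/alt alleles, MAF at most 0.5, positions inside the genome when one is
#' supplied, and 71-bp flanks whose centre base equals the reference allele.
#' @param records candidate SNP data.frame (see [snp_records()]).
#' @param genome optional [genome()] for positional validation.
#' @return `records`, invisibly, or an error naming the first offending row.
#' @export
validate_snp_records <- function(records, genome = NULL) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(c("chrom", "pos", "ref", "alt"), names(records))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(records) == 0L) return(invisible(records))
  bad <- function(i, why) stop("record ", i, " (", records$chrom[i], ":",
                               records$pos[i], "): ", why)
  ok_base <- function(x) x %in% c("A", "C", "G", "T")
  i <- which(!ok_base(records$ref) | !ok_base(records$alt))
  if (length(i)) bad(i[1L], "alleles must be single bases in A/C/G/T")
  i <- which(records$ref == records$alt)
  if (length(i)) bad(i[1L], "ref and alt alleles are identical")
  i <- which(records$pos < 1L)
  if (length(i)) bad(i[1L], "position below 1")
  if (!is.null(records$maf)) {
    i <- which(!is.na(records$maf) & (records$maf < 0 | records$maf > 0.5))
    if (length(i)) bad(i[1L], "MAF outside [0, 0.5]")
  }
  if (!is.null(records$category)) {
    i <- which(!is.na(records$category) &
                 !records$category %in% SNP_CATEGORIES)
    if (length(i)) bad(i[1L], paste0("unknown category '",
                                     records$category[i[1L]], "'"))
  }
  if (!is.null(genome)) {
    i <- which(!records$chrom %in% names(genome$sequences))
    if (length(i)) bad(i[1L], "chromosome not in genome")
    i <- which(records$pos > genome$lengths[records$chrom])
    if (length(i)) bad(i[1L], "position beyond chromosome length")
  }
  if (!is.null(records$flank)) {
    has <- which(!is.na(records$flank))
    i <- has[nchar(records$flank[has]) != 71L]
    if (length(i)) bad(i[1L], "flank is not 71 bases")
    ctr <- substr(records$flank[has], 36L, 36L)
    i <- has[ctr != records$ref[has]]
    if (length(i)) bad(i[1L], "flank centre base differs from ref allele")
  }
  invisible(records)
}

# ---- FASTA ------------------------------------------------------------------

#' Read a reference genome from FASTA
#'
#' Sequence names are the first whitespace-delimited token of each header;
#' sequences are uppercased. Names matching `unplaced_pattern` are classified
#' as unassembled scaffolds.
#'
#' @param path FASTA file.
#' @inheritParams genome
#' @return a [genome()].
#' @export
read_fasta <- function(path, unplaced_pattern = "^(scaffold|contig|un)") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(genome(character(0)))
  dss <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  nm <- sub("\\s.*$", "", names(dss))
  seqs <- as.character(dss)
  names(seqs) <- nm
  genome(seqs, unplaced_pattern = unplaced_pattern)
}

#' Write a genome to FASTA
#' @param genome a [genome()].
#' @param path output file.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  dss <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

# ---- VCF --------------------------------------------------------------------

#' Read biallelic SNP candidates from a VCF
#'
#' Keeps biallelic single-base substitutions only; indels and multiallelic
#' records are skipped and counted. Call statistics are taken from `QUAL` and
#' the INFO keys `DP`, `MAC`, `MAF`; the optional INFO keys `CATEGORY` and
#' `STRAIN` populate the corresponding columns.
#'
#' @param path VCF file (plain text, VCF 4.x).
#' @param genome optional [genome()]; positions validated when supplied.
#' @return candidate SNP data.frame (see [snp_records()]) with attribute
#'   `n_skipped` = count of non-SNP/non-biallelic records dropped.
#' @export
read_vcf <- function(path, genome = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1,
                                        dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snp)
  info_get <- function(key, numeric = TRUE) {
    x <- vcfR::extract.info(v, element = key, as.numeric = numeric)
    if (length(x) == 0L) rep(NA, nrow(fix)) else x
  }
  cat_raw <- info_get("CATEGORY", numeric = FALSE)
  strain  <- info_get("STRAIN", numeric = FALSE)
  rec <- snp_records(
    chrom = fix[is_snp, "CHROM"], pos = as.integer(fix[is_snp, "POS"]),
    ref = ref[is_snp], alt = alt[is_snp],
    qual = as.numeric(fix[is_snp, "QUAL"]),
    depth = as.integer(info_get("DP")[is_snp]),
    mac = as.integer(info_get("MAC")[is_snp]),
    maf = info_get("MAF")[is_snp],
    category = as.character(cat_raw)[is_snp],
    strain = as.character(strain)[is_snp],
    genome = genome)
  attr(rec, "n_skipped") <- n_skipped
  rec
}

#' Write candidate SNPs as a minimal VCF
#'
#' Emits a VCF 4.2 file with `DP`, `MAC`, `MAF`, `CATEGORY`, `STRAIN` INFO
#' keys, the inverse of [read_vcf()].
#' @param records candidate SNP data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=MAC,Number=1,Type=Integer,Description=\"Minor allele count\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
    "##INFO=<ID=CATEGORY,Number=1,Type=String,Description=\"SNP category\">",
    "##INFO=<ID=STRAIN,Number=1,Type=String,Description=\"Source strain\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- paste0("DP=", records$depth, ";MAC=", records$mac,
                 ";MAF=", format(records$maf, trim = TRUE),
                 ifelse(is.na(records$category), "",
                        paste0(";CATEGORY=", records$category)),
                 ifelse(is.na(records$strain), "",
                        paste0(";STRAIN=", records$strain)))
  body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                format(records$qual, trim = TRUE), "PASS", info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- SNP table --------------------------------------------------------------

#' Write / read the tab-separated candidate SNP table
#'
#' Fixed-header TSV with columns
#' `chrom, pos, ref, alt, qual, depth, mac, maf, category, strain, flank`.
#' The round trip `read_snp_table(write_snp_table(x))` is lossless.
#' @param records candidate SNP data.frame.
#' @param path file path.
#' @return `write_snp_table`: `path` invisibly; `read_snp_table`: the table.
#' @export
write_snp_table <- function(records, path) {
  out <- records[, intersect(SNP_TABLE_COLS, names(records)), drop = FALSE]
  for (col in setdiff(SNP_TABLE_COLS, names(out))) out[[col]] <- NA
  write.table(out[, SNP_TABLE_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_table
#' @export
read_snp_table <- function(path) {
  rec <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(chrom = "character", ref = "character",
                                   alt = "character", category = "character",
                                   strain = "character", flank = "character"),
                    stringsAsFactors = FALSE)
  rec$pos <- as.integer(rec$pos); rec$depth <- as.integer(rec$depth)
  rec$mac <- as.integer(rec$mac)
  validate_snp_records(rec)
  rec
}

# ---- genotype matrix --------------------------------------------------------

#' Genotype matrix container
#'
#' Samples-by-markers matrix of alternate-allele dosages (0, 1, 2; `NA` =
#' missing call) with per-sample metadata (population/strain label, family and
#' parent ids) and a marker map (chromosome, physical position).
#'
#' @param calls integer matrix, rows = samples, columns = markers, values in
#'   `{0, 1, 2, NA}`; dimnames give sample and marker ids.
#' @param sample_meta data.frame with columns `sample_id`, and optionally
#'   `population`, `family_id`, `father_id`, `mother_id`.
#' @param marker_map data.frame with columns `marker_id`, `chrom`, `pos`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sample_meta = NULL, marker_map = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)) && nrow(calls) > 0L)
    rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  if (is.null(colnames(calls)) && ncol(calls) > 0L)
    colnames(calls) <- paste0("M", seq_len(ncol(calls)))
  if (!all(calls %in% c(0L, 1L, 2L, NA)))
    stop("dosages must be 0, 1, 2 or NA")
  if (is.null(sample_meta))
    sample_meta <- data.frame(sample_id = rownames(calls) %||% character(0),
                              population = rep(NA_character_, nrow(calls)),
                              family_id = rep(NA_character_, nrow(calls)),
                              father_id = rep(NA_character_, nrow(calls)),
                              mother_id = rep(NA_character_, nrow(calls)),
                              stringsAsFactors = FALSE)
  stopifnot(identical(sample_meta$sample_id,
                      rownames(calls) %||% character(0)))
  for (col in c("population", "family_id", "father_id", "mother_id"))
    if (is.null(sample_meta[[col]])) sample_meta[[col]] <- NA_character_
  ped_refs <- c(sample_meta$father_id, sample_meta$mother_id)
  ped_refs <- ped_refs[!is.na(ped_refs) & ped_refs != "0"]
  if (!all(ped_refs %in% rownames(calls)))
    stop("pedigree parent id not among sample ids: ",
         setdiff(ped_refs, rownames(calls))[1L])
  if (!is.null(marker_map)) {
    stopifnot(identical(as.character(marker_map$marker_id), colnames(calls)))
    marker_map$pos <- as.integer(marker_map$pos)
  }
  structure(list(calls = calls, sample_meta = sample_meta,
                 marker_map = marker_map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "samples x", ncol(x$calls),
      "markers;", sum(is.na(x$calls)), "missing calls\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

# ---- PED/MAP ----------------------------------------------------------------

#' Read genotypes from PED/MAP files
#'
#' Standard 6-column-prefix PED (family, individual, father, mother, sex,
#' phenotype) with paired allele columns, plus a 4-column MAP (chrom, id,
#' genetic pos, physical pos). Allele pairs become alternate-allele dosages;
#' unless `alleles` is given, the alternate allele of a marker is the
#' lexicographically later of the two alleles observed at it. `0 0` encodes a
#' missing call. The PED family/parent columns populate `sample_meta`
#' (family and population share the PED family field).
#'
#' @param ped_path,map_path file paths.
#' @param alleles optional data.frame `marker_id, ref, alt` fixing dosage
#'   orientation.
#' @return a [genotype_matrix()].
#' @export
read_pedmap <- function(ped_path, map_path, alleles = NULL) {
  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "marker_id", "cm", "pos"),
                    colClasses = c("character", "character", "numeric",
                                   "integer"))
  ped <- read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  n_mark <- nrow(map)
  if (ncol(ped) != 6L + 2L * n_mark)
    stop("PED has ", ncol(ped) - 6L, " allele columns but MAP describes ",
         n_mark, " markers (expected ", 2L * n_mark, " columns)")
  n_samp <- nrow(ped)
  a1 <- as.matrix(ped[, 6L + 2L * seq_len(n_mark) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(n_mark), drop = FALSE])
  calls <- matrix(NA_integer_, n_samp, n_mark)
  for (j in seq_len(n_mark)) {
    obs <- c(a1[, j], a2[, j])
    if (is.null(alleles)) {
      lv <- sort(setdiff(unique(obs), "0"))
      alt <- if (length(lv)) lv[length(lv)] else NA_character_
    } else {
      alt <- alleles$alt[match(map$marker_id[j], alleles$marker_id)]
    }
    miss <- a1[, j] == "0" | a2[, j] == "0"
    calls[, j] <- (a1[, j] == alt) + (a2[, j] == alt)
    calls[miss, j] <- NA_integer_
  }
  rownames(calls) <- ped[[2L]]
  colnames(calls) <- map$marker_id
  meta <- data.frame(sample_id = ped[[2L]], population = ped[[1L]],
                     family_id = ped[[1L]],
                     father_id = ifelse(ped[[3L]] == "0", NA, ped[[3L]]),
                     mother_id = ifelse(ped[[4L]] == "0", NA, ped[[4L]]),
                     stringsAsFactors = FALSE)
  genotype_matrix(calls, meta,
                  marker_map = map[, c("marker_id", "chrom", "pos")])
}

#' Write genotypes to PED/MAP files
#'
#' Inverse of [read_pedmap()]. Dosages are expanded to allele pairs using the
#' per-marker `ref`/`alt` letters in `alleles` (defaults to A as reference and
#' the letter C as alternate so that dosage orientation survives the
#' lexicographic round trip); missing calls become `0 0`.
#'
#' @param gm a [genotype_matrix()] whose `marker_map` is populated.
#' @param ped_path,map_path output paths.
#' @param alleles optional data.frame `marker_id, ref, alt`.
#' @return invisibly, a list of the two paths.
#' @export
write_pedmap <- function(gm, ped_path, map_path, alleles = NULL) {
  if (is.null(gm$marker_map)) stop("genotype_matrix has no marker_map")
  map <- gm$marker_map
  n_mark <- nrow(map)
  if (is.null(alleles))
    alleles <- data.frame(marker_id = map$marker_id, ref = "A", alt = "C",
                          stringsAsFactors = FALSE)
  idx <- match(map$marker_id, alleles$marker_id)
  refL <- alleles$ref[idx]; altL <- alleles$alt[idx]
  d <- gm$calls
  ped_geno <- matrix("0", nrow(d), 2L * n_mark)
  for (j in seq_len(n_mark)) {
    dj <- d[, j]
    p1 <- ifelse(is.na(dj), "0", ifelse(dj >= 1L, altL[j], refL[j]))
    p2 <- ifelse(is.na(dj), "0", ifelse(dj == 2L, altL[j], refL[j]))
    ped_geno[, 2L * j - 1L] <- p1
    ped_geno[, 2L * j] <- p2
  }
  meta <- gm$sample_meta
  prefix <- cbind(ifelse(is.na(meta$family_id), "FAM0", meta$family_id),
                  meta$sample_id,
                  ifelse(is.na(meta$father_id), "0", meta$father_id),
                  ifelse(is.na(meta$mother_id), "0", meta$mother_id),
                  "0", "-9")
  write.table(cbind(prefix, ped_geno), ped_path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(map$chrom, map$marker_id, 0, map$pos), map_path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(list(ped = ped_path, map = map_path))
}
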