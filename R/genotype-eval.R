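#' Performance class labels for assayed markers
#' @export
PERF_CLASSES <- c("PolyHighResolution", "NoMinorHom", "MonoHighResolution",
                  "CallRateBelowThreshold", "OTV", "Other")

#' Call rates of a genotype matrix
#'
#' Fraction of non-missing calls per marker and per sample.
#' @param gm a [genotype_matrix()].
#' @return list `marker` and `sample`, named numeric vectors in `[0, 1]`.
#' @export
call_rate <- function(gm) {
  d <- gm$calls
  if (nrow(d) == 0L || ncol(d) == 0L) stop("empty genotype matrix")
  list(marker = colMeans(!is.na(d)), sample = rowMeans(!is.na(d)))
}

#' Classify one marker's performance
#'
#' Applies, in order: an external off-target-variation flag (OTV markers are
#' identified from hybridisation intensities upstream and only accepted as a
#' flag here); the call-rate threshold (a rate exactly at the threshold
#' passes); monomorphic (exactly one genotype class observed, and it is a
#' homozygote); no-minor-homozygote (heterozygotes and the major homozygote
#' seen, minor homozygote absent); polymorphic high resolution (minor
#' homozygote observed); anything else — e.g. only heterozygotes — is
#' `Other`.
#'
#' @param counts integer vector `(n_homo_major, n_het, n_homo_minor,
#'   n_missing)`.
#' @param call_rate_threshold minimum fraction of called samples.
#' @param otv external OTV flag.
#' @return one of [PERF_CLASSES].
#' @export
classify_snp <- function(counts, call_rate_threshold = 0.95, otv = FALSE) {
  stopifnot(length(counts) == 4L)
  if (any(counts < 0)) stop("negative genotype count")
  if (isTRUE(otv)) return("OTV")
  n <- sum(counts)
  if (n == 0L) return("Other")
  cr <- 1 - counts[4L] / n
  if (cr < call_rate_threshold) return("CallRateBelowThreshold")
  observed <- counts[1:3] > 0L
  if (sum(observed) == 1L && (observed[1L] || observed[3L]))
    return("MonoHighResolution")
  if (counts[3L] >= 1L) return("PolyHighResolution")
  if (counts[2L] >= 1L && counts[1L] >= 1L) return("NoMinorHom")
  "Other"
}

#' Per-marker performance table
#'
#' Computes, for every marker, the call rate, minor-allele frequency among
#' called samples, genotype class counts oriented by the major allele, and
#' the performance class of [classify_snp()].
#'
#' @param gm a [genotype_matrix()].
#' @param call_rate_threshold minimum call rate.
#' @param otv_flags optional character vector of marker ids externally
#'   flagged as off-target variants.
#' @return data.frame `marker_id, call_rate, maf, n_homo_major, n_het,
#'   n_homo_minor, n_missing, perf_class`.
#' @export
snp_performance <- function(gm, call_rate_threshold = 0.95,
                            otv_flags = NULL) {
  d <- gm$calls
  n_samp <- nrow(d)
  n0 <- colSums(d == 0L, na.rm = TRUE)
  n1 <- colSums(d == 1L, na.rm = TRUE)
  n2 <- colSums(d == 2L, na.rm = TRUE)
  nmiss <- colSums(is.na(d))
  called <- n0 + n1 + n2
  p_alt <- ifelse(called > 0, (n1 + 2 * n2) / (2 * called), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  alt_major <- !is.na(p_alt) & p_alt > 0.5
  n_homo_major <- ifelse(alt_major, n2, n0)
  n_homo_minor <- ifelse(alt_major, n0, n2)
  otv <- colnames(d) %in% (otv_flags %||% character(0))
  perf <- vapply(seq_len(ncol(d)), function(j)
    classify_snp(c(n_homo_major[j], n1[j], n_homo_minor[j], nmiss[j]),
                 call_rate_threshold, otv[j]), character(1))
  data.frame(marker_id = colnames(d),
             call_rate = 1 - nmiss / n_samp,
             maf = maf,
             n_homo_major = n_homo_major, n_het = n1,
             n_homo_minor = n_homo_minor, n_missing = nmiss,
             perf_class = perf,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percentage breakdown of performance-class counts
#'
#' Turns per-class marker counts into percentages of the array total;
#' markers on the array but absent from the counts (e.g. probes that failed
#' manufacturing) are accounted under `Other`.
#'
#' @param class_counts named integer vector over (a subset of)
#'   [PERF_CLASSES].
#' @param array_total total number of SNPs on the array.
#' @return data.frame `perf_class, count, pct` (pct = 100 * count / total),
#'   rows in [PERF_CLASSES] order.
#' @export
summarize_class_counts <- function(class_counts, array_total) {
  counts <- setNames(numeric(length(PERF_CLASSES)), PERF_CLASSES)
  counts[names(class_counts)] <- class_counts
  assayed <- sum(counts)
  if (array_total < assayed)
    stop("array_total (", array_total, ") below assayed marker count (",
         assayed, ")")
  counts["Other"] <- counts["Other"] + (array_total - assayed)
  data.frame(perf_class = PERF_CLASSES,
             count = as.numeric(counts),
             pct = 100 * as.numeric(counts) / array_total,
             stringsAsFactors = FALSE)
}

#' Array evaluation summary
#'
#' Class counts and percentages over the whole array plus the MAF spectrum
#' of markers passing the call-rate threshold.
#'
#' @param performances a [snp_performance()] table.
#' @param array_total total SNPs on the array (at least the assayed count;
#'   the difference is reported as `Other`, unassayed).
#' @param call_rate_threshold threshold defining the MAF-spectrum
#'   denominator.
#' @param maf_cutoffs strict lower MAF cutoffs to report.
#' @return list `classes` (data.frame `perf_class, count, pct`) and
#'   `maf_spectrum` (data.frame `cutoff, fraction`).
#' @export
eval_summary <- function(performances, array_total = nrow(performances),
                         call_rate_threshold = 0.95,
                         maf_cutoffs = c(0.10, 0.20)) {
  tab <- table(factor(performances$perf_class, levels = PERF_CLASSES))
  classes <- summarize_class_counts(as.vector(tab) |>
                                      setNames(PERF_CLASSES), array_total)
  passing <- performances[performances$call_rate >= call_rate_threshold, ]
  spectrum <- maf_spectrum(passing, maf_cutoffs)
  list(classes = classes, maf_spectrum = spectrum)
}

#' MAF spectrum of qualifying markers
#'
#' Fraction of markers whose minor-allele frequency strictly exceeds each
#' cutoff; the caller supplies the qualifying set (markers passing the
#' call-rate threshold).
#'
#' @param performances data.frame with a `maf` column.
#' @param cutoffs numeric cutoffs (strict `>`).
#' @return data.frame `cutoff, fraction`.
#' @export
maf_spectrum <- function(performances, cutoffs = c(0.10, 0.20)) {
  if (!length(cutoffs))
    return(data.frame(cutoff = numeric(0), fraction = numeric(0)))
  if (nrow(performances) == 0L)
    stop("no qualifying markers: empty MAF-spectrum denominator")
  data.frame(cutoff = cutoffs,
             fraction = vapply(cutoffs, function(cc)
               mean(performances$maf > cc, na.rm = TRUE), numeric(1)))
}
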