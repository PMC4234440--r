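#' Filtering thresholds for candidate reduction
#'
#' Bundles every tunable of the candidate-reduction cascade. Defaults are the
#' values used to design the 250K carp array: SNP quality >= 20 with >= 10
#' supporting reads and MAC >= 2 / MAF >= 5% at calling; 71-bp probe context
#' rejected when it contains an N, more than four consecutive G or C, or more
#' than six consecutive A or T; GC content kept between 30% and 70%; flanks must
#' map uniquely to the reference; SNPs within 10 bp of another variant, or in
#' any 35-bp window holding more than two variants, are dropped; probes need a
#' conversion score >= 0.58.
#'
#' @param min_snp_quality,min_depth,min_mac,min_maf primary call filters.
#' @param max_gc_run,max_at_run longest tolerated homopolymer of G/C and A/T.
#' @param gc_min,gc_max inclusive GC-content bounds for the 71-bp flank.
#' @param flank_half_width bases kept either side of the SNP (71-bp probe
#'   context = 2 * 35 + 1).
#' @param min_pair_distance pairwise proximity limit in bp (both members of a
#'   pair at or under this distance are removed).
#' @param cluster_window,cluster_max_variants window size (bp) and the largest
#'   variant count tolerated in any such window.
#' @param min_pconvert probe conversion-score threshold.
#' @param run_mode `"same_base"` counts homopolymers of one base (GGGGG);
#'   `"base_class"` counts runs drawn from the base class ({G,C} or {A,T}).
#' @param pair_rule `"le"` removes pairs with distance <= `min_pair_distance`;
#'   `"lt"` uses strict inequality.
#' @param pconvert_mode `"any"` qualifies a SNP when either probe direction
#'   passes; `"both"` requires both.
#' @return classed list `filter_thresholds`.
#' @export
filter_thresholds <- function(min_snp_quality = 20, min_depth = 10,
                              min_mac = 2, min_maf = 0.05,
                              max_gc_run = 4, max_at_run = 6,
                              gc_min = 0.30, gc_max = 0.70,
                              flank_half_width = 35,
                              min_pair_distance = 10,
                              cluster_window = 35, cluster_max_variants = 2,
                              min_pconvert = 0.58,
                              run_mode = c("same_base", "base_class"),
                              pair_rule = c("le", "lt"),
                              pconvert_mode = c("any", "both")) {
  th <- list(min_snp_quality = min_snp_quality, min_depth = min_depth,
             min_mac = min_mac, min_maf = min_maf,
             max_gc_run = max_gc_run, max_at_run = max_at_run,
             gc_min = gc_min, gc_max = gc_max,
             flank_half_width = flank_half_width,
             min_pair_distance = min_pair_distance,
             cluster_window = cluster_window,
             cluster_max_variants = cluster_max_variants,
             min_pconvert = min_pconvert,
             run_mode = match.arg(run_mode),
             pair_rule = match.arg(pair_rule),
             pconvert_mode = match.arg(pconvert_mode))
  num <- vapply(th[1:13], is.numeric, logical(1))
  if (!all(num) || any(unlist(th[1:13]) < 0))
    stop("all numeric thresholds must be non-negative")
  if (th$gc_min >= th$gc_max) stop("gc_min must be below gc_max")
  if (th$flank_half_width < 1) stop("flank_half_width must be >= 1")
  class(th) <- "filter_thresholds"
  th
}

stage_report <- function(stage, input, output) {
  data.frame(stage_name = stage, input_count = input, output_count = output,
             removed_count = input - output, stringsAsFactors = FALSE)
}

#' Primary call-statistics filter
#'
#' Keeps candidates with SNP quality, read depth, minor-allele count and
#' minor-allele frequency all at or above their thresholds. Input order is
#' preserved.
#'
#' @param records candidate SNP data.frame (see [snp_records()]).
#' @param thresholds a [filter_thresholds()].
#' @return list `records` (survivors) and `report` (one stage-report row with
#'   input/output/removed counts).
#' @export
filter_primary <- function(records, thresholds = filter_thresholds()) {
  req <- c("qual", "depth", "mac", "maf")
  for (f in req) {
    i <- which(is.na(records[[f]]))
    if (length(i))
      stop("record ", i[1L], " (", records$chrom[i[1L]], ":",
           records$pos[i[1L]], ") is missing field '", f, "'")
  }
  keep <- records$qual >= thresholds$min_snp_quality &
    records$depth >= thresholds$min_depth &
    records$mac >= thresholds$min_mac &
    records$maf >= thresholds$min_maf
  list(records = records[keep, , drop = FALSE],
       report = stage_report("primary", nrow(records), sum(keep)))
}

#' Extract the probe flanking sequence for one locus
#'
#' Returns the `2 * half_width + 1` bases of the reference centred on `pos`
#' (71 bp at the default half-width). Loci closer than `half_width` to a
#' sequence end cannot provide a full probe context and return `NA` with
#' attribute `edge = TRUE`; flank-quality stages treat these as removed.
#'
#' @param genome a [genome()].
#' @param chrom,pos locus (1-based).
#' @param ref when given, the reference base at `pos` is checked against it
#'   and a data-consistency error is raised on mismatch.
#' @param half_width bases either side of the SNP.
#' @return the flank string, or `NA` flagged `edge` for boundary loci.
#' @export
extract_flank <- function(genome, chrom, pos, ref = NULL, half_width = 35) {
  len <- genome$lengths[[chrom]]
  if (is.null(len)) stop("unknown sequence: ", chrom)
  if (pos < 1L || pos > len) stop("position ", pos, " outside ", chrom)
  if (pos - half_width < 1L || pos + half_width > len)
    return(structure(NA_character_, edge = TRUE))
  fl <- substr(genome$sequences[[chrom]], pos - half_width, pos + half_width)
  centre <- substr(fl, half_width + 1L, half_width + 1L)
  if (!is.null(ref) && centre != ref)
    stop("reference base at ", chrom, ":", pos, " is ", centre,
         " but record says ", ref)
  fl
}

#' Populate the flank column of a candidate table
#'
#' Vectorised [extract_flank()] over a candidate table; adds columns `flank`
#' (NA for edge loci) and `edge`.
#' @param records candidate SNP data.frame.
#' @param genome a [genome()].
#' @param half_width bases either side of the SNP.
#' @return `records` with `flank` and `edge` columns filled.
#' @export
extract_flanks <- function(records, genome, half_width = 35) {
  fl <- character(nrow(records))
  edge <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    f <- extract_flank(genome, records$chrom[i], records$pos[i],
                       ref = records$ref[i], half_width = half_width)
    edge[i] <- isTRUE(attr(f, "edge"))
    fl[i] <- as.character(f)
  }
  records$flank <- fl
  records$edge <- edge
  records
}

#' Homopolymer-run and N screen for probe flanks
#'
#' A flank fails when it contains any `N`, a run of identical G or C longer
#' than `max_gc_run`, or a run of identical A or T longer than `max_at_run`
#' (strict inequalities: a run of exactly four G passes at the default). The
#' reported reason is the rule whose violation starts left-most.
#'
#' @param flank character vector of 71-bp flanks (uppercase).
#' @param thresholds a [filter_thresholds()]; `run_mode = "base_class"`
#'   counts runs over the sets {G,C} / {A,T} instead of single bases.
#' @return data.frame with columns `pass` (logical) and `reason`
#'   (`"N"`, `"gc_run"`, `"at_run"`, or NA when passing).
#' @export
flank_run_filter <- function(flank, thresholds = filter_thresholds()) {
  one <- function(fl) {
    if (is.na(fl)) return(c("FALSE", "edge"))
    ch <- strsplit(fl, "")[[1]]
    firstN <- match("N", ch)
    key <- if (thresholds$run_mode == "same_base") ch else
      ifelse(ch %in% c("G", "C"), "S", ifelse(ch %in% c("A", "T"), "W", ch))
    r <- rle(key)
    starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
    is_gc <- r$values %in% c("G", "C", "S")
    is_at <- r$values %in% c("A", "T", "W")
    bad <- (is_gc & r$lengths > thresholds$max_gc_run) |
      (is_at & r$lengths > thresholds$max_at_run)
    cand_pos <- c(if (!is.na(firstN)) firstN, starts[bad])
    cand_why <- c(if (!is.na(firstN)) "N",
                  ifelse(is_gc[bad], "gc_run", "at_run"))
    if (!length(cand_pos)) return(c("TRUE", NA_character_))
    c("FALSE", cand_why[which.min(cand_pos)])
  }
  res <- t(vapply(flank, one, character(2), USE.NAMES = FALSE))
  data.frame(pass = as.logical(res[, 1]), reason = res[, 2],
             stringsAsFactors = FALSE)
}

#' GC content of a probe flank
#' @param flank character vector of flanking sequences.
#' @return numeric fraction of G+C bases.
#' @export
gc_content <- function(flank) {
  vapply(strsplit(flank, ""), function(ch) mean(ch %in% c("G", "C")),
         numeric(1))
}

#' GC-content screen for probe flanks
#'
#' Passes flanks whose GC fraction lies within the closed interval
#' `[gc_min, gc_max]` (defaults 30%-70%; the bounds themselves pass).
#' @inheritParams flank_run_filter
#' @return logical vector (`NA` flanks fail).
#' @export
gc_filter <- function(flank, thresholds = filter_thresholds()) {
  gc <- rep(NA_real_, length(flank))
  ok <- !is.na(flank)
  gc[ok] <- gc_content(flank[ok])
  !is.na(gc) & gc >= thresholds$gc_min & gc <= thresholds$gc_max
}

#' Build a both-strand exact-match index of the reference
#'
#' Prepares the genome for flank-uniqueness counting: occurrences of a k-mer
#' are counted on the forward sequences and their reverse complements.
#' @param genome a [genome()].
#' @param k probe length (71 for the default flank width).
#' @return classed list `uniqueness_index`.
#' @export
build_uniqueness_index <- function(genome, k = 71) {
  subj <- Biostrings::DNAStringSet(genome$sequences)
  structure(list(subject = subj, k = as.integer(k)),
            class = "uniqueness_index")
}

count_genome_hits <- function(flanks, index) {
  stopifnot(inherits(index, "uniqueness_index"))
  if (any(is.na(flanks))) stop("flank absent for ", sum(is.na(flanks)),
                               " record(s); extract flanks first")
  if (any(nchar(flanks) != index$k))
    stop("flank length differs from index k = ", index$k)
  counts <- integer(length(flanks))
  clean <- !grepl("[^ACGT]", flanks)
  if (any(clean)) {
    q <- Biostrings::DNAStringSet(flanks[clean])
    pd <- Biostrings::PDict(q)
    fwd <- rowSums(Biostrings::vcountPDict(pd, index$subject))
    rcq <- Biostrings::reverseComplement(q)
    rc <- rowSums(Biostrings::vcountPDict(Biostrings::PDict(rcq),
                                          index$subject))
    counts[clean] <- fwd + rc
  }
  for (i in which(!clean)) {   # N-containing flanks: literal matching
    q <- Biostrings::DNAString(flanks[i])
    counts[i] <- sum(Biostrings::vcountPattern(q, index$subject, fixed = TRUE)) +
      sum(Biostrings::vcountPattern(Biostrings::reverseComplement(q),
                                    index$subject, fixed = TRUE))
  }
  counts
}

#' Flank-uniqueness filter
#'
#' A candidate survives when its 71-bp flank (reference allele at the centre)
#' occurs exactly once in the genome counting both strands; the occurrence at
#' its own locus is that single hit. Repeated contexts cannot be probed
#' unambiguously.
#'
#' @param records candidate SNP data.frame with `flank` populated.
#' @param index a [build_uniqueness_index()].
#' @return list `records` (survivors) and `report` (stage-report row), plus
#'   attribute `hit_counts` on the report for diagnostics.
#' @export
uniqueness_filter <- function(records, index) {
  counts <- count_genome_hits(records$flank, index)
  keep <- counts == 1L
  rep_ <- stage_report("uniqueness", nrow(records), sum(keep))
  attr(rep_, "hit_counts") <- counts
  list(records = records[keep, , drop = FALSE], report = rep_)
}

# Which sorted positions violate the pair or window proximity rules.
# Returns a logical removal mask for positions `pos` (one chromosome, sorted).
proximity_mask_sorted <- function(pos, thresholds) {
  n <- length(pos)
  remove <- logical(n)
  if (n >= 2L) {
    gap <- diff(pos)
    near <- if (thresholds$pair_rule == "le")
      gap <= thresholds$min_pair_distance else
        gap < thresholds$min_pair_distance
    remove[c(near, FALSE)] <- remove[c(near, FALSE)] | TRUE
    remove[c(FALSE, near)] <- remove[c(FALSE, near)] | TRUE
  }
  k <- thresholds$cluster_max_variants + 1L   # smallest over-full window
  span <- thresholds$cluster_window - 1L      # inclusive span of the window
  if (n >= k) {
    # a variant is in some over-full window iff it belongs to a set of k
    # order-consecutive variants spanning <= span bases
    tight <- pos[k:n] - pos[1:(n - k + 1L)] <= span
    for (s in which(tight)) remove[s:(s + k - 1L)] <- TRUE
  }
  remove
}

#' Close-proximity filter
#'
#' Removes every variant that lies within `min_pair_distance` bases of
#' another variant on the same chromosome (both members of such a pair go),
#' and every variant inside any `cluster_window`-base window that contains
#' more than `cluster_max_variants` variants. Window occupancy is counted
#' over the full set passed in, so a variant already doomed by the pair rule
#' still crowds its neighbours.
#'
#' @param records candidate SNP data.frame; sorted by (chrom, pos) internally
#'   when needed (noted in the report attribute `resorted`).
#' @param thresholds a [filter_thresholds()].
#' @return list `records` (survivors, original order among survivors) and
#'   `report`.
#' @export
proximity_filter <- function(records, thresholds = filter_thresholds()) {
  n <- nrow(records)
  ord <- order(records$chrom, records$pos)
  resorted <- !identical(ord, seq_len(n))
  remove <- logical(n)
  for (chrom in unique(records$chrom)) {
    idx <- ord[records$chrom[ord] == chrom]
    remove[idx] <- proximity_mask_sorted(records$pos[idx], thresholds)
  }
  rep_ <- stage_report("proximity", n, sum(!remove))
  attr(rep_, "resorted") <- resorted
  list(records = records[!remove, , drop = FALSE], report = rep_)
}

#' Marker identifiers for candidate SNPs
#'
#' Canonical `chrom:pos` marker ids used to join candidates with probe
#' scores and genotype matrices.
#' @param records candidate SNP data.frame.
#' @return character vector.
#' @export
marker_ids <- function(records) paste(records$chrom, records$pos, sep = ":")

#' Probe conversion-score filter
#'
#' Retains candidates whose predicted probe conversion score reaches
#' `min_pconvert` (default 0.58, boundary inclusive) in the better of the
#' forward and reverse probe directions (`pconvert_mode = "any"`), or in both
#' (`"both"`).
#'
#' @param records candidate SNP data.frame.
#' @param scores data.frame with `marker_id` (or `chrom` + `pos`),
#'   `pconvert_forward`, `pconvert_reverse`, values in `[0, 1]`.
#' @param thresholds a [filter_thresholds()].
#' @return list `records` and `report`.
#' @export
pconvert_filter <- function(records, scores,
                            thresholds = filter_thresholds()) {
  if (is.null(scores$marker_id))
    scores$marker_id <- paste(scores$chrom, scores$pos, sep = ":")
  if (any(scores$pconvert_forward < 0 | scores$pconvert_forward > 1 |
            scores$pconvert_reverse < 0 | scores$pconvert_reverse > 1,
          na.rm = TRUE))
    stop("conversion scores must lie in [0, 1]")
  idx <- match(marker_ids(records), scores$marker_id)
  if (anyNA(idx))
    stop("no conversion score for marker ",
         marker_ids(records)[which(is.na(idx))[1L]])
  fw <- scores$pconvert_forward[idx]
  rv <- scores$pconvert_reverse[idx]
  keep <- if (thresholds$pconvert_mode == "any")
    pmax(fw, rv) >= thresholds$min_pconvert else
      pmin(fw, rv) >= thresholds$min_pconvert
  list(records = records[keep, , drop = FALSE],
       report = stage_report("pconvert", nrow(records), sum(keep)))
}

#' Run the full candidate-reduction cascade
#'
#' Applies, in order: primary call filters, flank extraction, the
#' homopolymer/N screen (edge loci count as removed here), the GC screen,
#' flank uniqueness, close proximity, and — when probe scores are supplied —
#' the conversion-score threshold. Stage order mirrors the design pipeline's
#' accounting columns.
#'
#' @param records candidate SNP data.frame.
#' @param genome a [genome()].
#' @param thresholds a [filter_thresholds()].
#' @param scores optional probe-score table for [pconvert_filter()].
#' @param run_primary apply the primary call filters first (set `FALSE` when
#'   the input was already screened at calling time).
#' @return list `records` (final survivors) and `report` (stage-report
#'   data.frame, one row per applied stage; counts conserve
#'   `input = output + removed` row-wise and chain stage to stage).
#' @export
run_filter_cascade <- function(records, genome,
                               thresholds = filter_thresholds(),
                               scores = NULL, run_primary = TRUE) {
  reports <- list()
  cur <- records
  if (run_primary) {
    st <- filter_primary(cur, thresholds)
    cur <- st$records; reports <- c(reports, list(st$report))
  }
  cur <- extract_flanks(cur, genome,
                        half_width = thresholds$flank_half_width)
  rr <- flank_run_filter(cur$flank, thresholds)
  keep <- rr$pass & !cur$edge
  reports <- c(reports, list(stage_report("runs", nrow(cur), sum(keep))))
  cur <- cur[keep, , drop = FALSE]

  keep <- gc_filter(cur$flank, thresholds)
  reports <- c(reports, list(stage_report("gc", nrow(cur), sum(keep))))
  cur <- cur[keep, , drop = FALSE]

  idx <- build_uniqueness_index(genome,
                                k = 2L * thresholds$flank_half_width + 1L)
  st <- uniqueness_filter(cur, idx)
  cur <- st$records; reports <- c(reports, list(st$report))

  st <- proximity_filter(cur, thresholds)
  cur <- st$records; reports <- c(reports, list(st$report))

  if (!is.null(scores)) {
    st <- pconvert_filter(cur, scores, thresholds)
    cur <- st$records; reports <- c(reports, list(st$report))
  }
  list(records = cur, report = do.call(rbind, reports))
}
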