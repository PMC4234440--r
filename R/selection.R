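#' Per-category selection rule
#'
#' One row of a selection plan: a SNP category, its priority (1 is selected
#' first), the minimum spacing `t` in bases that a SNP of this category must
#' keep from every SNP already on the array, and an optional quota capping
#' how many may be taken.
#'
#' @param category one of [SNP_CATEGORIES].
#' @param priority integer rank, unique within a plan.
#' @param t minimum spacing in bases (>= 0).
#' @param quota optional maximum count for this category.
#' @return classed list `category_spec`.
#' @export
category_spec <- function(category, priority, t, quota = NULL) {
  stopifnot(category %in% SNP_CATEGORIES, t >= 0, priority >= 1)
  structure(list(category = category, priority = as.integer(priority),
                 t = as.numeric(t),
                 quota = if (is.null(quota)) Inf else as.numeric(quota)),
            class = "category_spec")
}

#' Selection plan
#'
#' An ordered set of [category_spec()]s (priorities must be unique; specs are
#' sorted by priority) plus an optional overall array-size cap.
#'
#' The default plan reproduces the category order and spacings used for the
#' 250K carp array: coding SNPs first (non-synonymous, then UTR) at 100-bp
#' spacing, other transcript SNPs at 1.8 kb, strain-shared re-sequencing SNPs
#' at 10 kb, and strain-specific SNPs at 17 kb from anything already chosen.
#'
#' @param specs list of [category_spec()]; default as described above.
#' @param target_total optional overall cap on the selected count.
#' @return classed list `selection_plan`.
#' @export
selection_plan <- function(specs = NULL, target_total = NULL) {
  if (is.null(specs))
    specs <- list(
      category_spec("nonsyn",           1, 100),
      category_spec("utr3",             2, 100),
      category_spec("utr5",             3, 100),
      category_spec("transcript_other", 4, 1800),
      category_spec("strain_shared",    5, 10000),
      category_spec("strain_specific",  6, 17000))
  pri <- vapply(specs, `[[`, integer(1), "priority")
  if (anyDuplicated(pri)) stop("priorities must be unique")
  specs <- specs[order(pri)]
  structure(list(specs = specs,
                 target_total = if (is.null(target_total)) Inf
                 else as.numeric(target_total)),
            class = "selection_plan")
}

#' Category-prioritised greedy spacing selection
#'
#' Builds the final array content from filtered candidates. Categories are
#' processed in priority order; within a category candidates are visited in
#' descending SNP quality with ties broken by chromosome then ascending
#' position (`strategy = "quality_first"`, the default) or in a plain
#' positional sweep (`"position_sweep"`). A candidate is accepted only if,
#' for every SNP already selected on the same chromosome, their distance is
#' at least the larger of the two categories' spacing thresholds — so the
#' finished array satisfies every member's own spacing requirement. A
#' category stops at its quota; selection stops at `target_total`.
#'
#' @param candidates candidate SNP data.frame with `chrom`, `pos`,
#'   `category`, `qual` populated.
#' @param plan a [selection_plan()] covering all candidate categories.
#' @param strategy within-category visiting order (see above).
#' @return the selected subset of `candidates` (row order = acceptance
#'   order), with attribute `category_counts` (named integer vector).
#' @export
greedy_select <- function(candidates, plan = selection_plan(),
                          strategy = c("quality_first", "position_sweep")) {
  strategy <- match.arg(strategy)
  cats <- vapply(plan$specs, `[[`, character(1), "category")
  tvals <- vapply(plan$specs, `[[`, numeric(1), "t")
  quotas <- vapply(plan$specs, `[[`, numeric(1), "quota")
  unknown <- setdiff(unique(candidates$category), cats)
  if (length(unknown))
    stop("candidate category not covered by plan: ", unknown[1L])

  # per chromosome, per category: sorted position vectors of selected SNPs
  sel_pos <- list()
  chrom_levels <- sort(unique(candidates$chrom))
  n_selected <- 0L
  counts <- setNames(integer(length(cats)), cats)
  take <- logical(nrow(candidates))
  order_in <- integer(nrow(candidates))

  conflicts <- function(chrom, pos, t_cand) {
    byc <- sel_pos[[chrom]]
    if (is.null(byc)) return(FALSE)
    for (k in seq_along(byc)) {
      v <- byc[[k]]
      if (!length(v)) next
      j <- findInterval(pos, v)
      d <- min(if (j >= 1L) pos - v[j] else Inf,
               if (j < length(v)) v[j + 1L] - pos else Inf)
      if (d < max(t_cand, tvals[k])) return(TRUE)
    }
    FALSE
  }

  for (k in seq_along(cats)) {
    rows <- which(candidates$category == cats[k])
    if (!length(rows)) next
    ord <- if (strategy == "quality_first")
      rows[order(-candidates$qual[rows],
                 match(candidates$chrom[rows], chrom_levels),
                 candidates$pos[rows])]
    else
      rows[order(match(candidates$chrom[rows], chrom_levels),
                 candidates$pos[rows])]
    for (i in ord) {
      if (counts[k] >= quotas[k]) break
      if (n_selected >= plan$target_total) break
      chrom <- candidates$chrom[i]; pos <- candidates$pos[i]
      if (conflicts(chrom, pos, tvals[k])) next
      if (is.null(sel_pos[[chrom]]))
        sel_pos[[chrom]] <- rep(list(numeric(0)), length(cats))
      v <- sel_pos[[chrom]][[k]]
      j <- findInterval(pos, v)
      sel_pos[[chrom]][[k]] <- append(v, pos, after = j)
      take[i] <- TRUE
      n_selected <- n_selected + 1L
      counts[k] <- counts[k] + 1L
      order_in[i] <- n_selected
    }
    if (n_selected >= plan$target_total) break
  }
  out <- candidates[take, , drop = FALSE]
  out <- out[order(order_in[take]), , drop = FALSE]
  attr(out, "category_counts") <- counts
  out
}

#' Adjacent intervals between selected SNPs
#'
#' Distances between consecutive selected positions within each chromosome
#' (chromosome boundaries contribute no interval). The mean is the total
#' intervening distance divided by the number of intervals and is `NA` when
#' no chromosome carries two SNPs.
#'
#' @param selected data.frame with `chrom`, `pos` (e.g. [greedy_select()]
#'   output).
#' @param bin_width histogram bin width in bases.
#' @return list with `intervals` (data.frame `chrom`, `interval`),
#'   `mean_interval`, and `histogram` (data.frame `bin_upper_bp`, `n`).
#' @export
interval_histogram <- function(selected, bin_width = 1000) {
  stopifnot(nrow(selected) > 0)
  iv <- do.call(rbind, lapply(split(selected$pos, selected$chrom),
                              function(p) {
    p <- sort(p)
    if (length(p) < 2L) return(NULL)
    data.frame(interval = diff(p))
  }))
  if (is.null(iv) || nrow(iv) == 0L)
    return(list(intervals = data.frame(chrom = character(0),
                                       interval = numeric(0)),
                mean_interval = NA_real_,
                histogram = data.frame(bin_upper_bp = numeric(0),
                                       n = integer(0))))
  chroms <- rep(names(split(selected$pos, selected$chrom)),
                vapply(split(selected$pos, selected$chrom),
                       function(p) max(0L, length(p) - 1L), integer(1)))
  intervals <- data.frame(chrom = chroms, interval = iv$interval,
                          stringsAsFactors = FALSE)
  bins <- ceiling(intervals$interval / bin_width)
  tab <- table(factor(bins, levels = seq_len(max(bins))))
  list(intervals = intervals,
       mean_interval = mean(intervals$interval),
       histogram = data.frame(bin_upper_bp = as.numeric(names(tab)) * bin_width,
                              n = as.integer(tab)))
}

#' Marker density per chromosome and per genomic bin
#'
#' Density in sites per megabase for each assembled chromosome; unplaced
#' scaffolds are concatenated (in genome order, cumulative offsets) into a
#' pseudo-chromosome `"P"` so scaffold markers are reported together.
#'
#' @param selected data.frame with `chrom`, `pos`.
#' @param genome a [genome()] distinguishing placed from unplaced sequences.
#' @param bin bin width in bases for per-bin counts.
#' @param pseudo_chrom collapse unplaced scaffolds into `"P"`.
#' @return list with `density` (data.frame `chrom, n_snps, length_bp,
#'   density_per_mb`) and `bins` (data.frame `chrom, bin_start, n`).
#' @export
density_report <- function(selected, genome, bin = 1e6, pseudo_chrom = TRUE) {
  if (any(genome$lengths == 0L)) stop("zero-length sequence in genome")
  chroms <- genome$placed_names
  pos <- selected$pos
  chr <- selected$chrom
  lens <- as.numeric(genome$lengths[chroms])
  names(lens) <- chroms
  if (pseudo_chrom && length(genome$unplaced_names)) {
    off <- cumsum(c(0, as.numeric(genome$lengths[genome$unplaced_names])))
    names(off) <- c(genome$unplaced_names, ".end")
    on_scaf <- chr %in% genome$unplaced_names
    pos[on_scaf] <- pos[on_scaf] + off[chr[on_scaf]]
    chr[on_scaf] <- "P"
    lens <- c(lens, P = off[[".end"]])
    chroms <- c(chroms, "P")
  }
  n <- vapply(chroms, function(cc) sum(chr == cc), integer(1))
  density <- data.frame(chrom = chroms, n_snps = n,
                        length_bp = as.numeric(lens),
                        density_per_mb = n / (as.numeric(lens) / 1e6),
                        row.names = NULL, stringsAsFactors = FALSE)
  bins <- do.call(rbind, lapply(chroms, function(cc) {
    nb <- ceiling(lens[[cc]] / bin)
    b <- findInterval(pos[chr == cc] - 1, seq(0, by = bin,
                                              length.out = nb + 1L),
                      rightmost.closed = FALSE)
    cnt <- tabulate(b, nbins = nb)
    data.frame(chrom = cc, bin_start = seq(0, by = bin, length.out = nb) + 1,
               n = cnt, stringsAsFactors = FALSE)
  }))
  list(density = density, bins = bins)
}

#' Design-stage accounting summary
#'
#' Tabulates, per SNP category, the number of surviving candidates at each
#' design stage and the per-stage grand totals, validating that every
#' category row is monotone non-increasing across stages (candidates are
#' only ever removed).
#'
#' @param counts data.frame or matrix: rows = categories (rownames or a
#'   `category` column), columns = stages in pipeline order.
#' @return classed list `design_summary` with `counts` (matrix) and `totals`
#'   (named numeric, one per stage).
#' @export
design_summary <- function(counts) {
  if (is.data.frame(counts)) {
    if (!is.null(counts$category)) {
      rn <- counts$category
      counts <- as.matrix(counts[, setdiff(names(counts), "category")])
      rownames(counts) <- rn
    } else counts <- as.matrix(counts)
  }
  if (any(counts < 0)) stop("negative stage count")
  bad <- apply(counts, 1L, function(r) any(diff(r) > 0))
  if (any(bad)) {
    r <- which(bad)[1L]
    s <- which(diff(counts[r, ]) > 0)[1L] + 1L
    stop("category '", rownames(counts)[r],
         "' increases at stage '", colnames(counts)[s], "'")
  }
  structure(list(counts = counts, totals = colSums(counts)),
            class = "design_summary")
}

#' @export
print.design_summary <- function(x, ...) {
  m <- rbind(x$counts, Total = x$totals)
  print(format(m, big.mark = ","), quote = FALSE)
  invisible(x)
}
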