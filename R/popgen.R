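#' Pairwise linkage disequilibrium (r-squared) within chromosomes
#'
#' For every same-chromosome marker pair separated by at most `max_distance`
#' bases, with both minor-allele frequencies strictly above `min_maf`,
#' computes r-squared as the squared Pearson correlation of dosage vectors
#' over jointly called samples (the genotype-based r2 of standard genotyping
#' toolkits; no phasing). Pairs with fewer than two informative samples or a
#' zero-variance marker are skipped and counted.
#'
#' @param gm a [genotype_matrix()] with `marker_map` populated.
#' @param max_distance largest physical distance (bp) considered.
#' @param min_maf strict minor-allele-frequency cutoff.
#' @return data.frame `marker_a, marker_b, chrom, distance, r2`, with
#'   attribute `n_skipped` (pairs dropped for lack of information).
#' @export
pairwise_r2 <- function(gm, max_distance = 1e5, min_maf = 0.05) {
  if (is.null(gm$marker_map)) stop("genotype_matrix has no marker_map")
  d <- gm$calls
  called <- colSums(!is.na(d))
  p_alt <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  use <- which(!is.na(maf) & maf > min_maf & called >= 2L)
  map <- gm$marker_map
  out <- list(); n_skipped <- 0L
  for (chrom in unique(map$chrom)) {
    j <- use[map$chrom[use] == chrom]
    if (length(j) < 2L) next
    j <- j[order(map$pos[j])]
    pos <- map$pos[j]
    hi <- findInterval(pos + max_distance, pos)
    for (a in seq_len(length(j) - 1L)) {
      if (hi[a] <= a) next
      for (b in (a + 1L):hi[a]) {
        dist <- pos[b] - pos[a]
        if (dist <= 0L) { n_skipped <- n_skipped + 1L; next }
        x <- d[, j[a]]; y <- d[, j[b]]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 2L ||
              stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
          n_skipped <- n_skipped + 1L; next
        }
        r <- stats::cor(x[ok], y[ok])
        out[[length(out) + 1L]] <-
          data.frame(marker_a = colnames(d)[j[a]],
                     marker_b = colnames(d)[j[b]],
                     chrom = chrom, distance = dist, r2 = r * r,
                     stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(marker_a = character(0), marker_b = character(0),
               chrom = character(0), distance = numeric(0), r2 = numeric(0))
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Distance-binned LD decay profile
#'
#' Averages r-squared in physical-distance bins: bin `b` covers
#' `((b-1) * bin_width, b * bin_width]` and is labelled by its upper edge.
#' All bins up to the furthest occupied one are reported; empty bins carry
#' count 0 and `NA` mean. The profile conserves mass:
#' `sum(mean_r2 * n_pairs)` equals the sum of r-squared over all pairs.
#'
#' @param pairs output of [pairwise_r2()].
#' @param bin_width bin width in bases.
#' @return data.frame `bin_upper_bp, bin_kb, mean_r2, n_pairs`.
#' @export
bin_decay <- function(pairs, bin_width = 1000) {
  if (bin_width <= 0) stop("bin width must be positive")
  if (nrow(pairs) == 0L) stop("no LD pairs to bin")
  b <- ceiling(pairs$distance / bin_width)
  levels <- seq_len(max(b))
  n <- tabulate(b, nbins = max(b))
  means <- vapply(levels, function(k)
    if (n[k]) mean(pairs$r2[b == k]) else NA_real_, numeric(1))
  data.frame(bin_upper_bp = levels * bin_width,
             bin_kb = levels * bin_width / 1000,
             mean_r2 = means, n_pairs = n)
}

#' Identity-by-state similarity matrix
#'
#' Allele-sharing similarity between every pair of samples:
#' `mean(2 - |d_i - d_j|) / 2` over markers where both calls are present
#' (1 for identical genotypes throughout, 0 for opposite homozygotes
#' throughout).
#'
#' @param gm a [genotype_matrix()] with at least two samples.
#' @return classed list `ibs_matrix` with `similarity` (symmetric matrix,
#'   unit diagonal) and `n_shared_markers` (matrix of jointly called
#'   counts).
#' @export
ibs_matrix <- function(gm) {
  d <- gm$calls
  n <- nrow(d)
  if (n < 2L) stop("need at least two samples")
  sim <- matrix(1, n, n, dimnames = list(rownames(d), rownames(d)))
  shared <- matrix(ncol(d), n, n, dimnames = dimnames(sim))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(d[i, ]) & !is.na(d[j, ])
      ns <- sum(ok)
      if (ns == 0L)
        stop("samples ", rownames(d)[i], " and ", rownames(d)[j],
             " share no called marker")
      s <- mean(2 - abs(d[i, ok] - d[j, ok])) / 2
      sim[i, j] <- sim[j, i] <- s
      shared[i, j] <- shared[j, i] <- ns
    }
  }
  diag(shared) <- rowSums(!is.na(d))
  structure(list(similarity = sim, n_shared_markers = shared,
                 sample_ids = rownames(d)),
            class = "ibs_matrix")
}

#' Classical MDS embedding of an IBS matrix
#'
#' Embeds samples by Torgerson multidimensional scaling of the distance
#' matrix `1 - similarity` (square, double-centre, eigendecompose, scale by
#' the square root of the eigenvalues). Coordinates are defined up to sign;
#' for reproducibility the first nonzero loading of every axis is forced
#' positive. Compare embeddings through inter-point distances, not raw
#' coordinates.
#'
#' @param ibs an [ibs_matrix()].
#' @param dims number of dimensions (must not exceed the number of positive
#'   eigenvalues).
#' @return list `points` (samples x dims coordinate matrix) and `eig`
#'   (eigenvalues, descending).
#' @export
mds_ibs <- function(ibs, dims = 2) {
  dist <- 1 - ibs$similarity
  fit <- stats::cmdscale(dist, k = min(nrow(dist) - 1L, max(dims, 2L)),
                         eig = TRUE)
  n_pos <- sum(fit$eig > sqrt(.Machine$double.eps))
  if (dims > n_pos)
    stop("requested ", dims, " dimensions but only ", n_pos,
         " positive eigenvalues")
  pts <- fit$points[, seq_len(dims), drop = FALSE]
  for (k in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, k]) > sqrt(.Machine$double.eps))
    if (length(nz) && pts[nz[1L], k] < 0) pts[, k] <- -pts[, k]
  }
  rownames(pts) <- ibs$sample_ids
  colnames(pts) <- paste0("C", seq_len(dims))
  list(points = pts, eig = fit$eig)
}

#' Mean silhouette width of a labelled embedding
#'
#' Convenience wrapper used to quantify cluster separation of an MDS
#' embedding against known population labels.
#' @param points coordinate matrix (samples x dims).
#' @param labels group labels, one per sample.
#' @return mean silhouette width (requires the `cluster` package).
#' @export
silhouette_score <- function(points, labels) {
  if (!requireNamespace("cluster", quietly = TRUE))
    stop("silhouette_score needs the 'cluster' package")
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             stats::dist(points))
  mean(sil[, "sil_width"])
}
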