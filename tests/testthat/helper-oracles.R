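# Independent brute-force oracles. These deliberately re-derive each rule in
# the most literal way possible (character scans, O(n^2) sweeps, explicit
# gamete enumeration) and share no code with the implementation.

# character-by-character homopolymer/N scan: TRUE = flank acceptable
oracle_run_scan <- function(flank, max_gc_run = 4, max_at_run = 6) {
  ch <- strsplit(flank, "")[[1]]
  if (any(ch == "N")) return(FALSE)
  run <- 1L
  for (i in seq_along(ch)) {
    run <- if (i > 1L && ch[i] == ch[i - 1L]) run + 1L else 1L
    lim <- if (ch[i] %in% c("G", "C")) max_gc_run else max_at_run
    if (run > lim) return(FALSE)
  }
  TRUE
}

# literal proximity rule: pairwise scan plus every variant-anchored window
oracle_proximity_removed <- function(pos, pair_dist = 10, window = 35,
                                     max_in_window = 2) {
  n <- length(pos)
  rm_ <- logical(n)
  for (i in seq_len(n)) {
    d <- abs(pos - pos[i]); d[i] <- Inf
    if (any(d <= pair_dist)) rm_[i] <- TRUE
  }
  for (i in seq_len(n)) {
    inw <- which(pos >= pos[i] & pos <= pos[i] + window - 1L)
    if (length(inw) > max_in_window) rm_[inw] <- TRUE
  }
  rm_
}

# spacing checker: every selected pair on a chromosome at distance >= the
# larger of the two categories' thresholds
oracle_spacing_ok <- function(sel, tmap) {
  for (cc in unique(sel$chrom)) {
    s <- sel[sel$chrom == cc, , drop = FALSE]
    if (nrow(s) < 2L) next
    D <- abs(outer(s$pos, s$pos, "-")); diag(D) <- Inf
    req <- outer(tmap[s$category], tmap[s$category], pmax)
    if (any(D < req)) return(FALSE)
  }
  TRUE
}

# greedy-maximality: no rejected candidate could be added without violating
# a spacing constraint (valid only for quota-free, uncapped plans)
oracle_greedy_maximal <- function(cand, sel, tmap) {
  key <- paste(cand$chrom, cand$pos)
  rejected <- cand[!key %in% paste(sel$chrom, sel$pos), , drop = FALSE]
  for (i in seq_len(nrow(rejected))) {
    s <- sel[sel$chrom == rejected$chrom[i], , drop = FALSE]
    if (nrow(s) == 0L) return(FALSE)
    d <- abs(s$pos - rejected$pos[i])
    req <- pmax(tmap[[rejected$category[i]]], tmap[s$category])
    if (all(d >= req)) return(FALSE)
  }
  TRUE
}

# explicit gamete enumeration for a trio
oracle_trio_consistent <- function(f, m, c) {
  gam <- list("0" = 0L, "1" = c(0L, 1L), "2" = 1L)
  c %in% outer(gam[[as.character(f)]], gam[[as.character(m)]], "+")
}

# performance classification re-derived from the written rules
oracle_classify <- function(cnt, thr) {
  n <- sum(cnt)
  if (n == 0) return("Other")
  if (1 - cnt[4] / n < thr) return("CallRateBelowThreshold")
  present <- cnt[1:3] > 0
  if (sum(present) == 0) return("Other")
  if (sum(present) == 1 && present[2]) return("Other")
  if (sum(present) == 1) return("MonoHighResolution")
  if (cnt[3] >= 1) return("PolyHighResolution")
  if (cnt[1] >= 1 && cnt[2] >= 1) return("NoMinorHom")
  "Other"
}

# squared correlation written out from sums of squares
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy^2 / (sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# allele-sharing similarity via explicit shared-allele counting
oracle_ibs <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  shared <- pmin(a[ok], b[ok]) + pmin(2 - a[ok], 2 - b[ok])
  mean(shared) / 2
}

# Torgerson MDS written out: square, double-centre, eigendecompose
oracle_mds_points <- function(D, k) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen(B, symmetric = TRUE)
  e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
}

random_flank <- function(allow_n = FALSE) {
  alpha <- c("A", "C", "G", "T", if (allow_n) "N")
  prob <- if (allow_n) c(0.24, 0.24, 0.24, 0.24, 0.04) else rep(0.25, 4)
  paste(sample(alpha, 71, replace = TRUE, prob = prob), collapse = "")
}
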