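make_gm <- function(d, pos = NULL, chrom = "chr1") {
  colnames(d) <- paste0("m", seq_len(ncol(d)))
  if (is.null(pos)) pos <- seq_len(ncol(d)) * 1000L
  map <- data.frame(marker_id = colnames(d),
                    chrom = rep_len(chrom, ncol(d)), pos = pos)
  genotype_matrix(d, marker_map = map)
}

test_that("r2 endpoints: identical columns give 1, orthogonal give 0", {
  d <- cbind(c(0, 0, 2, 2), c(0, 0, 2, 2), c(0, 2, 0, 2))
  pr <- pairwise_r2(make_gm(d), max_distance = 1e5, min_maf = 0)
  r12 <- pr$r2[pr$marker_a == "m1" & pr$marker_b == "m2"]
  r13 <- pr$r2[pr$marker_a == "m1" & pr$marker_b == "m3"]
  expect_equal(r12, 1)
  expect_equal(r13, 0)
})

test_that("r2 matches the direct correlation oracle with missing data", {
  set.seed(55)
  d <- matrix(sample(c(0:2, NA), 50 * 20, TRUE, prob = c(.3, .3, .3, .1)),
              50, 20)
  gm <- make_gm(d, pos = sort(sample.int(19000L, 20)))
  pr <- pairwise_r2(gm, max_distance = 1e5, min_maf = 0)
  expect_gt(nrow(pr), 0)
  for (i in seq_len(nrow(pr))) {
    a <- match(pr$marker_a[i], colnames(gm$calls))
    b <- match(pr$marker_b[i], colnames(gm$calls))
    expect_equal(pr$r2[i], oracle_r2(d[, a], d[, b]), tolerance = 1e-12)
  }
})

test_that("r2 respects distance, MAF limits and dosage orientation", {
  set.seed(56)
  d <- matrix(sample(0:2, 30 * 10, TRUE), 30, 10)
  gm <- make_gm(d)  # positions 1..10 kb
  pr <- pairwise_r2(gm, max_distance = 3000, min_maf = 0)
  expect_true(all(pr$distance <= 3000 & pr$distance > 0))
  # flipping a marker's ref/alt orientation leaves r2 unchanged
  d2 <- d; d2[, 4] <- 2L - d2[, 4]
  pr2 <- pairwise_r2(make_gm(d2), max_distance = 3000, min_maf = 0)
  expect_equal(pr$r2, pr2$r2, tolerance = 1e-12)
  # a high MAF cutoff excludes near-monomorphic markers
  d3 <- d; d3[, 1] <- c(1L, rep(0L, 29))
  pr3 <- pairwise_r2(make_gm(d3), max_distance = 1e5, min_maf = 0.05)
  expect_false("m1" %in% c(pr3$marker_a, pr3$marker_b))
})

test_that("binned decay averages, labels and conserves mass", {
  pairs <- data.frame(distance = c(500, 900, 1500), r2 = c(0.4, 0.6, 0.2))
  bd <- bin_decay(pairs)
  expect_equal(bd$mean_r2[1], 0.5)
  expect_equal(bd$n_pairs, c(2L, 1L))
  expect_equal(bd$mean_r2[2], 0.2)          # singleton keeps its own r2
  expect_equal(sum(bd$mean_r2 * bd$n_pairs, na.rm = TRUE), sum(pairs$r2))
  # empty intermediate bins appear with zero counts
  bd2 <- bin_decay(data.frame(distance = c(500, 4500), r2 = c(0.5, 0.1)))
  expect_identical(bd2$n_pairs, c(1L, 0L, 0L, 0L, 1L))
  expect_true(all(is.na(bd2$mean_r2[2:4])))
  expect_error(bin_decay(pairs, 0), "positive")
})

test_that("synthetic haplotype chains show monotone decay and recover rho", {
  sim <- gen_genotypes(gen_markers(150, 1, 1000), n_populations = 1,
                       n_per_pop = 200, divergence = 0, ld_rho = 0.8,
                       missing_rate = 0, error_rate = 0, fixed_freq = 0.5,
                       seed = 11)
  pr <- pairwise_r2(sim$gm, max_distance = 10000)
  bd <- bin_decay(pr)
  expect_true(all(diff(bd$mean_r2) < 0.01))
  fit <- stats::lm(log(mean_r2) ~ bin_kb, data = bd[bd$bin_kb <= 8, ])
  rho_hat <- exp(unname(coef(fit)[2]) / 2)
  expect_lt(abs(rho_hat - 0.8) / 0.8, 0.2)
})

test_that("IBS similarity matches brute-force allele sharing", {
  dup <- rbind(c(0, 1, 2, 1), c(0, 1, 2, 1))
  ib <- ibs_matrix(genotype_matrix(dup))
  expect_equal(ib$similarity[1, 2], 1)
  opp <- rbind(c(0L, 0L, 2L), c(2L, 2L, 0L))
  expect_equal(ibs_matrix(genotype_matrix(opp))$similarity[1, 2], 0)

  set.seed(77)
  d <- matrix(sample(c(0:2, NA), 8 * 30, TRUE, prob = c(.3, .3, .3, .1)),
              8, 30)
  ib2 <- ibs_matrix(genotype_matrix(d))
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(ib2$similarity[i, j], oracle_ibs(d[i, ], d[j, ]))
  expect_identical(ib2$similarity, t(ib2$similarity))
  expect_true(all(diag(ib2$similarity) == 1))

  nosh <- rbind(c(0L, NA), c(NA, 1L))
  expect_error(ibs_matrix(genotype_matrix(nosh)), "share no called marker")
})

test_that("MDS reproduces exact embeddings and the Torgerson oracle", {
  # three collinear points with distances 1, 1, 2 embed exactly
  sim <- 1 - rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0)) / 2
  ib <- structure(list(similarity = sim, sample_ids = c("a", "b", "c")),
                  class = "ibs_matrix")
  md <- mds_ibs(ib, dims = 1)
  dd <- as.matrix(dist(md$points))
  expect_equal(sort(dd[upper.tri(dd)]), c(0.5, 0.5, 1), tolerance = 1e-9)

  set.seed(31)
  d <- matrix(sample(0:2, 12 * 40, TRUE), 12, 40)
  ib2 <- ibs_matrix(genotype_matrix(d))
  md2 <- mds_ibs(ib2, dims = 2)
  want <- oracle_mds_points(1 - ib2$similarity, 2)
  expect_equal(as.matrix(dist(md2$points)), as.matrix(dist(want)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # determinism: embedding distances identical across runs
  md3 <- mds_ibs(ib2, dims = 2)
  expect_identical(md2$points, md3$points)
  expect_error(mds_ibs(ib2, dims = 40), "positive eigenvalues")

  # identical samples land on identical coordinates
  d2 <- rbind(d[1, ], d)
  mdd <- mds_ibs(ibs_matrix(genotype_matrix(d2)), dims = 2)
  expect_equal(unname(mdd$points[1, ]), unname(mdd$points[2, ]),
               tolerance = 1e-9)
})

test_that("strong three-population structure separates in MDS", {
  sim <- gen_genotypes(gen_markers(400, 4, 5000), n_populations = 3,
                       n_per_pop = 30, divergence = 0.3,
                       missing_rate = 0.02, error_rate = 0, seed = 13)
  md <- mds_ibs(ibs_matrix(sim$gm), dims = 2)
  sil <- silhouette_score(md$points, sim$gm$sample_meta$population)
  expect_gt(sil, 0.5)
  sim0 <- gen_genotypes(gen_markers(400, 4, 5000), n_populations = 3,
                        n_per_pop = 30, divergence = 0,
                        missing_rate = 0.02, error_rate = 0, seed = 13)
  sil0 <- silhouette_score(mds_ibs(ibs_matrix(sim0$gm), dims = 2)$points,
                           sim0$gm$sample_meta$population)
  expect_lt(abs(sil0), 0.2)
})
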