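#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with desk-scale
#' defaults that echo the study design the package targets: a multi-
#' chromosome genome with unassembled scaffolds, a candidate pool carrying
#' all six SNP categories with optional planted filter violations, and
#' genotypes structured into populations (strains) plus a two-parent family
#' with 80 offspring.
#'
#' @param seed integer seed; every generator is deterministic under it.
#' @param genome list: `n_chroms`, `chrom_length`, `n_scaffolds`,
#'   `scaffold_length`, `gc_fraction`.
#' @param variants list: `density_per_kb`, `category_props` (named over
#'   [SNP_CATEGORIES]), `frac_run_violation`, `frac_gc_violation`,
#'   `frac_dup_flank`, `frac_proximity`.
#' @param genotypes list: `n_populations`, `n_per_pop`, `divergence`,
#'   `families` (list of `list(population=, n_offspring=)`), `ld_rho`
#'   (per-kb haplotype correlation decay), `missing_rate`, `error_rate`,
#'   `error_mode` (`"symmetric"` or `"mendel_visible"`).
#' @return classed list `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome = list(), variants = list(),
                       genotypes = list()) {
  g <- utils::modifyList(list(n_chroms = 5L, chrom_length = 200000L,
                              n_scaffolds = 2L, scaffold_length = 50000L,
                              gc_fraction = 0.37), genome)
  v <- utils::modifyList(list(
    density_per_kb = 1,
    category_props = c(nonsyn = 0.05, utr3 = 0.05, utr5 = 0.03,
                       transcript_other = 0.27, strain_shared = 0.35,
                       strain_specific = 0.25),
    frac_run_violation = 0, frac_gc_violation = 0,
    frac_dup_flank = 0, frac_proximity = 0), variants)
  gt <- utils::modifyList(list(
    n_populations = 3L, n_per_pop = 30L, divergence = 0.1,
    families = list(list(population = 1L, n_offspring = 80L)),
    ld_rho = 0, missing_rate = 0.02, error_rate = 0.004,
    error_mode = "symmetric"), genotypes)
  stopifnot(g$n_chroms >= 0, g$chrom_length > 0,
            g$gc_fraction > 0, g$gc_fraction < 1,
            all(v$category_props >= 0), sum(v$category_props) > 0,
            v$frac_run_violation >= 0, v$frac_gc_violation >= 0,
            v$frac_dup_flank >= 0, v$frac_proximity >= 0,
            v$frac_run_violation + v$frac_gc_violation +
              v$frac_dup_flank + v$frac_proximity <= 1,
            gt$ld_rho >= 0, gt$ld_rho < 1,
            gt$missing_rate >= 0, gt$missing_rate < 1,
            gt$error_rate >= 0, gt$error_rate < 1,
            gt$error_mode %in% c("symmetric", "mendel_visible"))
  structure(list(seed = as.integer(seed), genome = g, variants = v,
                 genotypes = gt), class = "sim_config")
}

random_dna <- function(n, gc_fraction) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc_fraction) / 2, gc_fraction / 2,
                        gc_fraction / 2, (1 - gc_fraction) / 2)),
        collapse = "")
}

#' Generate a random reference genome
#'
#' Independent-base random sequences at the requested GC fraction:
#' `n_chroms` assembled chromosomes (`chr1..`) and `n_scaffolds` unplaced
#' scaffolds (`scaffold1..`). Deterministic under `seed`.
#'
#' @param n_chroms,chrom_length,n_scaffolds,scaffold_length sizes.
#' @param gc_fraction target GC content.
#' @param seed optional integer seed.
#' @return a [genome()].
#' @export
gen_genome <- function(n_chroms = 5L, chrom_length = 200000L,
                       n_scaffolds = 0L, scaffold_length = 50000L,
                       gc_fraction = 0.37, seed = NULL) {
  if (n_chroms < 1L) stop("need at least one chromosome")
  if (chrom_length < 1L || (n_scaffolds > 0L && scaffold_length < 1L))
    stop("zero-length sequence requested")
  if (!is.null(seed)) set.seed(seed)
  seqs <- c(
    setNames(vapply(seq_len(n_chroms),
                    function(i) random_dna(chrom_length, gc_fraction),
                    character(1)),
             paste0("chr", seq_len(n_chroms))),
    if (n_scaffolds > 0L)
      setNames(vapply(seq_len(n_scaffolds),
                      function(i) random_dna(scaffold_length, gc_fraction),
                      character(1)),
               paste0("scaffold", seq_len(n_scaffolds))))
  genome(seqs)
}

str_sub_replace <- function(s, start, replacement) {
  paste0(substr(s, 1L, start - 1L), replacement,
         substr(s, start + nchar(replacement), nchar(s)))
}

# AT-rich 71-mer that passes the homopolymer screen but fails the GC screen
low_gc_flank <- function(thresholds) {
  repeat {
    fl <- paste(sample(c("A", "C", "G", "T"), 71, replace = TRUE,
                       prob = c(0.44, 0.06, 0.06, 0.44)), collapse = "")
    if (flank_run_filter(fl, thresholds)$pass &&
          gc_content(fl) < thresholds$gc_min - 0.02) return(fl)
  }
}

#' Plant candidate SNPs (and deliberate filter violations) on a genome
#'
#' Places well-separated candidate SNPs across all sequences and, for the
#' requested fractions, plants violations the reduction cascade must catch:
#' homopolymer runs injected next to the SNP (`runs` stage), AT-rich probe
#' contexts (`gc` stage), duplicated flank blocks copied elsewhere in the
#' genome with a twin SNP at the copy (`uniqueness` stage), and close
#' pairs/triples (`proximity` stage). Clean candidates are verified at
#' planting time to pass the homopolymer, GC, uniqueness and proximity
#' rules, so the returned truth table alone predicts the fate of every
#' record. Because violations are written into the sequence, the (modified)
#' genome is returned alongside the records.
#'
#' @param genome a [genome()] (from [gen_genome()]).
#' @param n_variants number of candidate records to produce (alternatively
#'   give `density_per_kb`).
#' @param density_per_kb used when `n_variants` is `NULL`.
#' @param category_props named sampling proportions over [SNP_CATEGORIES].
#' @param frac_run_violation,frac_gc_violation,frac_dup_flank,frac_proximity
#'   fractions of records planted as violations of each stage.
#' @param thresholds [filter_thresholds()] used for planting-time checks.
#' @param seed optional integer seed.
#' @return list `genome` (modified), `records` (candidate SNP data.frame,
#'   sorted by chrom then pos), `truth` (data.frame `chrom, pos, role,
#'   expected_stage` aligned with `records`).
#' @export
plant_variants <- function(genome, n_variants = NULL, density_per_kb = 1,
                           category_props = c(nonsyn = 0.05, utr3 = 0.05,
                                              utr5 = 0.03,
                                              transcript_other = 0.27,
                                              strain_shared = 0.35,
                                              strain_specific = 0.25),
                           frac_run_violation = 0, frac_gc_violation = 0,
                           frac_dup_flank = 0, frac_proximity = 0,
                           thresholds = filter_thresholds(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  total_len <- sum(as.numeric(genome$lengths))
  n <- if (is.null(n_variants)) round(density_per_kb * total_len / 1000)
  else n_variants
  if (n < 1L) stop("no variants requested")

  # candidate slots: >= 100 bp apart, >= 40 bp from sequence ends (flanks
  # and proximity companions must fit inside the sequence)
  slots <- do.call(rbind, lapply(names(genome$sequences), function(cc) {
    len <- genome$lengths[[cc]]
    if (len < 180L) return(NULL)
    starts <- seq(50L, len - 90L, by = 120L)
    if (!length(starts)) return(NULL)
    data.frame(chrom = cc,
               pos = starts + sample(-10:10, length(starts), replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  n_dup_pairs <- floor(frac_dup_flank * n / 2)
  n_prox_target <- round(frac_proximity * n)
  n_run <- round(frac_run_violation * n)
  n_gc <- round(frac_gc_violation * n)
  # proximity groups: pairs, with one triple when the target count is odd
  prox_sizes <- integer(0); left <- n_prox_target
  while (left >= 2L) {
    sz <- if (left == 3L) 3L else 2L
    prox_sizes <- c(prox_sizes, sz); left <- left - sz
  }
  n_clean <- n - n_run - n_gc - 2L * n_dup_pairs - sum(prox_sizes)
  if (n_clean < 0L) stop("violation fractions exceed the variant budget")
  n_slots_needed <- n_run + n_gc + 2L * n_dup_pairs + length(prox_sizes) +
    n_clean
  if (n_slots_needed > 0.9 * nrow(slots))
    stop("variant density too high for the clean-set spacing constraints")
  slots <- slots[sample.int(nrow(slots)), , drop = FALSE]
  slot_i <- 0L
  next_slot <- function() {
    slot_i <<- slot_i + 1L
    if (slot_i > nrow(slots))
      stop("ran out of well-spaced candidate positions")
    slots[slot_i, ]
  }
  seqs <- genome$sequences
  flank_at <- function(chrom, pos)
    substr(seqs[[chrom]], pos - 35L, pos + 35L)
  clean_context <- function(s) {
    fr <- flank_run_filter(s, thresholds)
    fr$pass && gc_filter(s, thresholds)
  }
  take_clean_slot <- function() {
    repeat {
      sl <- next_slot()
      if (clean_context(flank_at(sl$chrom, sl$pos))) return(sl)
    }
  }

  rows <- list()
  add_row <- function(chrom, pos, role, stage)
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, role = role, expected_stage = stage,
      stringsAsFactors = FALSE)

  for (i in seq_len(n_run)) {
    sl <- next_slot()
    base <- sample(c("G", "C", "A", "T"), 1L)
    run_len <- if (base %in% c("G", "C")) thresholds$max_gc_run + 1L
    else thresholds$max_at_run + 1L
    seqs[[sl$chrom]] <- str_sub_replace(seqs[[sl$chrom]], sl$pos + 5L,
                                        strrep(base, run_len))
    add_row(sl$chrom, sl$pos, "run_violation", "runs")
  }
  for (i in seq_len(n_gc)) {
    sl <- next_slot()
    seqs[[sl$chrom]] <- str_sub_replace(seqs[[sl$chrom]], sl$pos - 35L,
                                        low_gc_flank(thresholds))
    add_row(sl$chrom, sl$pos, "gc_violation", "gc")
  }
  for (i in seq_len(n_dup_pairs)) {
    src <- take_clean_slot()
    dst <- take_clean_slot()
    block <- substr(seqs[[src$chrom]], src$pos - 50L, src$pos + 50L)
    seqs[[dst$chrom]] <- str_sub_replace(seqs[[dst$chrom]], dst$pos - 50L,
                                         block)
    add_row(src$chrom, src$pos, "dup_flank", "uniqueness")
    add_row(dst$chrom, dst$pos, "dup_flank", "uniqueness")
  }
  for (sz in prox_sizes) {
    repeat {
      sl <- next_slot()
      offs <- if (sz == 2L) c(0L, sample(3:thresholds$min_pair_distance, 1L))
      else c(0L, 15L, 30L)
      ctx_ok <- all(vapply(offs, function(o)
        clean_context(flank_at(sl$chrom, sl$pos + o)), logical(1)))
      if (ctx_ok) {
        for (o in offs) add_row(sl$chrom, sl$pos + o, "proximity_cluster",
                                "proximity")
        break
      }
    }
  }
  for (i in seq_len(n_clean)) {
    sl <- take_clean_slot()
    add_row(sl$chrom, sl$pos, "clean", "none")
  }

  truth <- do.call(rbind, rows)
  ord <- order(match(truth$chrom, names(seqs)), truth$pos)
  truth <- truth[ord, , drop = FALSE]
  genome_mod <- genome
  genome_mod$sequences <- seqs

  m <- nrow(truth)
  ref <- substr(rep(NA_character_, m), 1, 1)
  for (i in seq_len(m))
    ref[i] <- substr(seqs[[truth$chrom[i]]], truth$pos[i], truth$pos[i])
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r),
                                        1L), character(1), USE.NAMES = FALSE)
  maf <- round(stats::runif(m, 0.05, 0.5), 3)
  records <- snp_records(
    chrom = truth$chrom, pos = truth$pos, ref = ref, alt = alt,
    qual = round(stats::runif(m, 25, 60), 1),
    depth = 10L + stats::rpois(m, 15),
    mac = pmax(2L, as.integer(round(maf * 36))),
    maf = maf,
    category = sample(names(category_props), m, replace = TRUE,
                      prob = category_props),
    genome = genome_mod)
  rownames(records) <- rownames(truth) <- NULL

  # verify clean / proximity / duplicate contexts against the real index so
  # the truth table is authoritative even for unlucky random genomes
  idx <- build_uniqueness_index(genome_mod,
                                k = 2L * thresholds$flank_half_width + 1L)
  need_unique <- truth$expected_stage %in% c("none", "proximity")
  if (any(need_unique)) {
    fl <- vapply(which(need_unique), function(i)
      flank_at(records$chrom[i], records$pos[i]), character(1))
    hits <- count_genome_hits(fl, idx)
    if (any(hits != 1L)) {
      drop <- which(need_unique)[hits != 1L]
      warning("dropped ", length(drop),
              " planted variant(s) with repeated flank context")
      records <- records[-drop, , drop = FALSE]
      truth <- truth[-drop, , drop = FALSE]
    }
  }
  list(genome = genome_mod, records = records, truth = truth)
}

#' Evenly spaced synthetic marker map
#'
#' Lightweight marker scaffold for genotype simulations that do not need a
#' sequence-level genome: `n` markers spread over `n_chroms` chromosomes at
#' `spacing` bp (with optional jitter).
#' @param n total markers.
#' @param n_chroms chromosomes.
#' @param spacing inter-marker distance in bp.
#' @param jitter maximum absolute positional jitter in bp.
#' @return data.frame `marker_id, chrom, pos`.
#' @export
gen_markers <- function(n, n_chroms = 1L, spacing = 1000L, jitter = 0L) {
  per <- ceiling(n / n_chroms)
  df <- do.call(rbind, lapply(seq_len(n_chroms), function(cc) {
    k <- min(per, n - (cc - 1L) * per)
    if (k <= 0L) return(NULL)
    pos <- seq_len(k) * spacing
    if (jitter > 0L) pos <- pos + sample(seq(-jitter, jitter), k,
                                         replace = TRUE)
    data.frame(chrom = paste0("chr", cc), pos = as.integer(pos),
               stringsAsFactors = FALSE)
  }))
  df$marker_id <- paste(df$chrom, df$pos, sep = ":")
  df[, c("marker_id", "chrom", "pos")]
}

# one haplotype: shared-uniform copy chain along each chromosome.
# State u is kept with probability rho^(distance in kb), else redrawn; the
# allele is 1[u < p]. Marginal frequency is exactly p at every marker and,
# for equal frequencies, corr(allele_i, allele_j) = rho^distance_kb.
sim_haplotype <- function(p, chrom, pos, rho) {
  m <- length(p)
  if (rho <= 0) return(as.integer(stats::runif(m) < p))
  u <- stats::runif(m)         # fresh draws
  keep <- stats::runif(m)
  if (m >= 2L) for (k in 2L:m) {
    if (chrom[k] == chrom[k - 1L]) {
      c_k <- rho^((pos[k] - pos[k - 1L]) / 1000)
      if (keep[k] < c_k) u[k] <- u[k - 1L]
    }
  }
  as.integer(u < p)
}

#' Generate structured genotype matrices with known truth
#'
#' Simulates populations diverged from a common ancestral allele-frequency
#' spectrum (Balding-Nichols Beta perturbation with variance set by
#' `divergence`), optional within-chromosome LD with per-kb haplotype
#' correlation `ld_rho`, families (two new parents per family drawn from
#' their population, offspring by per-marker gamete sampling), then planted
#' genotyping errors and missingness. Deterministic under `seed`.
#'
#' With `error_mode = "symmetric"` every call can be perturbed one dosage
#' step (0 and 2 to 1; 1 to 0 or 2); with `"mendel_visible"` errors hit only
#' offspring and are forced to be inconsistent with the (true) parental
#' genotypes, which makes planted error rates directly recoverable from
#' Mendelian checks (markers where both parents are heterozygous admit no
#' inconsistent child and are avoided).
#'
#' @param markers data.frame `chrom, pos` (and optionally `marker_id`), e.g.
#'   from [gen_markers()] or a selected candidate table.
#' @param n_populations,n_per_pop population structure.
#' @param divergence Balding-Nichols F between 0 (none) and 1.
#' @param families list of `list(population =, n_offspring =)`.
#' @param ld_rho per-kb haplotype correlation decay in `[0, 1)`.
#' @param missing_rate,error_rate per-call rates.
#' @param error_mode `"symmetric"` or `"mendel_visible"` (see above).
#' @param fixed_freq when given, all ancestral (and population) frequencies
#'   are fixed to this value — used for calibration runs where analytic
#'   decay is wanted.
#' @param seed optional integer seed.
#' @return list `gm` (a [genotype_matrix()]) and `truth`:
#'   `ancestral_freq`, `pop_freq` (markers x populations), `true_calls`
#'   (dosage matrix before errors/missingness), `errors` (data.frame
#'   `sample_id, marker_id, true, observed`).
#' @export
gen_genotypes <- function(markers, n_populations = 3L, n_per_pop = 30L,
                          divergence = 0.1,
                          families = list(), ld_rho = 0,
                          missing_rate = 0.02, error_rate = 0.004,
                          error_mode = c("symmetric", "mendel_visible"),
                          fixed_freq = NULL, seed = NULL) {
  error_mode <- match.arg(error_mode)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(markers$marker_id))
    markers$marker_id <- paste(markers$chrom, markers$pos, sep = ":")
  ord <- order(match(markers$chrom, unique(markers$chrom)), markers$pos)
  markers <- markers[ord, , drop = FALSE]
  m <- nrow(markers)
  if (m == 0L) stop("empty marker set")

  p0 <- if (!is.null(fixed_freq)) rep(fixed_freq, m) else
    pmin(pmax(stats::rbeta(m, 2, 2), 0.05), 0.95)
  F <- divergence
  n_freq_sets <- max(n_populations, 1L,
                     vapply(families, function(f) f$population %||% 1L,
                            numeric(1)))
  pop_freq <- vapply(seq_len(n_freq_sets), function(k) {
    if (F <= 0 || !is.null(fixed_freq)) p0 else
      pmin(pmax(stats::rbeta(m, p0 * (1 - F) / F,
                             (1 - p0) * (1 - F) / F), 0.01), 0.99)
  }, numeric(m))

  haps <- list()   # sample_id -> list(h1, h2) for gamete sampling
  ids <- character(0); pop_lab <- character(0)
  fam_id <- father_id <- mother_id <- character(0)
  calls <- NULL
  add_sample <- function(id, pop, h1, h2, fam = NA, fa = NA, mo = NA) {
    haps[[id]] <<- list(h1 = h1, h2 = h2)
    ids <<- c(ids, id); pop_lab <<- c(pop_lab, pop)
    fam_id <<- c(fam_id, fam)
    father_id <<- c(father_id, fa); mother_id <<- c(mother_id, mo)
    calls <<- rbind(calls, h1 + h2)
  }
  for (k in seq_len(n_populations)) {
    pk <- pop_freq[, k]
    for (s in seq_len(n_per_pop))
      add_sample(sprintf("pop%d_s%02d", k, s), paste0("pop", k),
                 sim_haplotype(pk, markers$chrom, markers$pos, ld_rho),
                 sim_haplotype(pk, markers$chrom, markers$pos, ld_rho))
  }
  for (f in seq_along(families)) {
    fam <- families[[f]]
    k <- fam$population %||% 1L
    pk <- pop_freq[, k]
    fa <- sprintf("fam%d_father", f); mo <- sprintf("fam%d_mother", f)
    add_sample(fa, paste0("pop", k),
               sim_haplotype(pk, markers$chrom, markers$pos, ld_rho),
               sim_haplotype(pk, markers$chrom, markers$pos, ld_rho),
               fam = paste0("fam", f))
    add_sample(mo, paste0("pop", k),
               sim_haplotype(pk, markers$chrom, markers$pos, ld_rho),
               sim_haplotype(pk, markers$chrom, markers$pos, ld_rho),
               fam = paste0("fam", f))
    for (o in seq_len(fam$n_offspring)) {
      g_fa <- ifelse(stats::runif(m) < 0.5, haps[[fa]]$h1, haps[[fa]]$h2)
      g_mo <- ifelse(stats::runif(m) < 0.5, haps[[mo]]$h1, haps[[mo]]$h2)
      add_sample(sprintf("fam%d_o%03d", f, o), paste0("pop", k),
                 g_fa, g_mo, fam = paste0("fam", f), fa = fa, mo = mo)
    }
  }
  rownames(calls) <- ids
  colnames(calls) <- markers$marker_id
  true_calls <- calls

  errors <- data.frame(sample_id = character(0), marker_id = character(0),
                       true = integer(0), observed = integer(0),
                       stringsAsFactors = FALSE)
  perturb <- function(d) ifelse(d == 1L, sample(c(0L, 2L), length(d),
                                                replace = TRUE), 1L)
  if (error_rate > 0) {
    if (error_mode == "symmetric") {
      hit <- which(matrix(stats::runif(length(calls)) < error_rate,
                          nrow(calls)))
      if (length(hit)) {
        old <- calls[hit]
        calls[hit] <- perturb(old)
        errors <- data.frame(
          sample_id = ids[(hit - 1L) %% nrow(calls) + 1L],
          marker_id = markers$marker_id[(hit - 1L) %/% nrow(calls) + 1L],
          true = old, observed = calls[hit], stringsAsFactors = FALSE)
      }
    } else {
      for (i in which(!is.na(father_id))) {
        fa <- true_calls[father_id[i], ]; mo <- true_calls[mother_id[i], ]
        eligible <- which(!(fa == 1L & mo == 1L))
        n_err <- stats::rbinom(1L, m, error_rate)
        pick <- sample(eligible, min(n_err, length(eligible)))
        for (j in pick) {
          allowed <- child_dosage_set(fa[j], mo[j])
          bad <- setdiff(0:2, allowed)
          old <- calls[i, j]
          calls[i, j] <- bad[sample.int(length(bad), 1L)]
          errors <- rbind(errors, data.frame(
            sample_id = ids[i], marker_id = markers$marker_id[j],
            true = old, observed = calls[i, j], stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (missing_rate > 0)
    calls[matrix(stats::runif(length(calls)) < missing_rate,
                 nrow(calls))] <- NA_integer_

  meta <- data.frame(sample_id = ids, population = pop_lab,
                     family_id = fam_id, father_id = father_id,
                     mother_id = mother_id, stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, meta,
                        marker_map = markers[, c("marker_id", "chrom",
                                                 "pos")])
  list(gm = gm,
       truth = list(ancestral_freq = p0, pop_freq = pop_freq,
                    true_calls = true_calls, errors = errors))
}

#' Possible offspring dosages for a parental pair
#'
#' Enumerates the alternate-allele dosages an offspring can inherit from
#' parents with the given dosages (one allele from each).
#' @param father,mother dosages in `{0, 1, 2}`.
#' @return sorted integer vector of feasible child dosages.
#' @export
child_dosage_set <- function(father, mother) {
  gf <- switch(as.character(father), "0" = 0L, "1" = c(0L, 1L), "2" = 1L)
  gm <- switch(as.character(mother), "0" = 0L, "1" = c(0L, 1L), "2" = 1L)
  sort(unique(as.vector(outer(gf, gm, `+`))))
}
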