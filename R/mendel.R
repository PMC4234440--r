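#' Mendelian consistency of a parent-offspring trio
#'
#' A child genotype is consistent when it can be assembled from one allele
#' of each parent: a homozygote requires both parents to carry that allele,
#' and a heterozygote is impossible only when both parents are the same
#' homozygote. Vectorised over markers.
#'
#' @param father,mother,child alternate-allele dosages in `{0, 1, 2}`
#'   (callers exclude missing calls).
#' @return logical vector, `TRUE` where consistent.
#' @export
trio_consistent <- function(father, mother, child) {
  (child == 0L & father <= 1L & mother <= 1L) |
    (child == 2L & father >= 1L & mother >= 1L) |
    (child == 1L & !(father == 0L & mother == 0L) &
       !(father == 2L & mother == 2L))
}

#' Genotyping accuracy from family trios
#'
#' Counts Mendelian inconsistencies between two declared parents and each
#' offspring across all markers where all three calls are present, and
#' reports per-offspring error rates and an overall accuracy
#' `1 - sum(errors) / sum(tested)`. Errors are attributed once per
#' (marker, offspring) pair; parental calls are never blamed. Offspring with
#' no testable marker are dropped from the summary with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @param father_id,mother_id sample ids of the parents; defaults taken from
#'   the pedigree columns of `gm$sample_meta` when a single family is
#'   declared.
#' @param offspring_ids sample ids of the offspring; default: all samples
#'   whose pedigree names both parents.
#' @return list `trios` (data.frame `offspring_id, n_tested, n_errors,
#'   error_rate`) and `accuracy` (overall, in `[0, 1]`).
#' @export
family_accuracy <- function(gm, father_id = NULL, mother_id = NULL,
                            offspring_ids = NULL) {
  meta <- gm$sample_meta
  if (is.null(father_id)) {
    fam <- meta[!is.na(meta$father_id), ]
    if (nrow(fam) == 0L) stop("no pedigree information in sample_meta")
    father_id <- unique(fam$father_id)[1L]
    mother_id <- unique(fam$mother_id)[1L]
  }
  if (!father_id %in% rownames(gm$calls))
    stop("father '", father_id, "' absent from genotype matrix")
  if (!mother_id %in% rownames(gm$calls))
    stop("mother '", mother_id, "' absent from genotype matrix")
  if (is.null(offspring_ids))
    offspring_ids <- meta$sample_id[!is.na(meta$father_id) &
                                      meta$father_id == father_id &
                                      !is.na(meta$mother_id) &
                                      meta$mother_id == mother_id]
  if (!length(offspring_ids)) stop("no offspring found for declared parents")
  f <- gm$calls[father_id, ]
  m <- gm$calls[mother_id, ]
  res <- lapply(offspring_ids, function(oid) {
    o <- gm$calls[oid, ]
    ok <- !is.na(f) & !is.na(m) & !is.na(o)
    n_tested <- sum(ok)
    n_err <- if (n_tested) sum(!trio_consistent(f[ok], m[ok], o[ok])) else 0L
    data.frame(offspring_id = oid, n_tested = n_tested, n_errors = n_err,
               error_rate = if (n_tested) n_err / n_tested else NA_real_,
               stringsAsFactors = FALSE)
  })
  trios <- do.call(rbind, res)
  if (any(trios$n_tested == 0L))
    warning(sum(trios$n_tested == 0L),
            " offspring with no testable marker excluded from the summary")
  used <- trios[trios$n_tested > 0L, ]
  list(trios = trios,
       accuracy = 1 - sum(used$n_errors) / sum(used$n_tested))
}

#' Exclude pedigree-discordant offspring and recompute accuracy
#'
#' Drops offspring whose Mendelian error rate exceeds `max_error_rate`
#' (e.g. sample swaps or mislabelled pedigree entries) and recomputes the
#' overall accuracy on the remainder; the recomputed accuracy can only
#' improve.
#'
#' @param results output of [family_accuracy()] (or its `trios` table).
#' @param max_error_rate per-offspring exclusion threshold.
#' @return list `trios` (retained offspring), `excluded` (ids), and
#'   `accuracy` (recomputed).
#' @export
exclude_discordant <- function(results, max_error_rate) {
  trios <- if (is.data.frame(results)) results else results$trios
  if (nrow(trios) == 0L) stop("empty trio results")
  bad <- !is.na(trios$error_rate) & trios$error_rate > max_error_rate
  keep <- trios[!bad, , drop = FALSE]
  used <- keep[keep$n_tested > 0L, , drop = FALSE]
  if (nrow(used) == 0L) stop("all offspring excluded at this threshold")
  list(trios = keep, excluded = trios$offspring_id[bad],
       accuracy = 1 - sum(used$n_errors) / sum(used$n_tested))
}
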