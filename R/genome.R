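#' Genome container
#'
#' A `genome` is a light container for a reference assembly held in memory:
#' a named character vector of uppercase DNA sequences plus a split of the
#' sequence names into assembled chromosomes ("placed") and unassembled
#' scaffolds ("unplaced"). All coordinates used elsewhere in the package are
#' 1-based inclusive against these sequences.
#'
#' @param sequences named character vector of DNA sequences (A/C/G/T/N).
#' @param unplaced_pattern regular expression; sequence names matching it are
#'   classified as unplaced scaffolds. Ignored when `unplaced_names` is given.
#' @param unplaced_names explicit character vector of unplaced sequence names.
#' @return An object of class `genome` with elements `sequences`, `lengths`,
#'   `placed_names`, `unplaced_names`.
#' @examples
#' g <- genome(c(chr1 = "ACGTACGT", scaffold1 = "TTTT"))
#' g$lengths
#' @export
genome <- function(sequences, unplaced_pattern = "^(scaffold|contig|un)",
                   unplaced_names = NULL) {
  if (length(sequences) == 0L) {
    out <- list(sequences = character(0), lengths = integer(0),
                placed_names = character(0), unplaced_names = character(0))
    class(out) <- "genome"
    return(out)
  }
  nm <- names(sequences)
  if (is.null(nm) || any(is.na(nm)) || any(nm == ""))
    stop("all sequences must be named")
  if (anyDuplicated(nm))
    stop("duplicate sequence name: ", nm[duplicated(nm)][1L])
  sequences <- toupper(sequences)
  bad <- vapply(sequences, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad))
    stop("non-ACGTN character in sequence '", nm[bad][1L], "'")
  if (is.null(unplaced_names))
    unplaced_names <- nm[grepl(unplaced_pattern, nm, ignore.case = TRUE)]
  out <- list(
    sequences      = sequences,
    lengths        = vapply(sequences, nchar, integer(1)),
    placed_names   = setdiff(nm, unplaced_names),
    unplaced_names = intersect(nm, unplaced_names)
  )
  class(out) <- "genome"
  out
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x$sequences), "sequences,",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp",
      sprintf("(%d placed, %d unplaced)\n",
              length(x$placed_names), length(x$unplaced_names)))
  invisible(x)
}

#' @export
length.genome <- function(x) length(x$sequences)
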