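# HSP statistics recomputed from the aligned strings themselves, plus the
# five-class colour binning used by the hit-distribution graphic and the
# query-coverage summary.  Recomputation against the parsed header counts is
# the guard that no error is introduced between file and visualisation.

#' Recompute HSP statistics from the aligned strings
#'
#' Counts identities (columns where query and subject carry the same non-gap
#' symbol, case-insensitively), gaps (total `-` columns over both strings)
#' and positives (midline columns holding a non-blank mark; not defined for
#' blastn) directly from the alignment, and compares them with the counts the
#' file declared.  A disagreement signals a corrupt file or a parser bug.
#'
#' @param hsp A [new_hsp()] object.
#' @param check If `TRUE` (default), raise an error of condition class
#'   `inconsistent_hsp` when recomputed counts differ from the stored ones;
#'   if `FALSE`, just return the recomputed statistics.
#' @return A list of class `alignment_stats` with integer counts
#'   `identities`, `positives` (`NA` for blastn), `gap_count`, `align_len`
#'   and integer percentages `pct_identity`, `pct_positives`, `pct_gaps`
#'   (rounded to the nearest integer, halves away from zero).
#' @export
#' @examples
#' hsp <- new_hsp("blastp", 30, 1e-4, 7, 5, 5, 1, 1, 6, 1, 7,
#'                "ACDE-FG", "ACDYEFG", "ACD  FG")
#' recompute_hsp_stats(hsp)
recompute_hsp_stats <- function(hsp, check = TRUE) {
  stopifnot(inherits(hsp, "blast_hsp"))
  L <- nchar(hsp$qseq)
  if (nchar(hsp$hseq) != L || nchar(hsp$midline) != L) {
    abort_inconsistent_hsp("qseq/hseq/midline lengths differ")
  }
  qc <- strsplit(toupper(hsp$qseq), "", fixed = TRUE)[[1]]
  hc <- strsplit(toupper(hsp$hseq), "", fixed = TRUE)[[1]]
  mc <- strsplit(hsp$midline, "", fixed = TRUE)[[1]]

  identities <- sum(qc == hc & qc != "-")
  gap_count <- sum(qc == "-") + sum(hc == "-")
  positives <- if (hsp$program == "blastn") NA_integer_ else sum(mc != " ")

  stats <- structure(
    list(
      identities = as.integer(identities),
      positives = as.integer(positives),
      gap_count = as.integer(gap_count),
      align_len = as.integer(L),
      pct_identity = pct_of(identities, L),
      pct_positives = if (is.na(positives)) NA_integer_ else pct_of(positives, L),
      pct_gaps = pct_of(gap_count, L)
    ),
    class = "alignment_stats"
  )

  if (check) {
    mismatches <- character()
    if (stats$identities != hsp$identities) {
      mismatches <- c(mismatches, sprintf(
        "identities: stored %d, recomputed %d", hsp$identities, stats$identities
      ))
    }
    if (stats$gap_count != hsp$gap_count) {
      mismatches <- c(mismatches, sprintf(
        "gaps: stored %d, recomputed %d", hsp$gap_count, stats$gap_count
      ))
    }
    if (!is.na(stats$positives) && !is.na(hsp$positives) &&
        stats$positives != hsp$positives) {
      mismatches <- c(mismatches, sprintf(
        "positives: stored %d, recomputed %d", hsp$positives, stats$positives
      ))
    }
    if (stats$align_len != hsp$align_len) {
      mismatches <- c(mismatches, sprintf(
        "align_len: stored %d, recomputed %d", hsp$align_len, stats$align_len
      ))
    }
    if (length(mismatches)) {
      abort_inconsistent_hsp(paste(mismatches, collapse = "; "))
    }
  }
  stats
}

# Default bin edges: the NCBI graphic-overview convention for bit scores and
# a five-decade E-value analogue.  Both are configurable wherever used.
DEFAULT_BITS_EDGES <- c(40, 50, 80, 200)
DEFAULT_EVALUE_EDGES <- c(1, 1e-5, 1e-10, 1e-50)

bin_labels <- function(mode, edges) {
  e <- format(edges, scientific = (mode == "evalue"), trim = TRUE)
  if (mode == "bits") {
    c(paste0("<", e[1]), paste0(e[1], "-", e[2]), paste0(e[2], "-", e[3]),
      paste0(e[3], "-", e[4]), paste0(">=", e[4]))
  } else {
    c(paste0(">=", e[1]), paste0(e[2], "-", e[1]), paste0(e[3], "-", e[2]),
      paste0(e[4], "-", e[3]), paste0("<", e[4]))
  }
}

#' Assign an HSP to one of five ordinal colour bins
#'
#' Bins follow the NCBI graphic-overview convention.  In `bits` mode the
#' edges are `{40, 50, 80, 200}` with each bin closed on its lower edge
#' (a bit score of exactly 40 falls in bin 1); in `evalue` mode the edges
#' are `{1, 1e-5, 1e-10, 1e-50}` with bin 0 for E >= 1 and bin 4 for
#' E < 1e-50.  The ordinal always increases with alignment quality.
#'
#' @param hsp A [new_hsp()] object, or a bare numeric score/E-value.
#' @param mode `"bits"` (default) or `"evalue"`.
#' @param edges Four increasing (bits) or decreasing (evalue) bin edges.
#' @return A list of class `color_bin` with fields `ordinal` (0..4),
#'   `label` and `mode`.
#' @export
#' @examples
#' score_bin(new_hsp("blastp", 55, 1e-9, 4, 4, 4, 0, 1, 4, 1, 4,
#'                   "ACDE", "ACDE", "ACDE"))$ordinal  # 2
score_bin <- function(hsp, mode = c("bits", "evalue"),
                      edges = NULL) {
  mode <- match.arg(mode)
  value <- if (inherits(hsp, "blast_hsp")) {
    if (mode == "bits") hsp$bit_score else hsp$evalue
  } else {
    as.numeric(hsp)
  }
  if (is.null(edges)) {
    edges <- if (mode == "bits") DEFAULT_BITS_EDGES else DEFAULT_EVALUE_EDGES
  }
  stopifnot(length(edges) == 4L)
  ordinal <- if (mode == "bits") {
    sum(value >= edges)
  } else {
    sum(value < edges)
  }
  structure(
    list(ordinal = as.integer(ordinal),
         label = bin_labels(mode, edges)[ordinal + 1L],
         mode = mode),
    class = "color_bin"
  )
}

#' Fraction of the query covered by a hit's HSPs
#'
#' Length of the union of the `[q_from, q_to]` intervals across the hit's
#' HSPs, divided by the query length.
#'
#' @param hit A [new_hit()] object.
#' @param query_len Query length.
#' @return A fraction in `[0, 1]`.
#' @export
query_coverage <- function(hit, query_len) {
  stopifnot(inherits(hit, "blast_hit"), query_len >= 1L)
  if (length(hit$hsps) == 0L) return(0)
  ir <- IRanges::IRanges(
    start = vapply(hit$hsps, `[[`, integer(1), "q_from"),
    end = vapply(hit$hsps, `[[`, integer(1), "q_to")
  )
  covered <- sum(IRanges::width(IRanges::reduce(ir)))
  covered / query_len
}
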