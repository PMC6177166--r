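# Chunked per-residue alignment view: the classic BLAST presentation of an
# HSP as Query/midline/Sbjct line triples at a fixed column width, with
# coordinate labels that advance by the program's step factor (3 nucleotides
# per column on translated sides) and run downwards on minus-strand /
# negative-frame sides.

# Per-chunk coordinate labels for one side of an HSP.
# `anchor` is the displayed start (from for ascending, to for descending).
chunk_labels <- function(chunk_seqs, anchor, step, descending) {
  nongap <- nchar(chunk_seqs) - n_gaps(chunk_seqs)
  dirstep <- if (descending) -step else step
  consumed <- c(0L, cumsum(nongap)[-length(nongap)])
  from <- anchor + dirstep * consumed
  to <- anchor + dirstep * (consumed + nongap) - sign(dirstep)
  list(from = from, to = to)
}

split_chunks <- function(s, width) {
  L <- nchar(s)
  starts <- seq.int(1L, L, by = width)
  substring(s, starts, pmin(starts + width - 1L, L))
}

#' Format an HSP as a chunked text alignment block
#'
#' Renders the query, midline and subject strings of one HSP as the familiar
#' BLAST alignment triples, `chunk_width` columns at a time.  Coordinate
#' labels advance by the step factor (3 for the nucleotide side of translated
#' searches, otherwise 1) times the number of non-gap symbols in each chunk,
#' and decrease on minus-strand or negative-frame sides.
#'
#' @param hsp A [new_hsp()] object.
#' @param program BLAST program; defaults to the HSP's own.
#' @param chunk_width Columns per chunk (>= 10; BLAST's default is 60).
#' @return An object of class `alignment_block`: a list with `lines` (the
#'   text lines, chunks separated by blank lines), `chunk_width` and
#'   `n_chunks`.
#' @export
#' @examples
#' hsp <- new_hsp("blastp", 52.8, 1e-8, 7, 6, 6, 0, 1, 7, 3, 9,
#'                "ACDEFGH", "ACDEFGY", "ACDEFG ", raw_score = 120)
#' cat(format_alignment(hsp)$lines, sep = "\n")
format_alignment <- function(hsp, program = hsp$program, chunk_width = 60L) {
  stopifnot(inherits(hsp, "blast_hsp"), chunk_width >= 10L)
  steps <- step_factors(program)
  desc_q <- side_descending(hsp$q_strand, hsp$q_frame)
  desc_s <- side_descending(hsp$s_strand, hsp$s_frame)

  q_chunks <- split_chunks(hsp$qseq, chunk_width)
  s_chunks <- split_chunks(hsp$hseq, chunk_width)
  m_chunks <- split_chunks(hsp$midline, chunk_width)

  q_lab <- chunk_labels(q_chunks, if (desc_q) hsp$q_to else hsp$q_from,
                        steps[["q"]], desc_q)
  s_lab <- chunk_labels(s_chunks, if (desc_s) hsp$s_to else hsp$s_from,
                        steps[["s"]], desc_s)

  w <- max(nchar(c(q_lab$from, q_lab$to, s_lab$from, s_lab$to)))
  prefix_w <- 5L + 2L + w + 2L     # "Query" + gap + coordinate + gap
  lines <- character()
  for (k in seq_along(q_chunks)) {
    qline <- sprintf("Query  %*d  %s  %d", w, q_lab$from[k], q_chunks[k],
                     q_lab$to[k])
    mline <- sub("\\s+$", "",
                 paste0(strrep(" ", prefix_w), m_chunks[k]))
    sline <- sprintf("Sbjct  %*d  %s  %d", w, s_lab$from[k], s_chunks[k],
                     s_lab$to[k])
    lines <- c(lines, qline, mline, sline,
               if (k < length(q_chunks)) "")
  }
  structure(
    list(lines = lines, chunk_width = as.integer(chunk_width),
         n_chunks = length(q_chunks)),
    class = "alignment_block"
  )
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(x$lines, sep = "\n")
  invisible(x)
}
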