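# The alignment data model: blast_report > blast_query > blast_hit > blast_hsp.
# Plain S3 lists with constructors and a recursive validator.  Coordinates are
# stored 1-based inclusive with from <= to on both sequences; minus-strand /
# negative-frame orientation is carried explicitly and serializers reconstruct
# descending display coordinates from it.

BLAST_PROGRAMS <- c("blastp", "blastn", "blastx", "tblastn", "tblastx")

# Coordinate step factors: translated sides advance 3 nucleotides per
# alignment column (blastx/tblastx query; tblastn/tblastx subject).
step_factors <- function(program) {
  c(
    q = if (program %in% c("blastx", "tblastx")) 3L else 1L,
    s = if (program %in% c("tblastn", "tblastx")) 3L else 1L
  )
}

# Alphabet at the alignment level: nucleotide only for blastn; all translated
# programs align amino acids.
alignment_alphabet <- function(program) {
  if (program == "blastn") {
    c("A", "C", "G", "T")
  } else {
    c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  }
}

# A side (query or subject) displays with descending coordinates when on the
# minus strand (blastn) or in a negative reading frame (translated programs).
side_descending <- function(strand, frame) {
  identical(strand, "minus") || (!is.na(frame) && frame < 0)
}

#' Construct a high-scoring pair (HSP)
#'
#' The HSP is the atom of BLAST reporting: one gapped local alignment between
#' a query region and a subject region, with its scores and counts.
#'
#' @param program BLAST program that produced the alignment (one of
#'   `"blastp"`, `"blastn"`, `"blastx"`, `"tblastn"`, `"tblastx"`); determines
#'   coordinate step factors and whether positives exist.
#' @param bit_score Normalised score in bits.
#' @param evalue Expected value (non-negative).
#' @param align_len Number of alignment columns.
#' @param identities,positives,gap_count Column counts; `positives` is
#'   `NA` for blastn.
#' @param q_from,q_to,s_from,s_to 1-based inclusive coordinates, `from <= to`.
#' @param qseq,hseq,midline Aligned query string, subject string and midline,
#'   all of length `align_len`.
#' @param raw_score Integer raw score, or `NA` when unknown.
#' @param q_strand,s_strand `"plus"`, `"minus"` or `"n/a"` (only blastn uses
#'   strands; translated sides encode orientation in the frame sign).
#' @param q_frame,s_frame Reading frame in `-3..-1, 1..3`, or `NA`.
#' @return An object of class `blast_hsp`.
#' @export
new_hsp <- function(program, bit_score, evalue, align_len,
                    identities, positives, gap_count,
                    q_from, q_to, s_from, s_to,
                    qseq, hseq, midline,
                    raw_score = NA_integer_,
                    q_strand = "n/a", s_strand = "n/a",
                    q_frame = NA_integer_, s_frame = NA_integer_) {
  structure(
    list(
      program = program,
      bit_score = as.numeric(bit_score),
      raw_score = as.integer(raw_score),
      evalue = as.numeric(evalue),
      align_len = as.integer(align_len),
      identities = as.integer(identities),
      positives = as.integer(positives),
      gap_count = as.integer(gap_count),
      q_from = as.integer(q_from), q_to = as.integer(q_to),
      s_from = as.integer(s_from), s_to = as.integer(s_to),
      q_strand = q_strand, s_strand = s_strand,
      q_frame = as.integer(q_frame), s_frame = as.integer(s_frame),
      qseq = qseq, hseq = hseq, midline = midline
    ),
    class = "blast_hsp"
  )
}

#' Construct a hit (one subject sequence with its HSPs)
#'
#' @param hit_id Subject identifier token.
#' @param description Free-text description (may be empty).
#' @param subject_len Subject sequence length.
#' @param hsps Non-empty list of [new_hsp()] objects.
#' @return An object of class `blast_hit`.
#' @export
new_hit <- function(hit_id, description, subject_len, hsps) {
  structure(
    list(
      hit_id = hit_id,
      description = description,
      subject_len = as.integer(subject_len),
      hsps = hsps
    ),
    class = "blast_hit"
  )
}

#' Construct a query result
#'
#' @param query_id Query identifier token.
#' @param query_desc Free-text description (may be empty).
#' @param query_len Query length in residues or bases.
#' @param hits Possibly-empty list of [new_hit()] objects ("No hits found"
#'   yields an empty list).
#' @return An object of class `blast_query`.
#' @export
new_query_result <- function(query_id, query_desc, query_len, hits = list()) {
  structure(
    list(
      query_id = query_id,
      query_desc = query_desc,
      query_len = as.integer(query_len),
      hits = hits
    ),
    class = "blast_query"
  )
}

#' Construct a BLAST report
#'
#' @param program One of `"blastp"`, `"blastn"`, `"blastx"`, `"tblastn"`,
#'   `"tblastx"`.
#' @param version Free-text version string (e.g. `"2.6.0+"`).
#' @param database Database name.
#' @param queries Ordered list of [new_query_result()] objects.
#' @param footer_stats Optional Karlin-Altschul footer statistics as
#'   `list(lambda =, k =, h =)`, or `NULL`.
#' @return An object of class `blast_report`.
#' @export
new_blast_report <- function(program, version, database, queries,
                             footer_stats = NULL) {
  program <- match.arg(tolower(program), BLAST_PROGRAMS)
  structure(
    list(
      program = program,
      version = version,
      database = database,
      queries = queries,
      footer_stats = footer_stats
    ),
    class = "blast_report"
  )
}

n_gaps <- function(seq) {
  lengths(regmatches(seq, gregexpr("-", seq, fixed = TRUE)))
}

# ---- validation -----------------------------------------------------------

validate_hsp <- function(hsp, program, query_len, subject_len, where = "hsp") {
  p <- character()
  note <- function(msg) p[[length(p) + 1L]] <<- sprintf("%s: %s", where, msg)

  L <- hsp$align_len
  if (is.na(L) || L < 1L) note("align_len must be a positive integer")
  if (nchar(hsp$qseq) != L || nchar(hsp$hseq) != L || nchar(hsp$midline) != L) {
    note(sprintf(
      "qseq/hseq/midline lengths (%d/%d/%d) must all equal align_len (%d)",
      nchar(hsp$qseq), nchar(hsp$hseq), nchar(hsp$midline), L
    ))
    return(p)  # downstream checks meaningless
  }

  if (hsp$identities < 0L || hsp$identities > L) {
    note("identities outside [0, align_len]")
  }
  if (!is.na(hsp$positives) &&
      (hsp$identities > hsp$positives || hsp$positives > L)) {
    note("need identities <= positives <= align_len")
  }

  gq <- n_gaps(hsp$qseq)
  gh <- n_gaps(hsp$hseq)
  if (hsp$gap_count != gq + gh) {
    note(sprintf(
      "gap_count %d != gaps counted in sequences (%d + %d)",
      hsp$gap_count, gq, gh
    ))
  }
  qc <- strsplit(hsp$qseq, "", fixed = TRUE)[[1]]
  hc <- strsplit(hsp$hseq, "", fixed = TRUE)[[1]]
  if (any(qc == "-" & hc == "-")) note("column gapped in both sequences")

  steps <- step_factors(program)
  if (is.na(hsp$q_from) || is.na(hsp$q_to) || hsp$q_from > hsp$q_to ||
      hsp$q_from < 1L) {
    note("query coordinates must satisfy 1 <= q_from <= q_to")
  } else {
    if (!is.na(query_len) && hsp$q_to > query_len) {
      note(sprintf("q_to %d exceeds query length %d", hsp$q_to, query_len))
    }
    span <- steps[["q"]] * (L - gq)
    if (hsp$q_to - hsp$q_from + 1L != span) {
      note(sprintf(
        "query span %d != step %d x non-gap columns %d",
        hsp$q_to - hsp$q_from + 1L, steps[["q"]], L - gq
      ))
    }
  }
  if (is.na(hsp$s_from) || is.na(hsp$s_to) || hsp$s_from > hsp$s_to ||
      hsp$s_from < 1L) {
    note("subject coordinates must satisfy 1 <= s_from <= s_to")
  } else {
    if (!is.na(subject_len) && hsp$s_to > subject_len) {
      note(sprintf("s_to %d exceeds subject length %d", hsp$s_to, subject_len))
    }
    span <- steps[["s"]] * (L - gh)
    if (hsp$s_to - hsp$s_from + 1L != span) {
      note(sprintf(
        "subject span %d != step %d x non-gap columns %d",
        hsp$s_to - hsp$s_from + 1L, steps[["s"]], L - gh
      ))
    }
  }

  if (program == "blastn") {
    if (!hsp$q_strand %in% c("plus", "minus") ||
        !hsp$s_strand %in% c("plus", "minus")) {
      note("blastn HSPs need plus/minus strands on both sides")
    }
    if (!is.na(hsp$q_frame) || !is.na(hsp$s_frame)) {
      note("blastn HSPs carry no frames")
    }
  } else {
    if (!identical(hsp$q_strand, "n/a") || !identical(hsp$s_strand, "n/a")) {
      note("strand must be n/a outside blastn")
    }
    q_translated <- program %in% c("blastx", "tblastx")
    s_translated <- program %in% c("tblastn", "tblastx")
    ok_frame <- function(f) !is.na(f) && f %in% c(-3:-1, 1:3)
    if (q_translated && !ok_frame(hsp$q_frame)) {
      note("translated query needs frame in -3..-1, 1..3")
    }
    if (!q_translated && !is.na(hsp$q_frame)) note("unexpected query frame")
    if (s_translated && !ok_frame(hsp$s_frame)) {
      note("translated subject needs frame in -3..-1, 1..3")
    }
    if (!s_translated && !is.na(hsp$s_frame)) note("unexpected subject frame")
  }

  if (is.na(hsp$evalue) || hsp$evalue < 0) note("evalue must be non-negative")
  p
}

#' Validate a BLAST report against the data-model invariants
#'
#' Checks every structural invariant: alignment string lengths, count bounds,
#' gap bookkeeping, coordinate spans against program step factors, strand and
#' frame rules.
#'
#' @param report A [new_blast_report()] object.
#' @return Invisibly, a character vector of problems (empty when valid).
#' @export
validate_blast_report <- function(report) {
  stopifnot(inherits(report, "blast_report"))
  problems <- character()
  for (qi in seq_along(report$queries)) {
    qr <- report$queries[[qi]]
    if (is.na(qr$query_len) || qr$query_len < 1L) {
      problems <- c(problems, sprintf("query %s: non-positive length", qr$query_id))
    }
    for (hi in seq_along(qr$hits)) {
      hit <- qr$hits[[hi]]
      if (length(hit$hsps) == 0L) {
        problems <- c(problems, sprintf(
          "query %s hit %s: hit must contain at least one HSP",
          qr$query_id, hit$hit_id
        ))
      }
      for (ki in seq_along(hit$hsps)) {
        problems <- c(problems, validate_hsp(
          hit$hsps[[ki]], report$program, qr$query_len, hit$subject_len,
          where = sprintf("query %s hit %s HSP %d", qr$query_id, hit$hit_id, ki)
        ))
      }
    }
  }
  invisible(problems)
}

# Abort with malformed_input if a report breaks any invariant.
assert_valid_report <- function(report) {
  problems <- validate_blast_report(report)
  if (length(problems)) {
    abort_malformed_input(paste(problems, collapse = "; "))
  }
  invisible(report)
}

# ---- print methods --------------------------------------------------------

#' @export
print.blast_report <- function(x, ...) {
  n_hits <- sum(vapply(x$queries, function(q) length(q$hits), integer(1)))
  n_hsps <- sum(vapply(
    x$queries,
    function(q) sum(vapply(q$hits, function(h) length(h$hsps), integer(1))),
    numeric(1)
  ))
  cat(sprintf(
    "<blast_report> %s %s | db: %s | %d quer%s, %d hit%s, %d HSP%s\n",
    toupper(x$program), x$version, x$database,
    length(x$queries), if (length(x$queries) == 1) "y" else "ies",
    n_hits, if (n_hits == 1) "" else "s",
    n_hsps, if (n_hsps == 1) "" else "s"
  ))
  invisible(x)
}

#' @export
print.blast_hsp <- function(x, ...) {
  cat(sprintf(
    "<blast_hsp> %.1f bits, E=%s | query %d-%d, subject %d-%d | %d/%d identities\n",
    x$bit_score, format_evalue(x$evalue),
    x$q_from, x$q_to, x$s_from, x$s_to, x$identities, x$align_len
  ))
  invisible(x)
}
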