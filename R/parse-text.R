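# Parser for the BLAST+ default pairwise-text report dialect.
#
# Line-oriented state machine over the grammar:
#
#   BLASTP 2.6.0+
#   Database: <name>
#   Query= <id> <desc>
#   Length=<Q>
#   [summary table | ***** No hits found *****]
#   > <hit_id> <description>
#   Length=<S>
#    Score = <b> bits (<raw>),  Expect = <e>
#    Identities = a/L (p%)[, Positives = b/L (q%)], Gaps = g/L (r%)
#    [Frame = ...] [Strand=Plus/Minus]
#   Query  <from>  <CHUNK>  <to>
#           <midline chunk>
#   Sbjct  <from>  <CHUNK>  <to>
#   ...
#   [Lambda K H footer]
#
# Hit detail sections are authoritative; the summary table is only
# cross-checked for hit count.  Coordinates are normalised to from <= to with
# orientation kept in strand (blastn) or frame sign (translated programs).

RX_PROGRAM <- "^(?i)(blastp|blastn|blastx|tblastn|tblastx)\\b\\s*(.*)$"
RX_SCORE <- paste0(
  "^Score\\s*=\\s*([0-9.eE+-]+)\\s*bits\\s*\\((\\d+)\\)",
  ",\\s*Expect\\s*=\\s*([0-9.eE+-]+)",
  "(?:,\\s*Method:.*)?,?\\s*$"      # BLAST+ appends ", Method: ..."
)
# Statistics/parameter boilerplate BLAST+ prints between and after sections;
# recognised so genuine files do not drown in unknown-line warnings.
RX_BOILERPLATE <- paste0(
  "^(Matrix:|Gap Penalties:|Neighboring words|Window for multiple|",
  "Length adjustment:|Effective |Gapped$|Posted date:|",
  "Number of |Total number|Database:|RID:|Reference|Score\\s+E$|",
  "\\(Bits\\)\\s+Value$|T: |A: |X1: |X2: |X3: |S1: |S2: )"
)
RX_IDENT <- paste0(
  "^Identities\\s*=\\s*(\\d+)/(\\d+)\\s*\\((\\d+)%\\)",
  "(?:,\\s*Positives\\s*=\\s*(\\d+)/(\\d+)\\s*\\((\\d+)%\\))?",
  ",\\s*Gaps\\s*=\\s*(\\d+)/(\\d+)\\s*\\((\\d+)%\\)\\s*$"
)
RX_FRAME <- "^Frame\\s*=\\s*([+-][1-3])(?:\\s*/\\s*([+-][1-3]))?\\s*$"
RX_STRAND <- "^Strand\\s*=\\s*(Plus|Minus)\\s*/\\s*(Plus|Minus)\\s*$"
RX_QCHUNK <- "^(Query\\s+\\d+\\s+)([A-Za-z*-]+)\\s+(\\d+)\\s*$"
RX_SCHUNK <- "^Sbjct\\s+(\\d+)\\s+([A-Za-z*-]+)\\s+(\\d+)\\s*$"
RX_BOUNDARY <- "^(Score\\s*=|>|Query=|Lambda\\b)"

#' Detect the format of a BLAST output
#'
#' @param raw A file path, connection, or the raw text itself.
#' @return `"blast_xml"` if the content opens with an XML declaration or a
#'   `BlastOutput` root element, `"pairwise_text"` if the first non-blank line
#'   begins with a BLAST program token; errors with condition class
#'   `unrecognised_format` otherwise (this includes BLAST "XML2" and JSON
#'   outputs, which are out of scope).
#' @export
#' @examples
#' detect_format("BLASTP 2.6.0+\nDatabase: db\n")
detect_format <- function(raw) {
  text <- read_input_text(raw)
  if (!nzchar(trimws(text))) {
    abort_unrecognised_format("input is empty")
  }
  head <- sub("^\\s+", "", text)
  if (grepl("^<\\?xml", head) || grepl("^<!DOCTYPE\\s+BlastOutput", head) ||
      grepl("^<BlastOutput", head)) {
    return("blast_xml")
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  first <- trimws(lines[nzchar(trimws(lines))][1])
  if (grepl(RX_PROGRAM, first, perl = TRUE)) {
    return("pairwise_text")
  }
  abort_unrecognised_format(
    "input is neither BLAST pairwise text nor BlastOutput XML"
  )
}

#' Parse a BLAST output of either supported format
#'
#' Dispatches on [detect_format()] to [parse_pairwise_text()] or
#' [parse_blast_xml()].  In strict mode (the default) any malformed section or
#' invariant violation raises an error of class `malformed_input`; in lenient
#' mode malformed hits/HSPs are dropped and reported as issues, never silently
#' repaired.
#'
#' @param raw A file path, connection, or the raw text itself.
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return A list with elements `report` (a `blast_report`) and `issues`
#'   (a list of [parse_issue()] records).
#' @export
parse_report <- function(raw, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  text <- read_input_text(raw)
  switch(detect_format(text),
    pairwise_text = parse_pairwise_text(text, mode),
    blast_xml = parse_blast_xml(text, mode)
  )
}

# Signal used internally to unwind one malformed unit in lenient mode.
skip_unit <- function(message) {
  stop(structure(
    class = c("bv_skip_unit", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

# Record an error-severity issue (aborts in strict mode) then unwind the
# enclosing unit so lenient mode can drop it.
unit_error <- function(col, message, line_no) {
  collect_issue(col, "error", message, line_no)
  skip_unit(message)
}

#' Parse BLAST pairwise-text output
#'
#' @inheritParams parse_report
#' @return As [parse_report()].
#' @export
parse_pairwise_text <- function(raw, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  text <- gsub("\r\n", "\n", read_input_text(raw), fixed = TRUE)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  tt <- trimws(lines)
  n <- length(lines)
  col <- new_issue_collector(mode)

  st <- new.env(parent = emptyenv())
  st$i <- 1L

  peek <- function() if (st$i <= n) tt[st$i] else NA_character_
  skip_blanks <- function() {
    while (st$i <= n && tt[st$i] == "") st$i <- st$i + 1L
  }
  # Advance past the current line, then to the next structural boundary.
  recover <- function() {
    st$i <- st$i + 1L
    while (st$i <= n && !grepl(RX_BOUNDARY, tt[st$i])) st$i <- st$i + 1L
  }

  # -- header ---------------------------------------------------------------
  skip_blanks()
  if (st$i > n) abort_unrecognised_format("input is empty")
  m <- regmatches(tt[st$i], regexec(RX_PROGRAM, tt[st$i], perl = TRUE))[[1]]
  if (length(m) == 0L) {
    abort_unrecognised_format("first line does not name a BLAST program")
  }
  program <- tolower(m[2])
  version <- trimws(m[3])
  st$i <- st$i + 1L

  database <- ""
  # Header block up to the first Query= section: capture Database:, ignore
  # citation/reference boilerplate silently.
  while (st$i <= n && !startsWith(tt[st$i], "Query=")) {
    if (startsWith(tt[st$i], "Database:") && !nzchar(database)) {
      database <- trimws(sub("^Database:", "", tt[st$i]))
    }
    st$i <- st$i + 1L
  }

  # -- helpers --------------------------------------------------------------

  # Description possibly continued over lines until a Length= line.
  read_id_desc <- function(first_rest) {
    id_m <- regmatches(first_rest, regexec("^(\\S+)\\s*(.*)$", first_rest))[[1]]
    if (length(id_m) == 0L) {
      unit_error(col, "section header lacks an identifier", st$i)
    }
    id <- id_m[2]
    desc <- id_m[3]
    st$i <- st$i + 1L
    while (st$i <= n && tt[st$i] != "" &&
           !grepl("^Length\\s*=\\s*\\d+$", tt[st$i])) {
      desc <- trimws(paste(desc, tt[st$i]))
      st$i <- st$i + 1L
    }
    list(id = id, desc = trimws(desc))
  }

  read_length <- function(what) {
    skip_blanks()
    lm <- if (st$i <= n) {
      regmatches(tt[st$i], regexec("^Length\\s*=\\s*(\\d+)$", tt[st$i]))[[1]]
    } else character()
    if (length(lm) == 0L) {
      unit_error(col, sprintf("expected Length= line for %s", what), st$i)
    }
    st$i <- st$i + 1L
    as.integer(lm[2])
  }

  parse_hsp <- function(query_len, subject_len, where) {
    line0 <- st$i
    sm <- regmatches(tt[st$i], regexec(RX_SCORE, tt[st$i]))[[1]]
    if (length(sm) == 0L) {
      unit_error(col, sprintf("%s: malformed Score line", where), st$i)
    }
    bit_score <- as.numeric(sm[2])
    raw_score <- as.integer(sm[3])
    evalue <- as.numeric(sm[4])
    if (is.na(bit_score) || is.na(evalue)) {
      unit_error(col, sprintf("%s: unparseable score values", where), st$i)
    }
    st$i <- st$i + 1L
    skip_blanks()

    im <- if (st$i <= n) {
      regmatches(tt[st$i], regexec(RX_IDENT, tt[st$i], perl = TRUE))[[1]]
    } else character()
    if (length(im) == 0L) {
      unit_error(col, sprintf("%s: missing Identities line", where), st$i)
    }
    identities <- as.integer(im[2])
    align_len <- as.integer(im[3])
    positives <- if (nzchar(im[5])) as.integer(im[5]) else NA_integer_
    gap_count <- as.integer(im[8])
    denoms <- as.integer(c(im[3], if (nzchar(im[6])) im[6], im[9]))
    if (length(unique(denoms)) != 1L) {
      unit_error(col, sprintf("%s: inconsistent denominators", where), st$i)
    }
    st$i <- st$i + 1L

    q_strand <- "n/a"; s_strand <- "n/a"
    q_frame <- NA_integer_; s_frame <- NA_integer_
    repeat {
      skip_blanks()
      t <- peek()
      if (!is.na(t) && grepl(RX_FRAME, t)) {
        fm <- regmatches(t, regexec(RX_FRAME, t))[[1]]
        f1 <- as.integer(fm[2])
        f2 <- if (nzchar(fm[3])) as.integer(fm[3]) else NA_integer_
        if (program == "blastx") {
          q_frame <- f1
        } else if (program == "tblastn") {
          s_frame <- f1
        } else if (program == "tblastx") {
          if (is.na(f2)) {
            unit_error(col, sprintf("%s: tblastx needs two frames", where), st$i)
          }
          q_frame <- f1; s_frame <- f2
        } else {
          collect_issue(col, "warning",
                        sprintf("%s: unexpected Frame line ignored", where), st$i)
        }
        st$i <- st$i + 1L
      } else if (!is.na(t) && grepl(RX_STRAND, t)) {
        sm2 <- regmatches(t, regexec(RX_STRAND, t))[[1]]
        if (program == "blastn") {
          q_strand <- tolower(sm2[2]); s_strand <- tolower(sm2[3])
        } else {
          collect_issue(col, "warning",
                        sprintf("%s: unexpected Strand line ignored", where), st$i)
        }
        st$i <- st$i + 1L
      } else {
        break
      }
    }
    if (program == "blastn" && q_strand == "n/a") {
      unit_error(col, sprintf("%s: blastn HSP lacks a Strand line", where), st$i)
    }

    # -- alignment chunks --
    chunks <- list()
    repeat {
      skip_blanks()
      if (st$i > n || !grepl("^Query\\s+\\d", tt[st$i])) break
      qm <- regmatches(lines[st$i], regexec(RX_QCHUNK, lines[st$i]))[[1]]
      if (length(qm) == 0L) {
        unit_error(col, sprintf("%s: malformed Query chunk line", where), st$i)
      }
      seq_start <- nchar(qm[2]) + 1L         # column where the sequence begins
      q_lab_from <- as.integer(sub("^Query\\s+(\\d+)\\s+$", "\\1", qm[2]))
      q_chunk <- qm[3]
      q_lab_to <- as.integer(qm[4])
      if (st$i + 2L > n) {
        unit_error(col, sprintf("%s: truncated alignment chunk", where), st$i)
      }
      mid_raw <- lines[st$i + 1L]
      width <- nchar(q_chunk)
      mid_padded <- formatC(mid_raw, width = -(seq_start + width - 1L))
      mid_chunk <- substr(mid_padded, seq_start, seq_start + width - 1L)
      sm3 <- regmatches(lines[st$i + 2L],
                        regexec(RX_SCHUNK, lines[st$i + 2L]))[[1]]
      if (length(sm3) == 0L) {
        unit_error(col, sprintf("%s: malformed Sbjct chunk line", where),
                   st$i + 2L)
      }
      if (nchar(sm3[3]) != width) {
        unit_error(col, sprintf("%s: chunk width mismatch", where), st$i + 2L)
      }
      chunks[[length(chunks) + 1L]] <- list(
        q_from = q_lab_from, q_chunk = q_chunk, q_to = q_lab_to,
        mid = mid_chunk,
        s_from = as.integer(sm3[2]), s_chunk = sm3[3], s_to = as.integer(sm3[4])
      )
      st$i <- st$i + 3L
    }
    if (length(chunks) == 0L) {
      unit_error(col, sprintf("%s: HSP has no alignment chunks", where), line0)
    }

    steps <- step_factors(program)
    desc_q <- side_descending(q_strand, q_frame)
    desc_s <- side_descending(s_strand, s_frame)

    # Validate per-chunk label continuity on one side; returns total non-gap
    # symbol count.
    check_side <- function(side, step, descending) {
      from_lab <- vapply(chunks, `[[`, integer(1), paste0(side, "_from"))
      to_lab <- vapply(chunks, `[[`, integer(1), paste0(side, "_to"))
      seqs <- vapply(chunks, `[[`, character(1), paste0(side, "_chunk"))
      nongap <- nchar(seqs) - n_gaps(seqs)
      expected <- from_lab[1]
      for (k in seq_along(chunks)) {
        dirstep <- if (descending) -step else step
        to_expect <- expected + dirstep * nongap[k] - sign(dirstep)
        if (from_lab[k] != expected || to_lab[k] != to_expect) {
          unit_error(col, sprintf(
            "%s: %s chunk %d coordinates discontinuous (saw %d..%d, expected %d..%d)",
            where, if (side == "q") "query" else "subject",
            k, from_lab[k], to_lab[k], expected, to_expect
          ), line0)
        }
        expected <- expected + dirstep * nongap[k]
      }
      sum(nongap)
    }
    tot_q <- check_side("q", steps[["q"]], desc_q)
    tot_s <- check_side("s", steps[["s"]], desc_s)

    first_q <- chunks[[1]]$q_from
    first_s <- chunks[[1]]$s_from
    if (desc_q) {
      q_to <- first_q; q_from <- first_q - steps[["q"]] * tot_q + 1L
    } else {
      q_from <- first_q; q_to <- first_q + steps[["q"]] * tot_q - 1L
    }
    if (desc_s) {
      s_to <- first_s; s_from <- first_s - steps[["s"]] * tot_s + 1L
    } else {
      s_from <- first_s; s_to <- first_s + steps[["s"]] * tot_s - 1L
    }

    hsp <- new_hsp(
      program = program,
      bit_score = bit_score, raw_score = raw_score, evalue = evalue,
      align_len = align_len,
      identities = identities, positives = positives, gap_count = gap_count,
      q_from = q_from, q_to = q_to, s_from = s_from, s_to = s_to,
      qseq = paste(vapply(chunks, `[[`, character(1), "q_chunk"), collapse = ""),
      hseq = paste(vapply(chunks, `[[`, character(1), "s_chunk"), collapse = ""),
      midline = paste(vapply(chunks, `[[`, character(1), "mid"), collapse = ""),
      q_strand = q_strand, s_strand = s_strand,
      q_frame = q_frame, s_frame = s_frame
    )
    problems <- validate_hsp(hsp, program, query_len, subject_len, where)
    if (length(problems)) {
      unit_error(col, paste(problems, collapse = "; "), line0)
    }
    hsp
  }

  parse_hit <- function(query_id, query_len) {
    rest <- trimws(sub("^>", "", tt[st$i]))
    hd <- read_id_desc(rest)
    where0 <- sprintf("query %s hit %s", query_id, hd$id)
    subject_len <- read_length(where0)
    hsps <- list()
    repeat {
      skip_blanks()
      if (st$i > n || !grepl("^Score\\s*=", tt[st$i])) break
      k <- length(hsps) + 1L
      hsp_start <- st$i
      hsp <- tryCatch(
        parse_hsp(query_len, subject_len, sprintf("%s HSP %d", where0, k)),
        bv_skip_unit = function(e) NULL
      )
      if (is.null(hsp)) {
        # parse_hsp already recorded the issue; resynchronise without
        # consuming the next unit if the cursor already reached it
        if (st$i == hsp_start) {
          recover()
        } else {
          skip_blanks()
          if (st$i <= n && !grepl(RX_BOUNDARY, tt[st$i])) recover()
        }
        next
      }
      hsps[[k]] <- hsp
    }
    if (length(hsps) == 0L) {
      unit_error(col, sprintf("%s: hit contains no valid HSP", where0), st$i)
    }
    new_hit(hd$id, hd$desc, subject_len, hsps)
  }

  parse_query <- function() {
    rest <- trimws(sub("^Query=", "", tt[st$i]))
    qh <- read_id_desc(rest)
    query_len <- read_length(sprintf("query %s", qh$id))
    hits <- list()
    n_summary <- NA_integer_
    saw_no_hits <- FALSE
    repeat {
      skip_blanks()
      if (st$i > n) break
      t <- tt[st$i]
      if (startsWith(t, "Query=") || grepl("^Lambda\\b", t)) break
      if (grepl("No hits found", t, fixed = TRUE)) {
        saw_no_hits <- TRUE
        st$i <- st$i + 1L
      } else if (startsWith(t, "Sequences producing significant alignments")) {
        st$i <- st$i + 1L
        skip_blanks()
        cnt <- 0L
        while (st$i <= n && tt[st$i] != "" && !startsWith(tt[st$i], ">")) {
          cnt <- cnt + 1L
          st$i <- st$i + 1L
        }
        n_summary <- cnt
      } else if (startsWith(t, ">")) {
        hit_start <- st$i
        hit <- tryCatch(parse_hit(qh$id, query_len),
                        bv_skip_unit = function(e) NULL)
        if (is.null(hit)) {
          # skip forward only if no progress was made past the failed header
          if (st$i == hit_start ||
              (st$i <= n && !grepl(RX_BOUNDARY, tt[st$i]) &&
                 !startsWith(tt[st$i], "Sequences producing") &&
                 !grepl("No hits found", tt[st$i], fixed = TRUE))) {
            recover()
          }
        } else {
          hits[[length(hits) + 1L]] <- hit
        }
      } else if (grepl(RX_BOILERPLATE, t)) {
        st$i <- st$i + 1L      # statistics/parameter boilerplate: ignore
      } else {
        collect_issue(col, "warning",
                      sprintf("unrecognised line skipped: %s",
                              substr(t, 1, 60)), st$i)
        st$i <- st$i + 1L
      }
    }
    if (!is.na(n_summary) && n_summary != length(hits)) {
      collect_issue(col, "warning", sprintf(
        "query %s: summary table lists %d hits but %d detail sections parsed",
        qh$id, n_summary, length(hits)
      ))
    }
    new_query_result(qh$id, qh$desc, query_len, hits)
  }

  parse_footer <- function() {
    st$i <- st$i + 1L          # past the "Lambda      K        H" header
    skip_blanks()
    if (st$i > n) return(NULL)
    nums <- suppressWarnings(as.numeric(
      regmatches(tt[st$i], gregexpr("[0-9.eE+-]+", tt[st$i]))[[1]]
    ))
    st$i <- st$i + 1L
    if (length(nums) >= 3L && !anyNA(nums[1:3])) {
      list(lambda = nums[1], k = nums[2], h = nums[3])
    } else {
      collect_issue(col, "warning", "unparseable Lambda/K/H footer", st$i - 1L)
      NULL
    }
  }

  # -- main loop ------------------------------------------------------------
  queries <- list()
  footer_stats <- NULL
  while (st$i <= n) {
    t <- tt[st$i]
    if (t == "") {
      st$i <- st$i + 1L
    } else if (startsWith(t, "Query=")) {
      q_start <- st$i
      qr <- tryCatch(parse_query(), bv_skip_unit = function(e) NULL)
      if (is.null(qr)) {
        if (st$i == q_start ||
            (st$i <= n && !grepl(RX_BOUNDARY, tt[st$i]))) {
          recover()
        }
      } else {
        queries[[length(queries) + 1L]] <- qr
      }
    } else if (grepl("^Lambda\\b", t)) {
      fs <- parse_footer()
      if (!is.null(fs) && is.null(footer_stats)) footer_stats <- fs
    } else if (grepl(RX_BOILERPLATE, t)) {
      st$i <- st$i + 1L
    } else {
      collect_issue(col, "warning",
                    sprintf("unrecognised line skipped: %s", substr(t, 1, 60)),
                    st$i)
      st$i <- st$i + 1L
    }
  }

  if (length(queries) == 0L && mode == "strict") {
    abort_malformed_input("file contains no query sections")
  }

  report <- new_blast_report(program, version, database, queries, footer_stats)
  list(report = report, issues = col$issues)
}
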