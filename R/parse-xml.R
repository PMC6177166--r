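# Parser for NCBI BlastOutput XML (the classic DTD with the
# Iteration/Hit/Hsp element hierarchy).  Orientation mapping: blastn encodes
# strands as Hsp_query-frame / Hsp_hit-frame values of +1/-1; translated
# programs carry real frames; a frame of 0 or an absent element means "no
# frame".  BLAST "XML2" (Seq-align based) documents are rejected by
# detect_format() upstream.

#' Parse NCBI BlastOutput XML
#'
#' @inheritParams parse_report
#' @return As [parse_report()].
#' @export
parse_blast_xml <- function(raw, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  text <- read_input_text(raw)
  col <- new_issue_collector(mode)

  doc <- tryCatch(
    xml2::read_xml(text),
    error = function(e) abort_malformed_input(
      paste0("not well-formed XML: ", conditionMessage(e))
    )
  )
  if (xml2::xml_name(doc) != "BlastOutput") {
    abort_unrecognised_format("XML root element is not BlastOutput")
  }

  el_text <- function(node, name, required = TRUE, where = name) {
    found <- xml2::xml_find_first(node, paste0("./", name))
    if (inherits(found, "xml_missing")) {
      if (required) {
        unit_error(col, sprintf("%s: missing mandatory element <%s>", where, name),
                   NA_integer_)
      }
      return(NA_character_)
    }
    xml2::xml_text(found)
  }

  program <- tolower(trimws(el_text(doc, "BlastOutput_program",
                                    where = "report header")))
  if (!program %in% BLAST_PROGRAMS) {
    abort_malformed_input(sprintf("unknown BLAST program '%s'", program))
  }
  version <- trimws(el_text(doc, "BlastOutput_version", required = FALSE))
  if (is.na(version)) version <- ""
  version <- sub("^(?i)(blastp|blastn|blastx|tblastn|tblastx)\\s+", "",
                 version, perl = TRUE)
  database <- el_text(doc, "BlastOutput_db", required = FALSE)
  if (is.na(database)) database <- ""

  split_def <- function(def) {
    def <- trimws(def)
    m <- regmatches(def, regexec("^(\\S+)\\s*(.*)$", def))[[1]]
    if (length(m) == 0L) list(id = def, desc = "") else list(id = m[2], desc = m[3])
  }

  parse_hsp_node <- function(node, query_len, subject_len, where) {
    kids <- xml2::xml_children(node)
    vals <- stats::setNames(xml2::xml_text(kids), xml2::xml_name(kids))
    need <- function(name) {
      if (!name %in% names(vals)) {
        unit_error(col, sprintf("%s: missing mandatory element <%s>", where, name),
                   NA_integer_)
      }
      vals[[name]]
    }
    opt <- function(name) if (name %in% names(vals)) vals[[name]] else NA_character_

    qseq <- need("Hsp_qseq")
    hseq <- need("Hsp_hseq")
    midline <- need("Hsp_midline")
    gaps <- opt("Hsp_gaps")
    gap_count <- if (is.na(gaps)) n_gaps(qseq) + n_gaps(hseq) else as.integer(gaps)

    qf <- suppressWarnings(as.integer(opt("Hsp_query-frame")))
    sf <- suppressWarnings(as.integer(opt("Hsp_hit-frame")))
    if (program == "blastn") {
      q_strand <- if (!is.na(qf) && qf < 0) "minus" else "plus"
      s_strand <- if (!is.na(sf) && sf < 0) "minus" else "plus"
      q_frame <- NA_integer_; s_frame <- NA_integer_
    } else {
      q_strand <- "n/a"; s_strand <- "n/a"
      q_frame <- if (!is.na(qf) && qf != 0L &&
                     program %in% c("blastx", "tblastx")) qf else NA_integer_
      s_frame <- if (!is.na(sf) && sf != 0L &&
                     program %in% c("tblastn", "tblastx")) sf else NA_integer_
    }

    pos <- opt("Hsp_positive")
    hsp <- new_hsp(
      program = program,
      bit_score = as.numeric(need("Hsp_bit-score")),
      raw_score = suppressWarnings(as.integer(opt("Hsp_score"))),
      evalue = as.numeric(need("Hsp_evalue")),
      align_len = as.integer(need("Hsp_align-len")),
      identities = as.integer(need("Hsp_identity")),
      positives = if (is.na(pos)) NA_integer_ else as.integer(pos),
      gap_count = gap_count,
      q_from = as.integer(need("Hsp_query-from")),
      q_to = as.integer(need("Hsp_query-to")),
      s_from = as.integer(need("Hsp_hit-from")),
      s_to = as.integer(need("Hsp_hit-to")),
      qseq = qseq, hseq = hseq, midline = midline,
      q_strand = q_strand, s_strand = s_strand,
      q_frame = q_frame, s_frame = s_frame
    )
    problems <- validate_hsp(hsp, program, query_len, subject_len, where)
    if (length(problems)) {
      unit_error(col, paste(problems, collapse = "; "), NA_integer_)
    }
    hsp
  }

  parse_hit_node <- function(node, query_id, query_len) {
    hit_id <- el_text(node, "Hit_id", where = sprintf("query %s hit", query_id))
    desc <- el_text(node, "Hit_def", required = FALSE)
    if (is.na(desc)) desc <- ""
    where0 <- sprintf("query %s hit %s", query_id, hit_id)
    subject_len <- as.integer(el_text(node, "Hit_len", where = where0))
    hsp_nodes <- xml2::xml_find_all(node, "./Hit_hsps/Hsp")
    hsps <- list()
    for (k in seq_along(hsp_nodes)) {
      hsp <- tryCatch(
        parse_hsp_node(hsp_nodes[[k]], query_len, subject_len,
                       sprintf("%s HSP %d", where0, k)),
        bv_skip_unit = function(e) NULL
      )
      if (!is.null(hsp)) hsps[[length(hsps) + 1L]] <- hsp
    }
    if (length(hsps) == 0L) {
      unit_error(col, sprintf("%s: hit contains no valid HSP", where0),
                 NA_integer_)
    }
    new_hit(hit_id, trimws(desc), subject_len, hsps)
  }

  iterations <- xml2::xml_find_all(doc, "./BlastOutput_iterations/Iteration")
  queries <- list()
  for (it in iterations) {
    def <- el_text(it, "Iteration_query-def", required = FALSE)
    if (is.na(def) || !nzchar(trimws(def))) {
      def <- el_text(it, "Iteration_query-ID", where = "iteration")
    }
    qd <- split_def(def)
    query_len <- as.integer(el_text(it, "Iteration_query-len",
                                    where = sprintf("query %s", qd$id)))
    hit_nodes <- xml2::xml_find_all(it, "./Iteration_hits/Hit")
    hits <- list()
    for (hn in hit_nodes) {
      hit <- tryCatch(parse_hit_node(hn, qd$id, query_len),
                      bv_skip_unit = function(e) NULL)
      if (!is.null(hit)) hits[[length(hits) + 1L]] <- hit
    }
    queries[[length(queries) + 1L]] <-
      new_query_result(qd$id, qd$desc, query_len, hits)
  }

  footer_stats <- NULL
  stat <- xml2::xml_find_first(doc, ".//Statistics")
  if (!inherits(stat, "xml_missing")) {
    lam <- xml2::xml_text(xml2::xml_find_first(stat, "./Statistics_lambda"))
    kap <- xml2::xml_text(xml2::xml_find_first(stat, "./Statistics_kappa"))
    ent <- xml2::xml_text(xml2::xml_find_first(stat, "./Statistics_entropy"))
    vals <- suppressWarnings(as.numeric(c(lam, kap, ent)))
    if (!anyNA(vals)) {
      footer_stats <- list(lambda = vals[1], k = vals[2], h = vals[3])
    }
  }

  if (length(queries) == 0L && mode == "strict") {
    abort_malformed_input("XML contains no Iteration elements")
  }

  report <- new_blast_report(program, version, database, queries, footer_stats)
  list(report = report, issues = col$issues)
}
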