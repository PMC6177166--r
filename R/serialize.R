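# Serializers emitting the same two formats the parsers consume: the
# pairwise-text dialect (bit scores with one decimal, BLAST-style E-value
# formatting, 60-column chunks, descending coordinates on minus sides) and
# classic BlastOutput XML.  Together with the parsers they form the
# round-trip contract the whole test suite leans on.

# Frame elements for XML: blastn encodes strands as +/-1; translated sides
# carry their real frame; everything else is 0.
xml_frames <- function(program, hsp) {
  if (program == "blastn") {
    c(
      if (identical(hsp$q_strand, "minus")) -1L else 1L,
      if (identical(hsp$s_strand, "minus")) -1L else 1L
    )
  } else {
    c(
      if (!is.na(hsp$q_frame)) hsp$q_frame else 0L,
      if (!is.na(hsp$s_frame)) hsp$s_frame else 0L
    )
  }
}

#' Serialize a report to the BLAST pairwise-text dialect
#'
#' Emits the documented grammar: a program/version header, `Database:` line,
#' one `Query=` section per query (with a summary table cross-referencing the
#' hit detail sections, or the `No hits found` sentinel), per-HSP score and
#' count lines, chunked alignments, and an optional Lambda/K/H footer.
#' Minus-strand / negative-frame sides are printed with descending
#' coordinates.
#'
#' @param report A [new_blast_report()] object.
#' @param chunk_width Alignment columns per chunk (default 60, BLAST's own).
#' @return A single string (the full file contents).
#' @export
serialize_pairwise_text <- function(report, chunk_width = 60L) {
  stopifnot(inherits(report, "blast_report"))
  program <- report$program
  out <- list()
  put <- function(...) out[[length(out) + 1L]] <<- c(...)

  put(paste0(toupper(program), " ", report$version), "", "")
  put(paste0("Database: ", report$database), "", "")

  for (qr in report$queries) {
    qhead <- paste0("Query= ", qr$query_id,
                    if (nzchar(qr$query_desc)) paste0(" ", qr$query_desc))
    put(qhead, "", sprintf("Length=%d", qr$query_len), "")

    if (length(qr$hits) == 0L) {
      put("", "***** No hits found *****", "", "")
      next
    }

    put("Sequences producing significant alignments:", "")
    for (hit in qr$hits) {
      best <- hit$hsps[[which.max(vapply(hit$hsps, `[[`, numeric(1),
                                         "bit_score"))]]
      label <- trimws(paste(hit$hit_id, hit$description))
      if (nchar(label) > 60) label <- substr(label, 1, 60)
      put(sprintf("  %-62s %6.0f  %s", label, best$bit_score,
                  format_evalue(best$evalue)))
    }
    put("", "")

    for (hit in qr$hits) {
      hhead <- paste0("> ", hit$hit_id,
                      if (nzchar(hit$description)) paste0(" ", hit$description))
      put(hhead, sprintf("Length=%d", hit$subject_len), "")
      for (hsp in hit$hsps) {
        L <- hsp$align_len
        put(sprintf(" Score = %s bits (%d),  Expect = %s",
                    format_bits(hsp$bit_score),
                    if (is.na(hsp$raw_score)) {
                      as.integer(round(hsp$bit_score * 2))
                    } else hsp$raw_score,
                    format_evalue(hsp$evalue)))
        pos_part <- if (!is.na(hsp$positives)) {
          sprintf(", Positives = %d/%d (%d%%)", hsp$positives, L,
                  pct_of(hsp$positives, L))
        } else ""
        put(sprintf(" Identities = %d/%d (%d%%)%s, Gaps = %d/%d (%d%%)",
                    hsp$identities, L, pct_of(hsp$identities, L), pos_part,
                    hsp$gap_count, L, pct_of(hsp$gap_count, L)))
        if (program == "blastn") {
          cap <- function(s) paste0(toupper(substr(s, 1, 1)), substr(s, 2, 99))
          put(sprintf(" Strand=%s/%s", cap(hsp$q_strand), cap(hsp$s_strand)))
        } else if (program == "blastx") {
          put(sprintf(" Frame = %+d", hsp$q_frame))
        } else if (program == "tblastn") {
          put(sprintf(" Frame = %+d", hsp$s_frame))
        } else if (program == "tblastx") {
          put(sprintf(" Frame = %+d/%+d", hsp$q_frame, hsp$s_frame))
        }
        put("")
        put(format_alignment(hsp, program, chunk_width)$lines)
        put("", "")
      }
    }
  }

  if (!is.null(report$footer_stats)) {
    fs <- report$footer_stats
    put("Lambda      K        H",
        sprintf("   %.3f   %.4f    %.3f", fs$lambda, fs$k, fs$h),
        "")
  }
  paste(unlist(out), collapse = "\n")
}

#' Serialize a report to NCBI BlastOutput XML
#'
#' Classic BlastOutput DTD structure (Iteration/Hit/Hsp hierarchy), the
#' inverse of [parse_blast_xml()].  Real-valued fields are written at full
#' precision, so XML round-trips are lossless up to floating-point printing.
#'
#' @param report A [new_blast_report()] object.
#' @return A single string (the XML document).
#' @export
serialize_xml <- function(report) {
  stopifnot(inherits(report, "blast_report"))
  program <- report$program
  num <- function(x) sprintf("%.10g", x)
  out <- list()
  put <- function(...) out[[length(out) + 1L]] <<- c(...)

  q1 <- if (length(report$queries)) report$queries[[1]] else NULL
  put(
    "<?xml version=\"1.0\"?>",
    paste0("<!DOCTYPE BlastOutput PUBLIC \"-//NCBI//NCBI BlastOutput/EN\" ",
           "\"http://www.ncbi.nlm.nih.gov/dtd/NCBI_BlastOutput.dtd\">"),
    "<BlastOutput>",
    sprintf("  <BlastOutput_program>%s</BlastOutput_program>", program),
    sprintf("  <BlastOutput_version>%s</BlastOutput_version>",
            xml_escape(trimws(paste(toupper(program), report$version)))),
    sprintf("  <BlastOutput_db>%s</BlastOutput_db>",
            xml_escape(report$database))
  )
  if (!is.null(q1)) {
    put(
      sprintf("  <BlastOutput_query-ID>%s</BlastOutput_query-ID>",
              xml_escape(q1$query_id)),
      sprintf("  <BlastOutput_query-def>%s</BlastOutput_query-def>",
              xml_escape(trimws(paste(q1$query_id, q1$query_desc)))),
      sprintf("  <BlastOutput_query-len>%d</BlastOutput_query-len>",
              q1$query_len)
    )
  }
  put("  <BlastOutput_iterations>")

  for (qi in seq_along(report$queries)) {
    qr <- report$queries[[qi]]
    put(
      "    <Iteration>",
      sprintf("      <Iteration_iter-num>%d</Iteration_iter-num>", qi),
      sprintf("      <Iteration_query-ID>%s</Iteration_query-ID>",
              xml_escape(qr$query_id)),
      sprintf("      <Iteration_query-def>%s</Iteration_query-def>",
              xml_escape(trimws(paste(qr$query_id, qr$query_desc)))),
      sprintf("      <Iteration_query-len>%d</Iteration_query-len>",
              qr$query_len),
      "      <Iteration_hits>"
    )
    for (hi in seq_along(qr$hits)) {
      hit <- qr$hits[[hi]]
      put(
        "        <Hit>",
        sprintf("          <Hit_num>%d</Hit_num>", hi),
        sprintf("          <Hit_id>%s</Hit_id>", xml_escape(hit$hit_id)),
        sprintf("          <Hit_def>%s</Hit_def>",
                xml_escape(hit$description)),
        sprintf("          <Hit_accession>%s</Hit_accession>",
                xml_escape(hit$hit_id)),
        sprintf("          <Hit_len>%d</Hit_len>", hit$subject_len),
        "          <Hit_hsps>"
      )
      for (ki in seq_along(hit$hsps)) {
        hsp <- hit$hsps[[ki]]
        fr <- xml_frames(program, hsp)
        pos_el <- if (!is.na(hsp$positives)) {
          sprintf("              <Hsp_positive>%d</Hsp_positive>\n",
                  hsp$positives)
        } else ""
        score_el <- if (!is.na(hsp$raw_score)) {
          sprintf("              <Hsp_score>%d</Hsp_score>\n", hsp$raw_score)
        } else ""
        put(sprintf(paste0(
          "            <Hsp>\n",
          "              <Hsp_num>%d</Hsp_num>\n",
          "              <Hsp_bit-score>%s</Hsp_bit-score>\n",
          "%s",
          "              <Hsp_evalue>%s</Hsp_evalue>\n",
          "              <Hsp_query-from>%d</Hsp_query-from>\n",
          "              <Hsp_query-to>%d</Hsp_query-to>\n",
          "              <Hsp_hit-from>%d</Hsp_hit-from>\n",
          "              <Hsp_hit-to>%d</Hsp_hit-to>\n",
          "              <Hsp_query-frame>%d</Hsp_query-frame>\n",
          "              <Hsp_hit-frame>%d</Hsp_hit-frame>\n",
          "              <Hsp_identity>%d</Hsp_identity>\n",
          "%s",
          "              <Hsp_gaps>%d</Hsp_gaps>\n",
          "              <Hsp_align-len>%d</Hsp_align-len>\n",
          "              <Hsp_qseq>%s</Hsp_qseq>\n",
          "              <Hsp_hseq>%s</Hsp_hseq>\n",
          "              <Hsp_midline>%s</Hsp_midline>\n",
          "            </Hsp>"),
          ki, num(hsp$bit_score), score_el, num(hsp$evalue),
          hsp$q_from, hsp$q_to, hsp$s_from, hsp$s_to,
          fr[1], fr[2], hsp$identities, pos_el, hsp$gap_count,
          hsp$align_len,
          xml_escape(hsp$qseq), xml_escape(hsp$hseq), xml_escape(hsp$midline)
        ))
      }
      put("          </Hit_hsps>", "        </Hit>")
    }
    put("      </Iteration_hits>")
    if (!is.null(report$footer_stats)) {
      fs <- report$footer_stats
      put(
        "      <Iteration_stat>",
        "        <Statistics>",
        sprintf("          <Statistics_lambda>%s</Statistics_lambda>",
                num(fs$lambda)),
        sprintf("          <Statistics_kappa>%s</Statistics_kappa>", num(fs$k)),
        sprintf("          <Statistics_entropy>%s</Statistics_entropy>",
                num(fs$h)),
        "        </Statistics>",
        "      </Iteration_stat>"
      )
    }
    put("    </Iteration>")
  }

  put("  </BlastOutput_iterations>", "</BlastOutput>")
  paste(unlist(out), collapse = "\n")
}
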