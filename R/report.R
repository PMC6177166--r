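# Report assembly: the per-HSP attribute table (bit score, E-value, identity,
# positives, gaps plus coordinates), RFC 4180 CSV export, and the standalone
# HTML report embedding all three visual components per query.
#
# Anchor naming contract (stable, documented for post-processing): the
# alignment block of HSP k of the hit shown in row h of query section q has
# id "aln-q<q>-h<h>-s<k>", where q is the 1-based query index in file order
# and h the 1-based position in the displayed (best-first) hit order.  Each
# table row links to its block through this id.

HSP_TABLE_COLS <- c(
  "query_id", "hit_id", "description", "bit_score", "evalue",
  "pct_identity", "pct_positives", "pct_gaps",
  "q_from", "q_to", "s_from", "s_to"
)

#' Build the per-HSP attribute table for one query
#'
#' One row per HSP with the five attributes of the tabular view (bit score,
#' expected value, identity, positives and gaps, the latter three as integer
#' percentages) plus identifiers and coordinates.  Rows follow the display
#' ordering: hits best-first (max bit score desc, min E-value asc, input
#' order), HSPs within a hit by descending bit score.
#'
#' @param qr A [new_query_result()] object.
#' @return A data frame with the 12 columns above; `pct_positives` is `NA`
#'   for blastn.
#' @export
build_hsp_table <- function(qr) {
  stopifnot(inherits(qr, "blast_query"))
  rows <- list()
  for (hi in hit_order(qr$hits)) {
    hit <- qr$hits[[hi]]
    hsps <- hit$hsps[order(-vapply(hit$hsps, `[[`, numeric(1), "bit_score"))]
    for (hsp in hsps) {
      L <- hsp$align_len
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = qr$query_id,
        hit_id = hit$hit_id,
        description = hit$description,
        bit_score = hsp$bit_score,
        evalue = hsp$evalue,
        pct_identity = pct_of(hsp$identities, L),
        pct_positives = if (is.na(hsp$positives)) NA_integer_ else {
          pct_of(hsp$positives, L)
        },
        pct_gaps = pct_of(hsp$gap_count, L),
        q_from = hsp$q_from, q_to = hsp$q_to,
        s_from = hsp$s_from, s_to = hsp$s_to,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    df <- data.frame(
      query_id = character(), hit_id = character(), description = character(),
      bit_score = numeric(), evalue = numeric(),
      pct_identity = integer(), pct_positives = integer(),
      pct_gaps = integer(),
      q_from = integer(), q_to = integer(),
      s_from = integer(), s_to = integer(),
      stringsAsFactors = FALSE
    )
    return(df)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export HSP table rows as CSV
#'
#' RFC 4180 quoting, UTF-8, header row with the 12 column names; `NA`
#' percentages (positives under blastn) become empty fields.
#'
#' @param rows A data frame from [build_hsp_table()] (tables from several
#'   queries may be `rbind`ed first).
#' @param path Optional output file; when `NULL` the CSV text is returned.
#' @return The CSV text (invisibly when written to `path`).
#' @export
export_csv <- function(rows, path = NULL) {
  stopifnot(is.data.frame(rows), identical(names(rows), HSP_TABLE_COLS))
  con <- textConnection("csv_out", "w", local = TRUE)
  utils::write.csv(rows, con, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "")
  close(con)
  text <- paste(csv_out, collapse = "\n")
  if (is.null(path)) {
    text
  } else {
    write_atomic(text, path)
    invisible(text)
  }
}

html_head <- function(title) {
  c(
    "<!DOCTYPE html>",
    "<html lang=\"en\">",
    "<head>",
    "<meta charset=\"utf-8\"/>",
    sprintf("<title>%s</title>", xml_escape(title)),
    "<style>",
    "body { font-family: sans-serif; margin: 1.5em; color: #222; }",
    "h1 { font-size: 1.4em; } h2 { font-size: 1.15em; margin-top: 2em; }",
    "table { border-collapse: collapse; font-size: 0.85em; }",
    "th, td { border: 1px solid #ccc; padding: 2px 6px; text-align: right; }",
    "th { background: #f0f0f0; }",
    "td.txt, th.txt { text-align: left; }",
    "pre { font-size: 0.8em; background: #f8f8f8; padding: 6px; ",
    "  overflow-x: auto; }",
    "nav ul { list-style: none; padding-left: 0; }",
    "nav li { display: inline-block; margin-right: 1em; }",
    ".alignment h4 { margin-bottom: 0.2em; }",
    "</style>",
    "</head>",
    "<body>"
  )
}

#' Render a standalone HTML report
#'
#' One self-contained HTML5 document: for every query, the embedded
#' hit-distribution SVG, the HSP attribute table (each row hyperlinked to
#' its alignment block), and the chunked per-residue alignments.  Multi-query
#' files get a query-selector anchor list at the top.
#'
#' @param report A [new_blast_report()] object.
#' @param cfg A [dist_config()] controlling the distribution views.
#' @param chunk_width Columns per alignment chunk.
#' @return The HTML document as one string.
#' @export
render_html_report <- function(report, cfg = dist_config(), chunk_width = 60L) {
  stopifnot(inherits(report, "blast_report"))
  if (!inherits(cfg, "dist_config")) cfg <- do.call(dist_config, cfg)
  title <- sprintf("%s %s vs %s", toupper(report$program), report$version,
                   report$database)
  out <- list()
  put <- function(...) out[[length(out) + 1L]] <<- c(...)
  put(html_head(title))
  put(sprintf("<h1>%s</h1>", xml_escape(title)))

  nq <- length(report$queries)
  if (nq > 1L) {
    put("<nav><ul>")
    for (qi in seq_len(nq)) {
      put(sprintf("<li><a href=\"#query-%d\">%s</a></li>", qi,
                  xml_escape(report$queries[[qi]]$query_id)))
    }
    put("</ul></nav>")
  }

  unit <- if (report$program %in% c("blastn", "blastx", "tblastx")) {
    "nt"
  } else "aa"

  for (qi in seq_len(nq)) {
    qr <- report$queries[[qi]]
    put(sprintf("<section id=\"query-%d\">", qi))
    put(sprintf("<h2>Query %s%s (%d %s)</h2>",
                xml_escape(qr$query_id),
                if (nzchar(qr$query_desc)) {
                  paste0(" &mdash; ", xml_escape(qr$query_desc))
                } else "",
                qr$query_len, unit))

    if (length(qr$hits) == 0L) {
      put("<p><em>No hits found</em></p>")
      put("</section>")
      next
    }

    layout <- layout_distribution(qr, cfg)
    put("<figure>", render_distribution(layout), "</figure>")

    tab <- build_hsp_table(qr)
    put("<table>", "<thead><tr>")
    hdr <- c("hit", "description", "bit score", "E-value", "identity %",
             "positives %", "gaps %", "q. start", "q. end", "s. start",
             "s. end", "alignment")
    txt_col <- c(TRUE, TRUE, rep(FALSE, 10))
    put(paste0(sprintf("<th%s>%s</th>",
                       ifelse(txt_col, " class=\"txt\"", ""),
                       xml_escape(hdr)), collapse = ""))
    put("</tr></thead>", "<tbody>")

    # Recover the (hit row, hsp) structure to number anchors consistently
    # with the table ordering.
    ord <- hit_order(qr$hits)
    row_i <- 0L
    anchors <- character(nrow(tab))
    for (h in seq_along(ord)) {
      hit <- qr$hits[[ord[h]]]
      for (k in seq_along(hit$hsps)) {
        row_i <- row_i + 1L
        anchors[row_i] <- sprintf("aln-q%d-h%d-s%d", qi, h, k)
      }
    }
    for (r in seq_len(nrow(tab))) {
      pos <- if (is.na(tab$pct_positives[r])) "" else tab$pct_positives[r]
      put(sprintf(paste0(
        "<tr><td class=\"txt\">%s</td><td class=\"txt\">%s</td>",
        "<td>%.1f</td><td>%s</td><td>%d</td><td>%s</td><td>%d</td>",
        "<td>%d</td><td>%d</td><td>%d</td><td>%d</td>",
        "<td class=\"txt\"><a href=\"#%s\">view</a></td></tr>"),
        xml_escape(tab$hit_id[r]), xml_escape(tab$description[r]),
        tab$bit_score[r], format_evalue(tab$evalue[r]),
        tab$pct_identity[r], pos, tab$pct_gaps[r],
        tab$q_from[r], tab$q_to[r], tab$s_from[r], tab$s_to[r],
        anchors[r]))
    }
    put("</tbody>", "</table>")

    put("<h3>Alignments</h3>")
    for (h in seq_along(ord)) {
      hit <- qr$hits[[ord[h]]]
      hsps <- hit$hsps[order(-vapply(hit$hsps, `[[`, numeric(1), "bit_score"))]
      for (k in seq_along(hsps)) {
        hsp <- hsps[[k]]
        put(sprintf("<div class=\"alignment\" id=\"aln-q%d-h%d-s%d\">",
                    qi, h, k))
        put(sprintf("<h4>%s %s &mdash; HSP %d: %.1f bits, E = %s</h4>",
                    xml_escape(hit$hit_id), xml_escape(hit$description),
                    k, hsp$bit_score, format_evalue(hsp$evalue)))
        block <- format_alignment(hsp, report$program, chunk_width)
        put("<pre>", xml_escape(paste(block$lines, collapse = "\n")), "</pre>")
        put("</div>")
      }
    }
    put("</section>")
  }

  put("</body>", "</html>")
  paste(unlist(out), collapse = "\n")
}
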