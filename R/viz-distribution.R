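# Hit-distribution graphic: the NCBI-overview-style view of where each hit's
# HSPs fall on the query.  A resolution-independent layout (ruler, legend,
# one row of coloured bars per hit, connectors between consecutive HSPs) is
# computed first; rendering to SVG is a separate, deterministic step.

#' Configuration for the distribution view
#'
#' @param width_px Canvas width in pixels.
#' @param margin_left,margin_right,margin_top,margin_bottom Margins in pixels
#'   (`margin_left` also hosts the per-row hit labels).
#' @param bar_height,bar_gap Bar height and inter-row gap in pixels.
#' @param ruler_height,legend_height Vertical space for ruler and legend.
#' @param max_hits Rows retained (hits beyond this are dropped from the view).
#' @param color_mode `"bits"` or `"evalue"` — which score drives the colour.
#' @param palette Five CSS colours by ascending bin ordinal.
#' @param bits_edges,evalue_edges Bin edges passed to [score_bin()].
#' @return A list of class `dist_config`.
#' @export
dist_config <- function(width_px = 700, margin_left = 90, margin_right = 20,
                        margin_top = 8, margin_bottom = 10,
                        bar_height = 7, bar_gap = 4,
                        ruler_height = 26, legend_height = 24,
                        max_hits = 50L,
                        color_mode = c("bits", "evalue"),
                        palette = c("#000000", "#1f5fbf", "#1fa04a",
                                    "#c03fc0", "#d62728"),
                        bits_edges = DEFAULT_BITS_EDGES,
                        evalue_edges = DEFAULT_EVALUE_EDGES) {
  color_mode <- match.arg(color_mode)
  stopifnot(length(palette) == 5L, width_px > margin_left + margin_right)
  structure(
    list(width_px = width_px, margin_left = margin_left,
         margin_right = margin_right, margin_top = margin_top,
         margin_bottom = margin_bottom, bar_height = bar_height,
         bar_gap = bar_gap, ruler_height = ruler_height,
         legend_height = legend_height, max_hits = as.integer(max_hits),
         color_mode = color_mode, palette = palette,
         bits_edges = bits_edges, evalue_edges = evalue_edges),
    class = "dist_config"
  )
}

# Display order of hits: best bit score first, ties by lowest E-value, then
# input order.
hit_order <- function(hits) {
  if (length(hits) == 0L) return(integer(0))
  max_bit <- vapply(hits, function(h) {
    max(vapply(h$hsps, `[[`, numeric(1), "bit_score"))
  }, numeric(1))
  min_e <- vapply(hits, function(h) {
    min(vapply(h$hsps, `[[`, numeric(1), "evalue"))
  }, numeric(1))
  order(-max_bit, min_e, seq_along(hits))
}

#' Compute the geometry of the hit-distribution graphic
#'
#' Maps every HSP of every retained hit onto pixel coordinates: the bar for
#' an HSP is the image of `[q_from - 1, q_to]` under the linear map from
#' `[0, query_len]` to the drawable x-range.  Consecutive HSP bars of a hit
#' are joined by thin connector segments.  Hits are ordered best-first (max
#' bit score, then min E-value, then input order), at most `max_hits` rows.
#'
#' @param qr A [new_query_result()] object.
#' @param cfg A [dist_config()].
#' @return A list of class `dist_layout` with `canvas`, `ruler`, `legend`
#'   and `rows` components; geometry only, no markup.
#' @export
layout_distribution <- function(qr, cfg = dist_config()) {
  stopifnot(inherits(qr, "blast_query"))
  if (!inherits(cfg, "dist_config")) cfg <- do.call(dist_config, cfg)
  qlen <- qr$query_len
  x0 <- cfg$margin_left
  x1 <- cfg$width_px - cfg$margin_right
  to_px <- function(v) x0 + (v / qlen) * (x1 - x0)

  edges <- if (cfg$color_mode == "bits") cfg$bits_edges else cfg$evalue_edges

  ord <- hit_order(qr$hits)
  ord <- ord[seq_len(min(length(ord), cfg$max_hits))]
  rows_y0 <- cfg$margin_top + cfg$legend_height + cfg$ruler_height
  rows <- vector("list", length(ord))
  for (r in seq_along(ord)) {
    hit <- qr$hits[[ord[r]]]
    y <- rows_y0 + (r - 1) * (cfg$bar_height + cfg$bar_gap)
    bars <- lapply(hit$hsps, function(hsp) {
      list(
        x0_px = to_px(hsp$q_from - 1L),
        x1_px = to_px(hsp$q_to),
        ordinal = score_bin(hsp, cfg$color_mode, edges)$ordinal
      )
    })
    bars <- bars[order(vapply(bars, `[[`, numeric(1), "x0_px"))]
    connectors <- list()
    if (length(bars) > 1L) {
      for (k in seq_len(length(bars) - 1L)) {
        gap_x0 <- bars[[k]]$x1_px
        gap_x1 <- bars[[k + 1L]]$x0_px
        if (gap_x1 > gap_x0) {
          connectors[[length(connectors) + 1L]] <-
            list(x0_px = gap_x0, x1_px = gap_x1)
        }
      }
    }
    rows[[r]] <- list(hit_id = hit$hit_id, y_px = y, bars = bars,
                      connectors = connectors)
  }

  ticks <- pretty(c(0, qlen), n = 8)
  ticks <- unique(c(ticks[ticks >= 0 & ticks <= qlen], qlen))
  height <- rows_y0 + length(rows) * (cfg$bar_height + cfg$bar_gap) +
    cfg$margin_bottom

  structure(
    list(
      query_id = qr$query_id,
      query_len = qlen,
      canvas = list(width_px = cfg$width_px, height_px = height),
      ruler = list(
        y_px = cfg$margin_top + cfg$legend_height + cfg$ruler_height - 6,
        ticks_px = vapply(ticks, to_px, numeric(1)),
        tick_labels = format(ticks, trim = TRUE, scientific = FALSE)
      ),
      legend = list(
        y_px = cfg$margin_top,
        labels = bin_labels(cfg$color_mode, edges),
        colors = cfg$palette,
        title = if (cfg$color_mode == "bits") "Bit score" else "E-value"
      ),
      rows = rows,
      cfg = cfg
    ),
    class = "dist_layout"
  )
}

#' Render a distribution layout as an SVG document
#'
#' Pure text generation: two renders of the same layout are byte-identical.
#' Each HSP bar is a `<rect class="bar">` carrying its bin colour; each hit
#' row is wrapped in a `<g>` with a stable id derived from the hit id, usable
#' as an HTML anchor.
#'
#' @param layout A [layout_distribution()] result.
#' @return A single string containing an SVG 1.1 document.
#' @export
render_distribution <- function(layout) {
  stopifnot(inherits(layout, "dist_layout"))
  cfg <- layout$cfg
  w <- layout$canvas$width_px
  h <- layout$canvas$height_px
  px <- function(v) formatC(v, format = "f", digits = 2, drop0trailing = TRUE)
  out <- list()
  put <- function(...) out[[length(out) + 1L]] <<- c(...)

  put(sprintf(paste0(
    "<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" ",
    "width=\"%s\" height=\"%s\" viewBox=\"0 0 %s %s\">"),
    px(w), px(h), px(w), px(h)))
  put(sprintf(paste0("<rect x=\"0\" y=\"0\" width=\"%s\" height=\"%s\" ",
                     "fill=\"#ffffff\"/>"), px(w), px(h)))

  # legend
  leg <- layout$legend
  lx <- cfg$margin_left
  lw <- (w - cfg$margin_left - cfg$margin_right) / 5
  put(sprintf(paste0("<text x=\"%s\" y=\"%s\" font-size=\"9\" ",
                     "font-family=\"sans-serif\">%s</text>"),
              px(4), px(leg$y_px + 10), xml_escape(leg$title)))
  for (k in 1:5) {
    bx <- lx + (k - 1) * lw
    put(sprintf(paste0(
      "<rect class=\"legend\" x=\"%s\" y=\"%s\" width=\"%s\" height=\"10\" ",
      "fill=\"%s\"/>"), px(bx), px(leg$y_px), px(lw), leg$colors[k]))
    put(sprintf(paste0(
      "<text x=\"%s\" y=\"%s\" font-size=\"8\" font-family=\"sans-serif\" ",
      "text-anchor=\"middle\" fill=\"#ffffff\">%s</text>"),
      px(bx + lw / 2), px(leg$y_px + 8), xml_escape(leg$labels[k])))
  }

  # ruler
  rl <- layout$ruler
  rx0 <- cfg$margin_left
  rx1 <- w - cfg$margin_right
  put(sprintf(paste0("<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" ",
                     "stroke=\"#333333\" stroke-width=\"1\"/>"),
              px(rx0), px(rl$y_px), px(rx1), px(rl$y_px)))
  put(sprintf(paste0("<text x=\"%s\" y=\"%s\" font-size=\"9\" ",
                     "font-family=\"sans-serif\">Query</text>"),
              px(4), px(rl$y_px + 3)))
  for (k in seq_along(rl$ticks_px)) {
    tx <- rl$ticks_px[k]
    put(sprintf(paste0("<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" ",
                       "stroke=\"#333333\" stroke-width=\"1\"/>"),
        px(tx), px(rl$y_px - 4), px(tx), px(rl$y_px)))
    put(sprintf(paste0(
      "<text x=\"%s\" y=\"%s\" font-size=\"8\" font-family=\"sans-serif\" ",
      "text-anchor=\"middle\">%s</text>"),
      px(tx), px(rl$y_px - 7), xml_escape(rl$tick_labels[k])))
  }

  # hit rows
  for (row in layout$rows) {
    gid <- paste0("dist-", sanitize_id(row$hit_id))
    put(sprintf("<g id=\"%s\">", gid))
    put(sprintf(paste0(
      "<text x=\"%s\" y=\"%s\" font-size=\"8\" font-family=\"monospace\" ",
      "text-anchor=\"end\">%s</text>"),
      px(cfg$margin_left - 4), px(row$y_px + cfg$bar_height - 1),
      xml_escape(substr(row$hit_id, 1, 14))))
    for (seg in row$connectors) {
      ymid <- row$y_px + cfg$bar_height / 2
      put(sprintf(paste0(
        "<line class=\"connector\" x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" ",
        "stroke=\"#999999\" stroke-width=\"1\"/>"),
        px(seg$x0_px), px(ymid), px(seg$x1_px), px(ymid)))
    }
    for (k in seq_along(row$bars)) {
      bar <- row$bars[[k]]
      put(sprintf(paste0(
        "<rect class=\"bar\" id=\"%s-b%d\" x=\"%s\" y=\"%s\" width=\"%s\" ",
        "height=\"%s\" fill=\"%s\"/>"),
        gid, k, px(bar$x0_px), px(row$y_px),
        px(max(bar$x1_px - bar$x0_px, 0.5)), px(cfg$bar_height),
        cfg$palette[bar$ordinal + 1L]))
    }
    put("</g>")
  }

  put("</svg>")
  paste(unlist(out), collapse = "\n")
}
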