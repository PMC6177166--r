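# Distribution layout/SVG and the chunked alignment view.

test_that("bar geometry is the linear image of query coordinates", {
  cfg <- dist_config(width_px = 400, margin_left = 0, margin_right = 0)
  # full-span HSP maps to the full canvas
  qr <- new_query_result("q", "", 40L,
                         list(new_hit("h", "", 100L,
                                      list(make_hsp(strrep("A", 40),
                                                    strrep("A", 40))))))
  lay <- layout_distribution(qr, cfg)
  bar <- lay$rows[[1]]$bars[[1]]
  expect_equal(bar$x0_px, 0)
  expect_equal(bar$x1_px, 400)

  # q_from=11, q_to=20 on query_len 40 -> [100, 200]
  h <- make_hsp(strrep("A", 10), strrep("A", 10), q_from = 11L)
  qr2 <- new_query_result("q", "", 40L, list(new_hit("h", "", 40L, list(h))))
  bar2 <- layout_distribution(qr2, cfg)$rows[[1]]$bars[[1]]
  expect_equal(bar2$x0_px, 100)
  expect_equal(bar2$x1_px, 200)
  # per-pixel brute force: every pixel inside the bar maps back into [from-1, to]
  px <- seq(bar2$x0_px, bar2$x1_px, by = 0.5)
  back <- px / 400 * 40
  expect_true(all(back >= 10 & back <= 20))
})

test_that("zero hits yield an empty-row layout that still renders", {
  qr <- new_query_result("q", "", 100L, list())
  lay <- layout_distribution(qr)
  expect_length(lay$rows, 0)
  expect_length(lay$legend$labels, 5)
  svg <- render_distribution(lay)
  doc <- xml2::read_xml(svg)
  expect_identical(xml2::xml_name(doc), "svg")
})

test_that("hit rows are ordered by max bit score, then min evalue, then input", {
  mk <- function(bit, ev) make_hsp("ACDEF", "ACDEF", bit_score = bit, evalue = ev)
  hits <- list(
    new_hit("low", "", 50L, list(mk(30, 1e-3))),
    new_hit("tie_b", "", 50L, list(mk(90, 1e-9))),
    new_hit("best", "", 50L, list(mk(120, 1e-30))),
    new_hit("tie_a", "", 50L, list(mk(90, 1e-12)))
  )
  qr <- new_query_result("q", "", 60L, hits)
  lay <- layout_distribution(qr)
  expect_identical(
    vapply(lay$rows, `[[`, character(1), "hit_id"),
    c("best", "tie_a", "tie_b", "low")
  )
})

test_that("layouts stay inside the canvas and respect max_hits (property)", {
  set.seed(303)
  corpus <- small_corpus(1L, seed_base = 2400L)
  n_checked <- 0L
  for (gt in corpus) {
    for (qr in gt$report$queries) {
      cfg <- dist_config(width_px = sample(300:900, 1),
                         max_hits = sample(1:5, 1))
      lay <- layout_distribution(qr, cfg)
      expect_lte(length(lay$rows), cfg$max_hits)
      for (row in lay$rows) {
        for (bar in row$bars) {
          n_checked <- n_checked + 1L
          expect_gte(bar$x0_px, 0)
          expect_lte(bar$x1_px, lay$canvas$width_px)
          expect_lte(bar$x0_px, bar$x1_px)
          expect_true(bar$ordinal %in% 0:4)
        }
        expect_lte(row$y_px + cfg$bar_height, lay$canvas$height_px)
      }
    }
  }
  expect_gt(n_checked, 20)
})

test_that("rendered SVG is well-formed, deterministic, one rect per bar", {
  gt <- simulate_report(sim_spec(program = "blastp", n_queries = 1,
                                 hits_per_query = c(3, 3),
                                 hsps_per_hit = c(1, 3), seed = 44))
  qr <- gt$report$queries[[1]]
  lay <- layout_distribution(qr)
  svg1 <- render_distribution(lay)
  svg2 <- render_distribution(lay)
  expect_identical(svg1, svg2)
  doc <- xml2::read_xml(svg1)
  bars <- xml2::xml_find_all(doc, "//*[@class='bar']")
  n_bars <- sum(vapply(lay$rows, function(r) length(r$bars), integer(1)))
  expect_length(bars, n_bars)
  # bin colours match the palette by ordinal
  fills <- xml2::xml_attr(bars, "fill")
  expect_true(all(fills %in% lay$cfg$palette))
  # stable ids derived from hit ids
  gids <- xml2::xml_attr(xml2::xml_find_all(doc, "//*[local-name()='g']"), "id")
  expect_true(all(grepl("^dist-", gids)))
})

test_that("format_alignment chunks by ceiling division with aligned midline", {
  qseq <- strrep("ACDEFGHIKLMNP", 10)          # 130 columns
  h <- make_hsp(qseq, qseq)
  block <- format_alignment(h, chunk_width = 60L)
  expect_identical(block$n_chunks, 3L)
  qlines <- grep("^Query", block$lines, value = TRUE)
  widths <- nchar(sub("^Query\\s+\\d+\\s+(\\S+)\\s+\\d+$", "\\1", qlines))
  expect_identical(widths, c(60L, 60L, 10L))
  # midline is vertically aligned under the sequence columns
  qpos <- regexpr("[A-Z-]+\\s+\\d+$", qlines[1])
  mid <- block$lines[2]
  expect_identical(substr(mid, qpos, qpos + 59), substr(qseq, 1, 60))
})

test_that("translated query coordinates advance 3 nucleotides per column", {
  qseq <- strrep("ACDEFGHIKLMNPQRSTVWY", 3)     # 60 residues, no gaps
  h <- make_hsp(qseq, qseq, program = "blastx", q_from = 10L, q_frame = 2L)
  block <- format_alignment(h, chunk_width = 60L)
  m <- regmatches(block$lines[1],
                  regexec("^Query\\s+(\\d+)\\s+\\S+\\s+(\\d+)$", block$lines[1]))[[1]]
  expect_identical(as.integer(m[2]), 10L)
  expect_identical(as.integer(m[3]), 10L + 3L * 60L - 1L)
})

test_that("minus-strand subject labels are strictly decreasing", {
  qseq <- strrep("ACGT", 40)                    # 160 columns, 3 chunks
  h <- make_hsp(qseq, qseq, program = "blastn", s_from = 100L,
                s_strand = "minus")
  block <- format_alignment(h, chunk_width = 60L)
  slines <- grep("^Sbjct", block$lines, value = TRUE)
  labs <- as.integer(unlist(regmatches(slines, gregexpr("\\d+", slines))))
  expect_true(all(diff(labs) < 0))
  expect_identical(labs[1], h$s_to)
  expect_identical(labs[length(labs)], h$s_from)
})

test_that("reassembling chunks reproduces qseq/hseq/midline byte-exactly", {
  for (gt in small_corpus(1L, seed_base = 3100L)) {
    for (hsp in all_hsps(gt$report)) {
      block <- format_alignment(hsp, chunk_width = 60L)
      qs <- paste(sub("^Query\\s+\\d+\\s+(\\S+)\\s+\\d+$", "\\1",
                      grep("^Query", block$lines, value = TRUE)), collapse = "")
      ss <- paste(sub("^Sbjct\\s+\\d+\\s+(\\S+)\\s+\\d+$", "\\1",
                      grep("^Sbjct", block$lines, value = TRUE)), collapse = "")
      expect_identical(qs, hsp$qseq)
      expect_identical(ss, hsp$hseq)
    }
  }
})
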