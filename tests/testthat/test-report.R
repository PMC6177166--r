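# HSP table, CSV export and the standalone HTML report.

test_that("build_hsp_table emits one row per HSP in display order", {
  mk <- function(bit) make_hsp("ACDEF", "ACDEF", bit_score = bit,
                               evalue = 2^(-bit))
  hits <- list(
    new_hit("h1", "one hsp", 50L, list(mk(40))),
    new_hit("h2", "two hsps", 50L, list(mk(60), mk(90))),
    new_hit("h3", "one hsp", 50L, list(mk(30)))
  )
  qr <- new_query_result("q", "", 60L, hits)
  tab <- build_hsp_table(qr)
  expect_identical(nrow(tab), 4L)
  expect_identical(names(tab), blastvista:::HSP_TABLE_COLS)
  # hits best-first, HSPs within hit by descending bit score
  expect_identical(tab$hit_id, c("h2", "h2", "h1", "h3"))
  expect_identical(tab$bit_score, c(90, 60, 40, 30))
})

test_that("empty query gives a header-only table and CSV", {
  qr <- new_query_result("q", "", 60L, list())
  tab <- build_hsp_table(qr)
  expect_identical(nrow(tab), 0L)
  csv <- export_csv(tab)
  expect_identical(csv, paste0("\"", paste(blastvista:::HSP_TABLE_COLS,
                                           collapse = "\",\""), "\""))
})

test_that("table rows agree with generator ground truth", {
  gt <- simulate_report(sim_spec(program = "blastp", n_queries = 3,
                                 hits_per_query = c(1, 3), seed = 55))
  total <- 0L
  for (qr in gt$report$queries) {
    tab <- build_hsp_table(qr)
    total <- total + nrow(tab)
    for (r in seq_len(nrow(tab))) {
      key <- gt$truth[gt$truth$query_id == tab$query_id[r] &
                        gt$truth$hit_id == tab$hit_id[r] &
                        gt$truth$bit_score == tab$bit_score[r] &
                        gt$truth$evalue == tab$evalue[r], ]
      expect_gte(nrow(key), 1L)
      ok <- any(
        tab$pct_identity[r] ==
          as.integer(floor(100 * key$identities / key$align_len + 0.5)) &
        tab$pct_gaps[r] ==
          as.integer(floor(100 * key$gap_count / key$align_len + 0.5))
      )
      expect_true(ok)
    }
  }
  expect_identical(total, nrow(gt$truth))
})

test_that("CSV is RFC 4180: commas quoted, round-trip lossless", {
  h <- make_hsp("ACDEF", "ACDEF")
  hit <- new_hit("h1", "putative transporter, partial \"x\"", 50L, list(h))
  qr <- new_query_result("q", "", 60L, list(hit))
  tab <- build_hsp_table(qr)
  csv <- export_csv(tab)
  expect_match(csv, "\"putative transporter, partial \"\"x\"\"\"", fixed = TRUE)
  back <- utils::read.csv(text = csv, stringsAsFactors = FALSE)
  expect_identical(back$description, tab$description)
  expect_identical(back$q_from, tab$q_from)
  expect_equal(back$bit_score, tab$bit_score)

  # blastn positives stay empty fields
  hn <- make_hsp("ACGT", "ACGT", program = "blastn")
  qn <- new_query_result("q", "", 10L, list(new_hit("h", "", 10L, list(hn))))
  csvn <- export_csv(build_hsp_table(qn))
  expect_match(strsplit(csvn, "\n")[[1]][2], ",,")
})

test_that("export_csv writes files atomically", {
  tab <- build_hsp_table(new_query_result("q", "", 60L, list()))
  path <- withr::local_tempfile(fileext = ".csv")
  export_csv(tab, path)
  expect_true(file.exists(path))
  expect_length(readLines(path), 1)
})

test_that("HTML report has one section and selector anchor per query", {
  gt <- simulate_report(sim_spec(program = "blastp", n_queries = 10,
                                 hits_per_query = c(0, 2), seed = 66))
  html <- render_html_report(gt$report)
  doc <- xml2::read_html(html)
  sections <- xml2::xml_find_all(doc, "//section")
  expect_length(sections, 10)
  nav <- xml2::xml_find_all(doc, "//nav//a")
  expect_length(nav, 10)
  nav_targets <- sub("^#", "", xml2::xml_attr(nav, "href"))
  ids <- xml2::xml_attr(xml2::xml_find_all(doc, "//*[@id]"), "id")
  expect_true(all(nav_targets %in% ids))
})

test_that("every table-row anchor target exists in the document", {
  gt <- simulate_report(sim_spec(program = "tblastn", n_queries = 3,
                                 hits_per_query = c(1, 3),
                                 hsps_per_hit = c(1, 2), seed = 88))
  html <- render_html_report(gt$report)
  doc <- xml2::read_html(html)
  hrefs <- xml2::xml_attr(
    xml2::xml_find_all(doc, "//table//a[starts-with(@href, '#aln-')]"), "href"
  )
  n_hsps <- length(all_hsps(gt$report))
  expect_length(hrefs, n_hsps)
  ids <- xml2::xml_attr(xml2::xml_find_all(doc, "//div[@class='alignment']"), "id")
  expect_setequal(sub("^#", "", hrefs), ids)
  # documented anchor naming contract
  expect_true(all(grepl("^aln-q\\d+-h\\d+-s\\d+$", ids)))
})

test_that("HTML embeds one SVG per non-empty query and marks empty ones", {
  gt <- simulate_report(sim_spec(program = "blastn", n_queries = 4,
                                 hits_per_query = c(0, 0), seed = 99))
  html <- render_html_report(gt$report)
  expect_identical(length(gregexpr("No hits found", html)[[1]]), 4L)
  gt2 <- simulate_report(sim_spec(program = "blastn", n_queries = 2,
                                  hits_per_query = c(1, 2), seed = 100))
  html2 <- render_html_report(gt2$report)
  doc <- xml2::read_html(html2)
  expect_length(xml2::xml_find_all(doc, "//*[local-name()='svg']"), 2)
})
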