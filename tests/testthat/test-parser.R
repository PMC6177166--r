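# Format detection and both parsers, against hand-parsed literals and the
# simulator's round-trip oracle.

GRAMMAR_EXAMPLE <- paste(c(
  "BLASTP 2.6.0+",
  "",
  "Database: toy_db",
  "",
  "Query= q1 toy query",
  "",
  "Length=30",
  "",
  "Sequences producing significant alignments:",
  "",
  "  s1 toy subject                                                      52  6.2e-10",
  "",
  "",
  "> s1 toy subject",
  "Length=40",
  "",
  " Score = 52.4 bits (124),  Expect = 6.2e-10",
  " Identities = 24/26 (92%), Positives = 25/26 (96%), Gaps = 0/26 (0%)",
  "",
  "Query   3  MKTAYIAKQRQISFVKSHFSRQLEER  28",
  "           MKTAYIAKQRQISFVKSHFSRQ+E R",
  "Sbjct   5  MKTAYIAKQRQISFVKSHFSRQIEGR  30",
  "",
  "Lambda      K        H",
  "   0.267   0.0410    0.140"
), collapse = "\n")

test_that("detect_format applies the program-token and XML-root rules", {
  expect_identical(detect_format("BLASTP 2.6.0+\nDatabase: x\n"), "pairwise_text")
  expect_identical(detect_format("  tblastx 2.12.0+\n"), "pairwise_text")
  expect_identical(
    detect_format("<?xml version=\"1.0\"?>\n<BlastOutput></BlastOutput>"),
    "blast_xml"
  )
  expect_identical(detect_format("<BlastOutput>\n</BlastOutput>"), "blast_xml")
  expect_error(
    detect_format("Sequences producing significant alignments:\n"),
    class = "unrecognised_format"
  )
  expect_error(detect_format("   \n  \n"), class = "unrecognised_format")
  # JSON output is out of scope and must be rejected, not half-parsed
  expect_error(detect_format("{\"BlastOutput2\": []}"),
               class = "unrecognised_format")
})

test_that("the worked grammar example parses field-for-field", {
  res <- parse_pairwise_text(GRAMMAR_EXAMPLE, "strict")
  expect_length(res$issues, 0)
  rep <- res$report
  expect_identical(rep$program, "blastp")
  expect_identical(rep$version, "2.6.0+")
  expect_identical(rep$database, "toy_db")
  expect_equal(rep$footer_stats, list(lambda = 0.267, k = 0.041, h = 0.14))
  expect_length(rep$queries, 1)

  qr <- rep$queries[[1]]
  expect_identical(qr$query_id, "q1")
  expect_identical(qr$query_desc, "toy query")
  expect_identical(qr$query_len, 30L)
  expect_length(qr$hits, 1)

  hit <- qr$hits[[1]]
  expect_identical(hit$hit_id, "s1")
  expect_identical(hit$description, "toy subject")
  expect_identical(hit$subject_len, 40L)
  expect_length(hit$hsps, 1)

  hsp <- hit$hsps[[1]]
  expect_equal(hsp$bit_score, 52.4)
  expect_identical(hsp$raw_score, 124L)
  expect_equal(hsp$evalue, 6.2e-10)
  expect_identical(hsp$align_len, 26L)
  expect_identical(hsp$identities, 24L)
  expect_identical(hsp$positives, 25L)
  expect_identical(hsp$gap_count, 0L)
  expect_identical(c(hsp$q_from, hsp$q_to), c(3L, 28L))
  expect_identical(c(hsp$s_from, hsp$s_to), c(5L, 30L))
  expect_identical(hsp$qseq, "MKTAYIAKQRQISFVKSHFSRQLEER")
  expect_identical(hsp$hseq, "MKTAYIAKQRQISFVKSHFSRQIEGR")
  expect_identical(hsp$midline, "MKTAYIAKQRQISFVKSHFSRQ+E R")
  expect_identical(hsp$q_strand, "n/a")
  expect_true(is.na(hsp$q_frame))
})

test_that("'No hits found' yields one query with empty hits and no issues", {
  rep0 <- make_report(list(make_hsp("ACDEF", "ACDEF")))
  rep0$queries[[1]]$hits <- list()
  txt <- serialize_pairwise_text(rep0)
  expect_match(txt, "No hits found")
  res <- parse_pairwise_text(txt, "strict")
  expect_length(res$issues, 0)
  expect_length(res$report$queries, 1)
  expect_length(res$report$queries[[1]]$hits, 0)
})

test_that("multi-query files produce one QueryResult per section, in order", {
  r1 <- make_report(list(make_hsp("ACDEFGHIKL", "ACDEFGHIKL")), query_id = "qA")
  r2 <- make_report(list(make_hsp("MNPQRSTVWY", "MNPQRSTVWY")), query_id = "qB")
  r1$queries <- c(r1$queries, r2$queries)
  res <- parse_pairwise_text(serialize_pairwise_text(r1), "strict")
  expect_identical(
    vapply(res$report$queries, `[[`, character(1), "query_id"),
    c("qA", "qB")
  )
})

test_that("minus-strand blastn subjects print descending and normalise back", {
  hsp <- make_hsp("ACGTACGTACGT", "ACGTACGAACGT", program = "blastn",
                  q_from = 11L, s_from = 21L, s_strand = "minus")
  rep <- make_report(list(hsp))
  txt <- serialize_pairwise_text(rep)
  expect_match(txt, "Strand=Plus/Minus")
  # the printed subject coordinates descend
  m <- regmatches(txt, regexec("Sbjct\\s+(\\d+)\\s+\\S+\\s+(\\d+)", txt))[[1]]
  expect_gt(as.integer(m[2]), as.integer(m[3]))
  parsed <- parse_pairwise_text(txt, "strict")$report$queries[[1]]$hits[[1]]$hsps[[1]]
  expect_identical(parsed$s_strand, "minus")
  expect_lt(parsed$s_from, parsed$s_to)
  expect_identical(c(parsed$s_from, parsed$s_to), c(hsp$s_from, hsp$s_to))
})

test_that("alignments printed at width 60 and width 80 parse identically", {
  gt <- simulate_report(sim_spec(program = "blastx", n_queries = 2,
                                 query_len = c(200, 400), seed = 91))
  t60 <- serialize_pairwise_text(gt$report, chunk_width = 60L)
  t80 <- serialize_pairwise_text(gt$report, chunk_width = 80L)
  expect_false(identical(t60, t80))
  r60 <- parse_pairwise_text(t60, "strict")$report
  r80 <- parse_pairwise_text(t80, "strict")$report
  expect_length(compare_reports(r60, r80), 0)
})

test_that("strict mode errors on truncated and corrupted HSP blocks", {
  rep <- make_report(list(make_hsp(strrep("ACDEF", 20), strrep("ACDEF", 20))))
  txt <- serialize_pairwise_text(rep)
  lines <- strsplit(txt, "\n")[[1]]
  # truncate mid-alignment
  cut <- grep("^Sbjct", lines)[1]
  truncated <- paste(lines[seq_len(cut - 1)], collapse = "\n")
  expect_error(parse_pairwise_text(truncated, "strict"),
               class = "malformed_input")
  # corrupt a chunk coordinate label
  bad <- sub("^(Query\\s+)(\\d+)", "\\19999", lines[grep("^Query\\s+\\d", lines)[2]])
  lines2 <- lines
  lines2[grep("^Query\\s+\\d", lines)[2]] <- bad
  expect_error(parse_pairwise_text(paste(lines2, collapse = "\n"), "strict"),
               class = "malformed_input")
})

test_that("lenient mode drops malformed HSPs with an issue, never repairs", {
  h1 <- make_hsp(strrep("ACDEF", 20), strrep("ACDEF", 20))
  h2 <- make_hsp("MNPQRSTVWY", "MNPQRSTVWY")
  rep <- make_report(list(h1, h2))
  txt <- serialize_pairwise_text(rep)
  lines <- strsplit(txt, "\n")[[1]]
  qlines <- grep("^Query\\s+\\d", lines)
  lines[qlines[2]] <- sub("^(Query\\s+)(\\d+)", "\\19999", lines[qlines[2]])
  res <- parse_pairwise_text(paste(lines, collapse = "\n"), "lenient")
  sev <- vapply(res$issues, `[[`, character(1), "severity")
  expect_true(any(sev == "error"))
  # first hit lost its only HSP and was dropped; second hit survives intact
  hits <- res$report$queries[[1]]$hits
  expect_length(hits, 1)
  expect_identical(hits[[1]]$hsps[[1]]$qseq, "MNPQRSTVWY")
  expect_length(validate_blast_report(res$report), 0)
  # the dropped detail section is also flagged by the summary cross-check
  expect_true(any(grepl("summary table", vapply(res$issues, `[[`,
                                                character(1), "message"))))
})

test_that("XML round-trips preserve every field and optional ones stay absent", {
  gtn <- simulate_report(sim_spec(program = "blastn", n_queries = 2,
                                  hits_per_query = c(0, 2), seed = 77))
  res <- parse_blast_xml(gtn$xml, "strict")
  expect_length(res$issues, 0)
  expect_length(compare_reports(gtn$report, res$report), 0)
  for (hsp in all_hsps(res$report)) {
    expect_true(is.na(hsp$positives))       # blastn has no positives
    expect_true(hsp$s_strand %in% c("plus", "minus"))
  }
  expect_false(grepl("Hsp_positive", gtn$xml, fixed = TRUE))
})

test_that("XML missing a mandatory element is malformed (strict) or dropped (lenient)", {
  gt <- simulate_report(sim_spec(program = "blastp", n_queries = 1,
                                 hits_per_query = c(2, 2),
                                 hsps_per_hit = c(1, 1), seed = 5))
  broken <- sub("<Hsp_qseq>[^<]*</Hsp_qseq>", "", gt$xml)
  expect_error(parse_blast_xml(broken, "strict"), class = "malformed_input")
  res <- parse_blast_xml(broken, "lenient")
  expect_true(any(vapply(res$issues, `[[`, character(1), "severity") == "error"))
  n_hsps <- length(all_hsps(res$report))
  expect_identical(n_hsps, length(all_hsps(gt$report)) - 1L)
})

test_that("text and XML renderings of the same report agree on all integer fields", {
  for (p in c("blastp", "tblastx")) {
    gt <- simulate_report(sim_spec(program = p, n_queries = 2, seed = 33))
    rt <- parse_pairwise_text(gt$text, "strict")$report
    rx <- parse_blast_xml(gt$xml, "strict")$report
    expect_length(compare_reports(rt, rx), 0)
  }
})

test_that("parse_report accepts a path, a connection and a string", {
  gt <- simulate_report(sim_spec(seed = 12))
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(gt$text, path)
  from_path <- parse_report(path)$report
  con <- file(path, open = "r")
  from_con <- parse_report(con)$report
  close(con)
  from_string <- parse_report(gt$text)$report
  expect_length(compare_reports(from_path, from_con), 0)
  expect_length(compare_reports(from_path, from_string), 0)
})

test_that("every parsed report from the corpus satisfies all type invariants", {
  for (gt in small_corpus(2L, seed_base = 900L)) {
    rep <- parse_report(gt$text)$report
    expect_length(validate_blast_report(rep), 0)
    rep2 <- parse_report(gt$xml)$report
    expect_length(validate_blast_report(rep2), 0)
  }
})
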