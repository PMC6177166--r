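# Shared helpers: independent brute-force oracles and small fixture builders.

# Column-by-column recount of identities/positives/gaps, independent of the
# package's vectorised implementation.
brute_stats <- function(qseq, hseq, midline, program) {
  qc <- strsplit(toupper(qseq), "")[[1]]
  hc <- strsplit(toupper(hseq), "")[[1]]
  mc <- strsplit(midline, "")[[1]]
  ident <- 0L; gaps <- 0L; pos <- 0L
  for (i in seq_along(qc)) {
    if (qc[i] == "-") gaps <- gaps + 1L
    if (hc[i] == "-") gaps <- gaps + 1L
    if (qc[i] != "-" && qc[i] == hc[i]) ident <- ident + 1L
    if (mc[i] != " ") pos <- pos + 1L
  }
  list(
    identities = ident,
    gap_count = gaps,
    positives = if (program == "blastn") NA_integer_ else pos
  )
}

# Per-position marking oracle for interval-union coverage.
brute_coverage <- function(froms, tos, query_len) {
  covered <- logical(query_len)
  for (i in seq_along(froms)) covered[froms[i]:tos[i]] <- TRUE
  sum(covered) / query_len
}

# Build a fully consistent HSP from aligned strings alone: counts, midline
# and coordinate spans are all derived, so data-model invariants hold by
# construction.
make_hsp <- function(qseq, hseq, program = "blastp",
                     q_from = 1L, s_from = 1L,
                     q_strand = if (program == "blastn") "plus" else "n/a",
                     s_strand = if (program == "blastn") "plus" else "n/a",
                     q_frame = NA_integer_, s_frame = NA_integer_,
                     bit_score = 50, evalue = 1e-6, raw_score = 110L) {
  if (program %in% c("blastx", "tblastx") && is.na(q_frame)) q_frame <- 1L
  if (program %in% c("tblastn", "tblastx") && is.na(s_frame)) s_frame <- 1L
  midline <- blastvista:::compute_midline(
    strsplit(qseq, "")[[1]], strsplit(hseq, "")[[1]], program
  )
  st <- brute_stats(qseq, hseq, midline, program)
  steps <- blastvista:::step_factors(program)
  L <- nchar(qseq)
  gq <- lengths(regmatches(qseq, gregexpr("-", qseq)))
  gh <- lengths(regmatches(hseq, gregexpr("-", hseq)))
  new_hsp(
    program = program, bit_score = bit_score, evalue = evalue,
    raw_score = raw_score, align_len = L,
    identities = st$identities, positives = st$positives,
    gap_count = st$gap_count,
    q_from = q_from, q_to = q_from + steps[["q"]] * (L - gq) - 1L,
    s_from = s_from, s_to = s_from + steps[["s"]] * (L - gh) - 1L,
    qseq = qseq, hseq = hseq, midline = midline,
    q_strand = q_strand, s_strand = s_strand,
    q_frame = q_frame, s_frame = s_frame
  )
}

# Wrap HSPs into a one-query report ready for serialization.
make_report <- function(hsps, program = hsps[[1]]$program,
                        query_id = "q1", query_desc = "test query",
                        query_len = NULL, footer = TRUE) {
  if (is.null(query_len)) {
    query_len <- max(vapply(hsps, `[[`, integer(1), "q_to")) + 5L
  }
  hits <- lapply(seq_along(hsps), function(i) {
    new_hit(sprintf("s%d", i), sprintf("subject %d", i),
            hsps[[i]]$s_to + 10L, hsps[i])
  })
  new_blast_report(
    program, "2.6.0+", "toy_db",
    list(new_query_result(query_id, query_desc, query_len, hits)),
    footer_stats = if (footer) list(lambda = 0.267, k = 0.041, h = 0.14)
  )
}

# Pool every HSP of a ground-truth (or parsed) report into a flat list.
all_hsps <- function(report) {
  out <- list()
  for (qr in report$queries) {
    for (hit in qr$hits) out <- c(out, hit$hsps)
  }
  out
}

# Small multi-program corpus shared by several test files (seeded, cheap).
small_corpus <- function(n_per_program = 3L, seed_base = 500L) {
  out <- list()
  for (p in c("blastp", "blastn", "blastx", "tblastn", "tblastx")) {
    for (s in seq_len(n_per_program)) {
      out[[length(out) + 1L]] <- simulate_report(sim_spec(
        program = p, n_queries = 2L, hits_per_query = c(0L, 3L),
        hsps_per_hit = c(1L, 2L), query_len = c(60L, 200L),
        seed = seed_base + 17L * s
      ))
    }
  }
  out
}
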