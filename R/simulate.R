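# Synthetic BLAST-output generator.  Builds reports with known ground-truth
# statistics and serializes them to both pairwise text and XML, so every
# parser/metrics/viz test has an oracle without ever running BLAST.
#
# Scores are deliberately not Karlin-Altschul-correct: the bit score is a
# fixed decreasing function of mismatches + gaps and the E-value is
# 2^(-bits) * 1e6, which preserves every ordering the viewer relies on.

# Similarity classes granting a '+' midline mark between non-identical
# protein residues: {ILVM} {FWY} {KRH} {DE} {ST} {NQ}.
PROT_SIM_CLASS <- c(
  I = 1L, L = 1L, V = 1L, M = 1L,
  F = 2L, W = 2L, Y = 2L,
  K = 3L, R = 3L, H = 3L,
  D = 4L, E = 4L,
  S = 5L, T = 5L,
  N = 6L, Q = 6L
)

# Midline for aligned character vectors: identity mark ('|' for blastn, the
# residue letter otherwise), '+' for same-class protein pairs, ' ' otherwise.
compute_midline <- function(qc, hc, program) {
  out <- rep(" ", length(qc))
  ident <- qc == hc & qc != "-"
  out[ident] <- if (program == "blastn") "|" else qc[ident]
  if (program != "blastn") {
    cq <- PROT_SIM_CLASS[qc]
    ch <- PROT_SIM_CLASS[hc]
    plus <- !ident & !is.na(cq) & !is.na(ch) & cq == ch & qc != "-" & hc != "-"
    out[plus] <- "+"
  }
  paste(out, collapse = "")
}

#' Specify a synthetic BLAST report simulation
#'
#' @param program BLAST program to emulate.
#' @param n_queries Number of queries (>= 1).
#' @param hits_per_query,hsps_per_hit Inclusive integer ranges `c(lo, hi)`
#'   (or single values); `hits_per_query` may include 0 to produce
#'   "No hits found" queries.
#' @param query_len Inclusive range of query lengths (residues or bases).
#' @param substitution_rate Per-column probability of a substitution.
#' @param gap_open_rate Per-column probability of opening a gap.
#' @param mean_gap_len Mean gap length (geometric, >= 1).
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return A validated list of class `sim_spec`.
#' @export
sim_spec <- function(program = "blastp", n_queries = 1L,
                     hits_per_query = c(1L, 3L), hsps_per_hit = c(1L, 2L),
                     query_len = c(80L, 300L), substitution_rate = 0.1,
                     gap_open_rate = 0.03, mean_gap_len = 2, seed = 1L) {
  spec <- structure(
    list(
      program = program, n_queries = n_queries,
      hits_per_query = hits_per_query, hsps_per_hit = hsps_per_hit,
      query_len = query_len, substitution_rate = substitution_rate,
      gap_open_rate = gap_open_rate, mean_gap_len = mean_gap_len,
      seed = as.integer(seed)
    ),
    class = "sim_spec"
  )
  validate_sim_spec(spec)
  spec
}

validate_sim_spec <- function(spec) {
  ok_range <- function(r, lo_min) {
    length(r) %in% c(1L, 2L) && !anyNA(r) && all(r >= lo_min) &&
      (length(r) == 1L || r[1] <= r[2])
  }
  if (!is.character(spec$program) || length(spec$program) != 1L ||
      !spec$program %in% BLAST_PROGRAMS) {
    abort_invalid_spec("program must be one of blastp/blastn/blastx/tblastn/tblastx")
  }
  if (!ok_range(spec$n_queries, 1)) abort_invalid_spec("n_queries must be >= 1")
  if (!ok_range(spec$hits_per_query, 0)) {
    abort_invalid_spec("hits_per_query must be a non-negative range")
  }
  if (!ok_range(spec$hsps_per_hit, 1)) {
    abort_invalid_spec("hsps_per_hit must be a positive range")
  }
  if (!ok_range(spec$query_len, 30)) {
    abort_invalid_spec("query_len must be a range with minimum >= 30")
  }
  for (rate in c("substitution_rate", "gap_open_rate")) {
    v <- spec[[rate]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      abort_invalid_spec(paste(rate, "must be a probability in [0, 1]"))
    }
  }
  if (!is.numeric(spec$mean_gap_len) || spec$mean_gap_len < 1) {
    abort_invalid_spec("mean_gap_len must be >= 1")
  }
  if (is.na(spec$seed)) abort_invalid_spec("seed must be an integer")
  invisible(spec)
}

# One simulated HSP: aligned columns plus consistent coordinates and scores.
simulate_hsp <- function(spec, program, query_len, steps) {
  alphabet <- alignment_alphabet(program)
  max_q_res <- query_len %/% steps[["q"]]
  n_q <- sample_range(c(10L, min(80L, max_q_res)))
  qres <- sample(alphabet, n_q, replace = TRUE)

  qc <- character(0)
  hc <- character(0)
  k <- 1L
  gap_len <- function() min(5L, 1L + stats::rgeom(1L, 1 / spec$mean_gap_len))
  while (k <= n_q) {
    if (k > 1L && k < n_q && stats::runif(1) < spec$gap_open_rate) {
      g <- gap_len()
      if (stats::runif(1) < 0.5) {
        # insertion in subject: gap columns in the query string
        qc <- c(qc, rep("-", g))
        hc <- c(hc, sample(alphabet, g, replace = TRUE))
      } else {
        # deletion in subject: consume query residues against subject gaps
        g <- min(g, n_q - k)   # keep the final column residue-bearing
        if (g > 0L) {
          qc <- c(qc, qres[k:(k + g - 1L)])
          hc <- c(hc, rep("-", g))
          k <- k + g
        }
      }
    }
    sub <- stats::runif(1) < spec$substitution_rate
    qc <- c(qc, qres[k])
    hc <- c(hc, if (sub) sample(setdiff(alphabet, qres[k]), 1L) else qres[k])
    k <- k + 1L
  }

  L <- length(qc)
  midline <- compute_midline(qc, hc, program)
  gq <- sum(qc == "-")
  gh <- sum(hc == "-")
  identities <- sum(qc == hc & qc != "-")
  positives <- if (program == "blastn") NA_integer_ else {
    sum(strsplit(midline, "", fixed = TRUE)[[1]] != " ")
  }

  mismatches <- (L - gq - gh) - identities
  gapcols <- gq + gh
  matches <- identities
  bit <- round(1.9 * matches - 1.1 * mismatches - 2.3 * gapcols + 24, 1)
  if (bit < 0.1) bit <- 0.1
  evalue <- signif(2^(-bit) * 1e6, 2)

  q_span <- steps[["q"]] * (L - gq)
  q_from <- sample_range(c(1L, query_len - q_span + 1L))
  s_nongap <- L - gh
  s_span <- steps[["s"]] * s_nongap
  s_from <- sample_range(c(1L, 150L))

  q_strand <- "n/a"; s_strand <- "n/a"
  q_frame <- NA_integer_; s_frame <- NA_integer_
  frames <- c(-3L, -2L, -1L, 1L, 2L, 3L)
  if (program == "blastn") {
    q_strand <- "plus"
    s_strand <- sample(c("plus", "minus"), 1L)
  }
  if (program %in% c("blastx", "tblastx")) q_frame <- sample(frames, 1L)
  if (program %in% c("tblastn", "tblastx")) s_frame <- sample(frames, 1L)

  new_hsp(
    program = program,
    bit_score = bit, raw_score = as.integer(round(bit * 2.19)),
    evalue = evalue, align_len = L,
    identities = identities, positives = positives, gap_count = gapcols,
    q_from = q_from, q_to = q_from + q_span - 1L,
    s_from = s_from, s_to = s_from + s_span - 1L,
    qseq = paste(qc, collapse = ""), hseq = paste(hc, collapse = ""),
    midline = midline,
    q_strand = q_strand, s_strand = s_strand,
    q_frame = q_frame, s_frame = s_frame
  )
}

DESC_VOCAB <- c(
  "hypothetical protein",
  "putative membrane transporter, partial",
  "DNA-directed RNA polymerase subunit",
  "ABC transporter ATP-binding protein",
  "elongation factor Tu",
  "cold-shock protein",
  ""
)

#' Simulate a BLAST report with retained ground truth
#'
#' Draws queries, hits and HSPs per the [sim_spec()]: each HSP copies a query window,
#' applies substitutions and gaps at the stated rates, computes the midline
#' (identity marks; `+` for protein residue pairs in the same similarity
#' class) and all counts and coordinates so that every data-model invariant
#' holds.  The result is serialized to both supported formats and, as a
#' generation-time self-check, both serializations are re-parsed and compared
#' against the in-memory report.
#'
#' @param spec A [sim_spec()] object.
#' @return A list of class `blast_ground_truth` with elements `report` (the
#'   `blast_report`), `truth` (a data frame of true per-HSP counts), `text`
#'   and `xml` (the serializations), and `spec`.
#' @export
#' @examples
#' gt <- simulate_report(sim_spec(n_queries = 2, seed = 42))
#' gt$report
simulate_report <- function(spec) {
  validate_sim_spec(spec)
  program <- spec$program
  steps <- step_factors(program)

  with_local_seed(spec$seed, {
    queries <- vector("list", spec$n_queries)
    truth <- list()
    for (qi in seq_len(spec$n_queries)) {
      query_len <- sample_range(spec$query_len)
      query_id <- sprintf("query_%04d", qi)
      query_desc <- sample(DESC_VOCAB, 1L)
      n_hits <- sample_range(spec$hits_per_query)
      hits <- vector("list", n_hits)
      for (hi in seq_len(n_hits)) {
        n_hsps <- sample_range(spec$hsps_per_hit)
        hsps <- lapply(seq_len(n_hsps), function(k) {
          simulate_hsp(spec, program, query_len, steps)
        })
        bits <- vapply(hsps, `[[`, numeric(1), "bit_score")
        hsps <- hsps[order(-bits)]
        s_len <- max(vapply(hsps, `[[`, integer(1), "s_to")) +
          sample_range(c(0L, 50L))
        hit_id <- sprintf("sbj_%04d_%02d", qi, hi)
        hits[[hi]] <- new_hit(hit_id, sample(DESC_VOCAB, 1L), s_len, hsps)
        for (k in seq_along(hsps)) {
          h <- hsps[[k]]
          truth[[length(truth) + 1L]] <- data.frame(
            query_id = query_id, hit_id = hit_id, hsp = k,
            identities = h$identities, positives = h$positives,
            gap_count = h$gap_count, align_len = h$align_len,
            bit_score = h$bit_score, evalue = h$evalue,
            stringsAsFactors = FALSE
          )
        }
      }
      queries[[qi]] <- new_query_result(query_id, query_desc, query_len, hits)
    }

    report <- new_blast_report(
      program, "2.6.0+", "synthetic_db", queries,
      footer_stats = list(lambda = 0.267, k = 0.041, h = 0.14)
    )
    problems <- validate_blast_report(report)
    if (length(problems)) {
      stop("internal simulator error, invalid report generated: ",
           paste(problems, collapse = "; "))
    }

    text <- serialize_pairwise_text(report)
    xml <- serialize_xml(report)

    # Generation-time self-check: both serializations must re-parse to the
    # stored report.
    rt_text <- parse_pairwise_text(text, "strict")
    rt_xml <- parse_blast_xml(xml, "strict")
    d1 <- compare_reports(report, rt_text$report)
    d2 <- compare_reports(report, rt_xml$report)
    if (length(d1) || length(d2)) {
      stop("simulator self-check failed: ",
           paste(c(d1, d2), collapse = "; "))
    }

    truth_df <- if (length(truth)) {
      do.call(rbind, truth)
    } else {
      data.frame(
        query_id = character(), hit_id = character(), hsp = integer(),
        identities = integer(), positives = integer(), gap_count = integer(),
        align_len = integer(), bit_score = numeric(), evalue = numeric(),
        stringsAsFactors = FALSE
      )
    }
    structure(
      list(report = report, truth = truth_df, text = text, xml = xml,
           spec = spec),
      class = "blast_ground_truth"
    )
  })
}

#' Field-by-field comparison of two reports
#'
#' Integer and string fields must match exactly; bit scores within 0.05 bits
#' and E-values within one significant figure of each other (the precision
#' the text format prints).
#'
#' @param a,b `blast_report` objects.
#' @return Character vector of differences (empty when equivalent).
#' @export
compare_reports <- function(a, b) {
  diffs <- character()
  note <- function(...) diffs[[length(diffs) + 1L]] <<- sprintf(...)

  same_real <- function(x, y, tol) {
    (is.na(x) && is.na(y)) || (!is.na(x) && !is.na(y) && abs(x - y) <= tol)
  }
  same_evalue <- function(x, y) {
    if (is.na(x) || is.na(y)) return(is.na(x) && is.na(y))
    if (x == y) return(TRUE)
    if (x == 0 || y == 0) return(max(x, y) < 1e-180)
    abs(x - y) / max(x, y) <= 0.06
  }

  if (!identical(a$program, b$program)) note("program: %s vs %s", a$program, b$program)
  if (!identical(a$version, b$version)) note("version: %s vs %s", a$version, b$version)
  if (!identical(a$database, b$database)) note("database differs")
  if (length(a$queries) != length(b$queries)) {
    note("query count: %d vs %d", length(a$queries), length(b$queries))
    return(diffs)
  }
  for (qi in seq_along(a$queries)) {
    qa <- a$queries[[qi]]; qb <- b$queries[[qi]]
    if (!identical(qa$query_id, qb$query_id) ||
        !identical(qa$query_desc, qb$query_desc) ||
        qa$query_len != qb$query_len) {
      note("query %d header differs", qi)
    }
    if (length(qa$hits) != length(qb$hits)) {
      note("query %d: hit count %d vs %d", qi, length(qa$hits), length(qb$hits))
      next
    }
    for (hi in seq_along(qa$hits)) {
      ha <- qa$hits[[hi]]; hb <- qb$hits[[hi]]
      if (!identical(ha$hit_id, hb$hit_id) ||
          !identical(ha$description, hb$description) ||
          ha$subject_len != hb$subject_len) {
        note("query %d hit %d header differs", qi, hi)
      }
      if (length(ha$hsps) != length(hb$hsps)) {
        note("query %d hit %d: HSP count differs", qi, hi)
        next
      }
      int_fields <- c("align_len", "identities", "positives", "gap_count",
                      "q_from", "q_to", "s_from", "s_to", "raw_score",
                      "q_frame", "s_frame")
      chr_fields <- c("qseq", "hseq", "midline", "q_strand", "s_strand")
      for (ki in seq_along(ha$hsps)) {
        xa <- ha$hsps[[ki]]; xb <- hb$hsps[[ki]]
        for (f in int_fields) {
          va <- xa[[f]]; vb <- xb[[f]]
          if (!((is.na(va) && is.na(vb)) ||
                (!is.na(va) && !is.na(vb) && va == vb))) {
            note("query %d hit %d HSP %d: %s %s vs %s",
                 qi, hi, ki, f, format(va), format(vb))
          }
        }
        for (f in chr_fields) {
          if (!identical(xa[[f]], xb[[f]])) {
            note("query %d hit %d HSP %d: %s differs", qi, hi, ki, f)
          }
        }
        if (!same_real(xa$bit_score, xb$bit_score, 0.05)) {
          note("query %d hit %d HSP %d: bit_score %.3f vs %.3f",
               qi, hi, ki, xa$bit_score, xb$bit_score)
        }
        if (!same_evalue(xa$evalue, xb$evalue)) {
          note("query %d hit %d HSP %d: evalue %g vs %g",
               qi, hi, ki, xa$evalue, xb$evalue)
        }
      }
    }
  }
  fa <- a$footer_stats; fb <- b$footer_stats
  if (is.null(fa) != is.null(fb)) {
    note("footer stats presence differs")
  } else if (!is.null(fa)) {
    if (!same_real(fa$lambda, fb$lambda, 1e-3) ||
        !same_real(fa$k, fb$k, 1e-4) || !same_real(fa$h, fb$h, 1e-3)) {
      note("footer stats differ")
    }
  }
  diffs
}
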