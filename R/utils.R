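# Small shared helpers: rounding, number formatting, escaping, seeded RNG.

# BLAST prints percentages rounded to the nearest integer, halves away from
# zero (72.5% -> 73%).  base::round() rounds half to even, so spell it out.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Integer percentage of count x over total n (n > 0).
pct_of <- function(x, n) {
  as.integer(round_half_away(100 * x / n))
}

# BLAST-style E-value formatting for the pairwise-text dialect: plain decimal
# at or above 1e-4, scientific below, "0.0" for exactly zero.  Two significant
# figures, which as.numeric() parses back exactly enough for round-trips.
format_evalue <- function(e) {
  stopifnot(length(e) == 1L, !is.na(e), e >= 0)
  if (e == 0) {
    "0.0"
  } else if (e >= 1e-4) {
    format(signif(e, 2), scientific = FALSE, trim = TRUE)
  } else {
    sprintf("%.1e", signif(e, 2))
  }
}

format_bits <- function(b) sprintf("%.1f", b)

# Escape text for inclusion in XML/HTML element content or attribute values.
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# Turn arbitrary identifiers into safe XML/HTML id attribute values.
sanitize_id <- function(x) {
  x <- gsub("[^A-Za-z0-9_.:-]", "_", x)
  ifelse(grepl("^[A-Za-z]", x), x, paste0("x", x))
}

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Sample one integer uniformly from an inclusive range given as c(lo, hi)
# or a single value.
sample_range <- function(range) {
  if (length(range) == 1L) range <- c(range, range)
  if (range[1] == range[2]) return(as.integer(range[1]))
  as.integer(sample(seq.int(range[1], range[2]), 1L))
}

# Write text to a file atomically: assemble in a sibling temp file, then
# rename.  Guarantees no partial output file is left behind on failure.
write_atomic <- function(text, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  con <- file(tmp, open = "wb")
  writeLines(text, con, sep = "\n", useBytes = TRUE)
  close(con)
  if (!file.rename(tmp, path)) {
    stop("failed to move temporary file into place: ", path)
  }
  invisible(path)
}

# Read a whole text input: accepts a file path, a connection, or a string
# (anything containing a newline or not naming an existing file is treated
# as literal text).
read_input_text <- function(x) {
  if (inherits(x, "connection")) {
    return(paste(readLines(x, warn = FALSE), collapse = "\n"))
  }
  stopifnot(is.character(x))
  if (length(x) > 1L) return(paste(x, collapse = "\n"))
  if (!grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(paste(readLines(x, warn = FALSE), collapse = "\n"))
  }
  x
}
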