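---
title: "blastvista: data model, rendering rules and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{blastvista: data model, rendering rules and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastvista)
```

## The problem and the data model

BLAST reports one or more *queries*, each with zero or more *hits*
(database subjects), each hit with one or more *high-scoring pairs*
(HSPs): gapped local alignments carrying a bit score, an E-value, count
statistics and coordinates on both sequences. `blastvista` parses the two
report formats every BLAST+ version emits — the default pairwise text
layout and the classic `BlastOutput` XML — into one data model
(`blast_report` → `blast_query` → `blast_hit` → `blast_hsp`) and renders
the three standard views (hit distribution, HSP table, per-residue
alignment) from that model only. Nothing downstream ever re-reads the
input file, so the model's validator is the single gate between file and
figure.

### Invariants

Every parsed or simulated report must satisfy, per HSP:

* `nchar(qseq) == nchar(hseq) == nchar(midline) == align_len`;
* `0 ≤ identities ≤ positives ≤ align_len` (positives only for protein
  and translated programs; blastn has none);
* `gap_count` equals the `-` characters counted over both strings, and no
  column is gapped in both;
* coordinate spans obey the step factors: a translated side advances 3
  nucleotides per alignment column, so
  `to − from + 1 = step × (align_len − gaps_on_that_side)` with
  `step_q = 3` for blastx/tblastx, `step_s = 3` for tblastn/tblastx, and
  1 otherwise;
* orientation: strands (`plus`/`minus`) exist only for blastn; translated
  sides carry a reading frame in `±1..±3` whose sign encodes orientation.

Coordinates are stored 1-based inclusive with `from ≤ to` on both sides.
Minus-strand and negative-frame sides are a display property: the text
serializer and the alignment view print those labels descending, and the
parser normalises them back. This "one internal convention, lossless
externally" rule removes an entire class of sign errors from the metrics
and layout code.

### Strict and lenient parsing

Strict mode (the default) raises a `malformed_input` condition at the
first structural error or invariant violation. Lenient mode drops the
offending HSP, hit or query, records an issue with a line number, and
continues — it never repairs values, because a silently "fixed" count is
worse than a missing alignment. Warnings (unrecognised lines, summary
table/detail section disagreement) are collected in both modes. Genuine
BLAST+ boilerplate — citation headers, `, Method: ...` score-line
suffixes, Karlin–Altschul and search-statistics trailers — is recognised
and skipped silently, so real files parse without warning noise; this is
exercised against committed output of BLASTP 2.17.0+ in the test suite.

The hit detail sections are authoritative. The `Sequences producing
significant alignments:` summary table truncates descriptions and rounds
scores, so it is only cross-checked for hit count (a mismatch is a
warning). Legacy pre-BLAST+ text layouts (sum statistics, `Expect(2) =`
score lines) and the newer seq-align-based "XML2" and JSON outputs are
out of scope; the latter two are rejected as unrecognised formats.

## Recomputed statistics

`recompute_hsp_stats()` recounts identities (equal non-gap symbols,
case-insensitive), gaps and positives (non-blank midline marks) directly
from the aligned strings and compares them with the counts the file
declared, raising `inconsistent_hsp` on any disagreement. A
single-character corruption of an aligned string is therefore detected
exactly when it changes a count; substituting one mismatched residue for
another mismatched residue is invisible to count-based checking *by
construction*, which the test suite verifies with an independent
column-by-column recount: detection must coincide exactly with the
corruption being count-changing, and all count-changing corruptions must
be caught.

Percentages are rounded to the nearest integer with halves away from
zero (62.5% → 63%), matching the convention of BLAST's printed
percentages on every round-tripped fixture.

## The five colour classes

The distribution graphic colours each HSP bar by an ordinal quality class.
The paper-facing convention for such overviews is the NCBI five-bin key,
adopted here as the default: bit-score edges `{40, 50, 80, 200}`, each
bin closed on its lower edge (a score of exactly 40 falls in bin 1), and
an E-value mode with edges `{1, 1e-5, 1e-10, 1e-50}` (bin 0 for E ≥ 1,
bin 4 for E < 1e-50). Both edge sets and the five-colour palette are
configurable through `dist_config()`; the default colour mode is bit
score, since bit scores are comparable across scoring systems while
E-values depend on database size. Binning is total and monotone in
alignment quality — property-tested over random score pairs.

## Layout and rendering

`layout_distribution()` is pure geometry: the bar for an HSP is the image
of `[q_from − 1, q_to]` under the linear map from `[0, query_len]` to the
drawable x-range, so bars can never leave the canvas for valid input.
Hits are ordered best-first — maximum bit score, ties by minimum E-value,
then input order — one row per hit with thin connectors between
consecutive HSP bars (the NCBI-overview appearance), at most `max_hits`
rows (default 50, chosen so a default-width canvas stays readable;
configurable). `render_distribution()` turns a layout into SVG 1.1 text
deterministically — two renders of one layout are byte-identical — with
stable element ids derived from hit ids.

The alignment view chunks the aligned strings at `chunk_width` columns
(default 60, BLAST's own). Per-chunk coordinate labels advance by
`step × non-gap symbols` in the chunk and descend on minus sides. A chunk
consisting entirely of gaps on one side is labelled with an empty span
(`to = from − step^0`, i.e. one before `from`); the serializer and parser
share this convention, so reassembly is exact in all cases.

The HTML report embeds, per query, the SVG, the table and the alignment
blocks, with a documented anchor contract (`aln-q<q>-h<h>-s<k>` for HSP
`k` of displayed hit `h` of query `q`) so callers can post-process the
document — the static counterpart of attaching callbacks to table rows in
an interactive viewer. PNG/JPEG rasterisation is deliberately out of
scope; SVG is the canonical graphic, and any external rasteriser can be
applied to it.

## The synthetic generator

`simulate_report()` produces the fixtures for the whole test suite: for
each HSP it draws aligned columns over the program-appropriate alphabet,
applies substitutions at `substitution_rate` per column and gap runs at
`gap_open_rate` (geometric lengths with mean `mean_gap_len`, capped at 5
columns, never at the alignment edges), computes the midline (identity
marks — `|` for blastn, the residue letter otherwise; `+` for
non-identical protein residues in the same similarity class, fixed as
{ILVM} {FWY} {KRH} {DE} {ST} {NQ}), and derives every count and
coordinate so the invariants hold by construction. Defaults
(`substitution_rate = 0.1`, `gap_open_rate = 0.03`, query lengths
80–300) sit in the range of a routine protein homology search — mostly
high-identity local alignments with occasional short indels.

Scores are deliberately not Karlin–Altschul statistics: the bit score is
a fixed decreasing function of mismatches and gap columns
(`1.9·matches − 1.1·mismatches − 2.3·gapcols + 24`, one decimal) and the
E-value is `signif(2^(−bits) · 10⁶, 2)`. Orderings — the only property
the viewer uses — are preserved, and the two-significant-figure E-value
means the text format (which prints ~2 significant figures) round-trips
it exactly. The viewer visualises scores; it does not compute them, and
the parsed Lambda/K/H footer is carried but unused.

What the generator does *not* emulate: compositional score adjustments,
biologically realistic sequence composition, overlapping HSP structure
from repeats, database-size-dependent E-values, and the decorated summary
tables of real BLAST output. Passing the round-trip suite therefore shows
the parser/serializer pair is self-consistent and the statistics are
recomputed correctly — compatibility with real output is checked
separately against committed genuine BLASTP 2.17 text/XML files, which
also cover the boilerplate the generator omits.

Determinism: identical `sim_spec` + seed gives byte-identical output
within a build; committed golden files guard against drift across R
versions (R's `sample()` has been stable since 3.6).

## Numerical and formatting choices

* Bit scores print with one decimal in the text dialect; round-trip
  tolerance is ±0.05 bits. XML carries full precision.
* E-values print as plain decimals at or above `1e-4`, scientific below,
  `0.0` for exactly zero; round-trip tolerance is one significant figure
  of the printed form.
* Percentage rounding: half away from zero (see above).
* Ties in hit ordering resolve by input order, making layouts and tables
  fully deterministic.

## Problem sizes in the tests

The acceptance-style tests use a 200-report corpus (40 per program, one
query each, 0–3 hits, 1–2 HSPs, query lengths 60–200), 1000 corruption
trials, 1000 randomized cases per invariant family, and rendered reports
of 10, 100 and 1000 queries (1–5 hits each) — sizes chosen to exercise
every code path many times while keeping the default test run in the
low minutes on a single CPU.

## Known limitations

* Pre-2.2.x legacy text dialects are not parsed (strict mode reports
  them as malformed); "XML2" and JSON outputs are rejected by design.
* `Database:` values spanning multiple header lines are truncated to the
  first line.
* The raw score is optional in the model; when serializing an HSP that
  lacks one (an XML-only source without `Hsp_score`), the text writer
  emits a placeholder of `2 × bit_score` rounded, since the text grammar
  requires the parenthesised integer.
* Query coverage uses the union of query-side HSP spans
  (`IRanges::reduce`); it does not attempt subject-side coverage.
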