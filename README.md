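# blastvista

Parse and visualise BLAST alignment results in R — without running BLAST
and without a web service.

Sequence-similarity searching with the BLAST family (BLASTp, BLASTn,
BLASTx, tBLASTn, tBLASTx) is often the first analysis applied to a new
protein or DNA sequence, but the raw report formats — the default pairwise
text layout and the `BlastOutput` XML — are awkward to inspect at scale.
`blastvista` turns either format into a validated data model and renders
the three views analysts actually use:

* **A. Hit distribution** — an SVG graphic in the style of the NCBI
  overview: the query as a ruler, each hit as a row of bars placed at its
  HSP coordinates, coloured by one of five ordinal score classes
  (bit-score edges `<40, 40–50, 50–80, 80–200, ≥200`, or a five-decade
  E-value analogue; both configurable).
* **B. HSP attribute table** — one row per high-scoring pair with the bit
  score, E-value, identity, positives and gaps (integer percentages as
  BLAST prints them) plus coordinates, exportable as RFC 4180 CSV.
* **C. Per-residue alignments** — the chunked `Query`/midline/`Sbjct`
  triples at a configurable width, with coordinate labels that advance by
  the program's step factor (3 nt per column on translated sides) and run
  downwards on minus-strand or negative-frame sides.

All three are assembled into a standalone HTML report per input file, with
each table row hyperlinked to its alignment block.

The package is built around a round-trip contract: a seeded synthetic
generator (`simulate_report()`) produces reports with known ground-truth
statistics and serializes them to both formats, and the parsers must
reproduce every field. Every parsed HSP can be re-validated from its
aligned strings alone with `recompute_hsp_stats()`: identities are the
columns where query and subject carry the same non-gap symbol, gaps the
`-` columns over both strings, positives the non-blank midline marks —
any disagreement with the declared counts raises an `inconsistent_hsp`
error. Coordinate invariants are enforced per program: for a query span,

    q_to - q_from + 1 = step_q * (align_len - gaps_in_qseq)

with `step_q = 3` for BLASTx/tBLASTx and 1 otherwise (symmetrically for
the subject with tBLASTn/tBLASTx).

## Worked example

```r
library(blastvista)

path <- system.file("extdata", "mahmi_peptide_synthetic.txt",
                    package = "blastvista")
res <- parse_report(path)        # strict mode: errors on malformed input
res$report
#> <blast_report> BLASTP 2.6.0+ | db: mahmi_peptides | 1 query, 2 hits, 2 HSPs

qr <- res$report$queries[[1]]
build_hsp_table(qr)[, c("hit_id", "bit_score", "evalue", "pct_identity",
                        "pct_positives", "q_from", "q_to")]
#>            hit_id bit_score  evalue pct_identity pct_positives q_from q_to
#> 1 MAHMI_pep_00471      44.7 2.1e-06           95           100      1   22
#> 2 MAHMI_pep_01198      31.2 1.8e-03           86            93      5   18

query_coverage(qr$hits[[1]], qr$query_len)   # union of HSP spans / length
#> [1] 1
score_bin(qr$hits[[1]]$hsps[[1]])$label      # colour class of the best HSP
#> [1] "40-50"

format_alignment(qr$hits[[1]]$hsps[[1]])
#> Query   1  LASDPIVLSKPDYGWANNHTFV  22
#>            LASDPIVLSKP+YGWANNHTFV
#> Sbjct   1  LASDPIVLSKPEYGWANNHTFV  22

writeLines(render_html_report(res$report), "report.html")
```

The 22-residue query is a peptide-vs-peptide-database search: hit 1
matches the full query with a single conservative substitution (D→E, a
`+` positive), hit 2 a 14-residue internal window.

## Command line

```sh
blastvista simulate --queries 10 --seed 7 --out sim.txt
blastvista render sim.txt --out report.html --csv report.csv --svg dist.svg
blastvista convert sim.txt --out sim.xml          # text <-> XML
blastvista validate sim.txt                       # parse + invariant check
```

(the `blastvista` script is installed under the package's `exec/`
directory; call it via its full path or symlink it onto your `PATH`).
`--lenient` downgrades malformed hits/HSPs from errors to dropped units
with warnings; exit codes are 0 (success), 1 (parse/validation failure),
2 (usage error).

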