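# irscan — exact gapped inverted repeats in IUPAC-encoded DNA

`irscan` exhaustively enumerates all **maximal gapped inverted repeats**
(IRs) in DNA sequences over the full 15-letter IUPAC ambiguity alphabet. An
IR is a segment of the form *W G W̄ᴿ* — an arm, a bounded central gap, and
the reverse complement of the arm — with the two arms allowed to disagree at
up to *k* positions (Hamming distance δ_H(W, W̄ᴿ) ≤ k). Such repeats can
extrude into cruciform structure and mark recombination and rearrangement
hotspots; on population-consensus references, polymorphic sites appear as
ambiguity codes (`R` = A/G, `Y` = C/T, …), so the matcher must understand
degenerate symbols.

The package is aimed at anyone scanning (possibly variant-annotated)
sequences for IRs: it is a drop-in, scriptable alternative to EMBOSS
`palindrome` that understands ambiguity codes as *sets of possibilities*.

## Method in brief

Two complement-matching schemes over IUPAC codes are provided as swappable
15×15 boolean matrices: **simple** (each code matches only its unique
elementwise-complement code, the EMBOSS convention) and **degenerate**
(codes match iff their base sets admit at least one Watson–Crick pairing;
e.g. `R` matches `C` because `R` contains `G`). The search indexes
*X · s₁ · rc(X) · s₂* with a suffix array + LCP array + sparse-table RMQ,
answering longest-common-extension queries in O(1), and walks outward from
each of the 2n−1 centres with the *kangaroo method*: literal LCE jumps, with
every stop adjudicated against the match matrix so degenerate-only matches
are crossed free of charge and true mismatches consume budget. A
gap-swallowing loop then grows the gap past one mismatch at a time, emitting
one maximal repeat per swallowed-mismatch count within the gap bound.
Reported repeats always begin and end with a matching pair.

## Worked example

```r
library(irscan)

s <- iupac_seq("ACGTACGAAGGT")
p <- search_params(min_arm = 1, max_arm = 100, max_gap = 100, max_mismatch = 1)
enumerate_irs_at_centre(build_index(s), centre = 6.5, p)
#> 3 inverted repeat(s) in 'seq' (12 bp; arm 1..100, gap <= 100, mismatches <= 1, degenerate matching)
#>   left_start left_end right_start right_end arm_len gap_len mismatches
#> 1          1        4           9        12       4       4          1
#> 2          1        2          11        12       2       8          0
#> 3          4        6           7         9       3       0          1
```

These three repeats share the centre between positions 6 and 7; each larger
gap swallows one more mismatching pair and buys a different maximal repeat —
row 3 has gap 0 and one internal mismatch, row 1 grows the gap to 4 for a
4-pair arm, row 2 to 8 and is mismatch-free. The full search
(`find_inverted_repeats(s, p)`) does this at all 23 centres and reports 16
repeats. Reports are written and read back in EMBOSS-palindrome block
format — the block for row 3:

```r
irs <- find_inverted_repeats(s, p)
write_palindrome_output(s, irs, "example.out")
cat(readLines("example.out")[36:38], sep = "\n")
#> 4    TAC    6
#>      | |
#> 9    AAG    7
```

(The middle line marks the pair `A:G` as a mismatch.) A degenerate-aware
run on an ambiguity code:

```r
match_matrix("degenerate")["R", "C"]   # TRUE — R contains G, complement of C
match_matrix("simple")["R", "C"]       # FALSE
```

From a shell (thin wrapper over the same functions; flags mirror EMBOSS
usage — input FASTA, sequence name, output, min/max arm, max gap,
mismatches):

```sh
Rscript exec/irscan -f genome.fasta -s chrX -o chrX.irs -m 10 -M 100 -g 100 -x 2
Rscript exec/irscan compare chrX.irs other.irs
```

Key functions: `iupac_seq()`, `search_params()`, `find_inverted_repeats()`,
`match_matrix()`, `build_index()`/`kangaroo_lce()` (the LCE layer),
`brute_force_find_irs()` (independent quadratic reference),
`random_iupac_sequence()` (seeded fixture generator), `validate_irs()`,
`write_palindrome_output()`/`parse_palindrome_output()`/`compare_outputs()`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end behaviour from scratch: generates a
seeded 100,000-symbol IUPAC sequence (10% ambiguity codes), runs the full
search at the default scan parameters (arm 10–100, gap ≤ 100) at mismatch
budgets 0 and 2, independently re-validates a sample of the reported
repeats, round-trips the EMBOSS-style report, and writes the JSON result
object to `--out`.

## Layout

- `R/`, `src/` — implementation (R surface, Rcpp index/search core)
- `tests/testthat/` — unit, property and acceptance batteries (brute-force
  and naive oracles live in `helper-oracles.R` and `R/oracle.R`)
- `exec/irscan` — command-line entry point
- `vignettes/inverted-repeats.Rmd` — model, assumptions, design choices
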