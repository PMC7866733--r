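---
title: "Detecting gapped inverted repeats in IUPAC-encoded DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gapped inverted repeats in IUPAC-encoded DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irscan)
```

## The problem

An *inverted repeat* (IR) is a DNA segment of the form $W\,G\,\bar W^R$: an
arm $W$, an arbitrary central gap $G$ (possibly empty), and then the reverse
complement of the arm. IRs can extrude into cruciform secondary structure and
are associated with recombination hotspots, chromosomal rearrangement and
regulatory elements, which makes their exhaustive annotation a routine task
in sequence analysis. Two relaxations matter in practice: the two arms are
allowed to differ at up to $k$ positions (a Hamming mismatch budget,
$\delta_H(W, \bar W^R) \le k$), and the gap may be bounded but nonzero.

Population-scale variation data are often folded into a single *degenerate*
reference in which each polymorphic position carries the IUPAC ambiguity code
for its observed alleles — `R` for A/G, `Y` for C/T, and so on through the 15
nonempty subsets of $\{A,C,G,T\}$. `irscan` enumerates, exactly and
exhaustively, **all maximal gapped IRs within a mismatch budget** in such
IUPAC-encoded sequences.

## Matching degenerate symbols

Complementarity must be extended from the four bases to the 15 codes. The
package implements both conventions in use:

* **simple complement matching** — every code has a unique complement code
  (the elementwise complement of its base set: `B`$=\{C,G,T\}$ pairs with
  `V`$=\{G,C,A\}$), and two codes match only if one is the complement of the
  other. This is the EMBOSS `palindrome` convention.
* **degenerate complement matching** (default) — codes $I_1, I_2$ match iff
  some $\sigma_1 \in I_1$ and $\sigma_2 \in I_2$ are Watson–Crick
  complements. `R` matches `C` because `R` contains `G`. This reading treats
  an ambiguity code as a set of possibilities and accepts any realizable
  pairing.

Both relations are symmetric; the simple relation is a strict subset of the
degenerate one; and restricted to solid bases the two coincide (exactly
A:T and C:G), so on a plain ACGT sequence the scheme choice is invisible.
The relation is materialized as a $15\times15$ logical matrix
(`match_matrix()`), and the search consults only this matrix — any symmetric
matrix with IUPAC dimnames can be swapped in to define a custom scheme.

```{r}
mm <- match_matrix("degenerate")
mm["R", c("C", "T", "G")]
```

## The algorithm

The search is centre-based. A sequence of length $n$ has $2n-1$ half-integer
centres; a pair of positions $(l, r)$, $l<r$, belongs to the centre
$(l+r)/2$. On-symbol centres leave one unpaired central symbol, so their
gaps are odd (minimum 1); between-symbol centres have even gaps (minimum 0).

**Index.** The sequence $X$ is concatenated with its reverse complement as
$X \cdot s_1 \cdot rc(X) \cdot s_2$ (distinct sentinels below the alphabet),
and a suffix array (prefix doubling), LCP array (Kasai) and sparse-table RMQ
are built over it, giving $O(1)$ *longest common extension* queries: the
longest literal match between a forward suffix and a reverse-complement
suffix. Comparing $X[l0-t]$ with $X[r0+t]$ for growing $t$ is the same as a
forward–forward comparison between $X$ at $r0$ and $rc(X)$ at $n-1-l0$.

**Kangaroo walks.** Because $rc(X)$ is built with the *simple* complement,
literal text equality implies a match under either scheme — never the
reverse. So each centre is scanned by kangaroo jumps: an $O(1)$ literal LCE,
then adjudication of the stopping pair against the match matrix. A pair that
matches degenerately (but not literally) continues the walk *free of
charge*; anything else is a true mismatch. Mismatch positions are produced
lazily, one jump each, so a centre only ever pays for the mismatches its
parameters can use.

**Gap swallowing.** For $j = 0, 1, 2, \dots$ let $s_j$ be the innermost pair
excluding the first $j$ true mismatches ($s_0$ = innermost possible pair);
the implied gap grows with $j$ and the loop stops when it exceeds the gap
bound. For each $j$ the arm runs from $s_j$ outward to just inside the
$(k{+}1)$-th remaining mismatch, the arm cap $M$, or the boundary, and is
then trimmed inward so the outermost pair matches (a reported IR always
begins and ends with a matching pair). Arms of at least $m$ pairs are
emitted. Every emitted IR is *maximal*: no outward extension with a matching
outermost pair stays within the budget, the cap and the boundary. Only
minimal gaps per swallowed-mismatch count are visited — intermediate gaps
would yield inward-extendable, non-maximal repeats.

IRs are keyed by their arm-interval pair; at one centre every $j$ produces a
distinct gap, and across centres the outer pair fixes the centre, so keys
are naturally unique. Output is ordered by left start, then right end
descending, then gap.

```{r}
s <- iupac_seq("ACGTACGAAGGT")
p <- search_params(min_arm = 1, max_arm = 100, max_gap = 100, max_mismatch = 1)
enumerate_irs_at_centre(build_index(s), centre = 6.5, p)
```

The three repeats share the centre between positions 6 and 7: each larger
gap swallows one more mismatch and buys a different maximal extension.
`find_inverted_repeats(s, p)` repeats this at all $2n-1$ centres.

## Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `min_arm` | shortest reportable arm (pairs) | 10 | conventional genome-scan floor; shorter arms are overwhelmingly chance pairings |
| `max_arm` | arm cap | 100 | bounds per-centre work and report size |
| `max_gap` | largest central spacer (symbols) | 100 | cruciform-plausible loop sizes |
| `max_mismatch` | Hamming budget between arms | 0 | exact arms unless asked otherwise |
| `scheme` | complement relation on IUPAC codes | degenerate | set-of-possibilities reading; `simple` reproduces EMBOSS behaviour |

All coordinates on the R surface are **1-based inclusive** — the R and
Bioconductor convention — including the `ir_set` columns and the positions
taken by `lce_literal()`/`kangaroo_lce()`. Internally the C++ core is
0-based half-open; the boundary sits at the R/C++ interface rather than in
the report writer.

## The synthetic-data generator

`random_iupac_sequence()` emulates a variant-annotated reference: each
position is a uniform solid base with probability `solid_fraction` (default
0.9), otherwise an ambiguity code drawn from configurable weights. The
default weights put 90% of the degenerate mass uniformly on the six two-base
codes (R, Y, S, W, K, M) — the signature of biallelic SNPs folded into a
consensus, which dominate real population data — and 2% each on B, D, H, V
and N. The 10% degenerate density is far above genome-wide SNP density; it
is chosen to exercise degenerate matching hard, not to mimic a particular
genome. What the generator does *not* emulate: linkage structure,
repeat/GC composition, indels (IUPAC encoding cannot express them), or the
long-range homology of real chromosomal IRs. A green randomized test
therefore establishes algorithmic correctness on i.i.d. sequence, not
biological realism of the fixtures.

## Verification

The package carries an independent reference implementation,
`brute_force_find_irs()`, which applies the same emission rules by direct
outward matrix scans at every centre — no suffix array, LCP, RMQ or
kangaroo machinery — plus naive test oracles (string-sorted suffix arrays,
character-scan extensions). The acceptance battery checks, over ~2,160
sequence-by-parameter combinations (lengths 50–300, solid and
10%-degenerate, arms 2–100, gaps 0–100, budgets 0–4, both schemes):

* set identity of the indexed search with the brute-force reference;
* independent per-repeat re-validation (geometry, bounds, mismatch recount,
  outermost-pair match, maximality);
* reverse-complement mirror symmetry and budget monotonicity;
* suffix array / LCP / LCE / kangaroo agreement with naive constructions
  up to length 200;
* byte-level report format stability and parse∘write identity;
* exhaustive re-derivation of both match matrices;
* a 100,000-symbol search at budget 2 (completes in seconds).

## Numerical and design choices

* **Trimming vs maximality.** After trimming, the pair just outside a
  reported IR is always a true mismatch, but including it need not exceed
  the budget when trimming has discarded mismatching outermost pairs. The
  correct maximality statement — implemented by `validate_irs()` — is that
  no outward extension *with a matching outermost pair* fits the budget,
  cap and boundary; reported IRs provably satisfy it.
* **Scheme monotonicity is count-level, not set-level.** The degenerate
  scheme finds at least as many repeats in practice, but a simple-scheme IR
  truncated at a degenerate-only matching pair is *extended through* that
  pair under the degenerate scheme and reported with wider arms; its exact
  coordinates then appear in neither output. On 10%-degenerate fixtures
  roughly a third of simple-scheme repeats are widened this way. The two
  schemes' outputs are identical on solid input, and the simple relation is
  a subset of the degenerate relation pair-by-pair — but set inclusion of
  whole maximal-repeat outputs does not hold in general (the acceptance
  suite records this expectation failure deliberately).
* **Uniqueness key** is the arm-interval pair; the gap is derived, not
  free. This matches the observable output of EMBOSS-style reports.
* **Sentinels** are integer codes below the alphabet (−1, −2), distinct so
  no suffix comparison crosses segment boundaries meaningfully; they never
  appear in output.
* **Aliases** `U` and `*` are normalized to `T` and `N` on input and never
  appear internally; lower case is folded. Invalid characters error with
  their record and 1-based position.
* **Determinism.** Reports contain no timestamps; identical inputs produce
  byte-identical files. Logging goes to standard error.

## Limitations

* Arm mismatches are substitutions only — no indels within arms (an IR
  model with bulges needs alignment scoring, a different paradigm).
* The brute-force reference is quadratic and intended for sequences up to a
  few hundred symbols; the indexed search handles chromosome-arm scale.
* Weighted match/mismatch scoring (Inverted-Repeats-Finder style) and
  overlap clustering of reported IRs are out of scope.
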