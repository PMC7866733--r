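Package: irscan
Title: Exact Detection of Gapped Inverted Repeats in IUPAC-Encoded DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exhaustive, exact enumeration of all maximal gapped inverted
    repeats (approximate DNA palindromes) within a Hamming mismatch budget, in
    sequences over the 15-letter IUPAC nucleotide alphabet. Degenerate symbols
    are matched either by the unique-complement ("simple") rule or by the
    set-intersection ("degenerate") rule, encoded as a swappable 15x15 match
    matrix. The search is backed by a suffix array, Kasai LCP array and a
    sparse-table range-minimum structure over the sequence concatenated with
    its reverse complement, so longest-common-extension queries run in constant
    time and mismatch positions are located with the kangaroo method. Includes
    a FASTA reader, an EMBOSS-palindrome-compatible report writer and parser, a
    command-line interface, a seeded random IUPAC sequence generator and an
    independent brute-force reference implementation for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
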