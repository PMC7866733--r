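#' Build the longest-common-extension index for a sequence
#'
#' Concatenates the sequence `X` with its reverse complement as
#' `X . s1 . rc(X) . s2` (two distinct sentinels smaller than every alphabet
#' symbol), then builds the suffix array of the concatenation, its LCP array
#' (Kasai's algorithm) and a sparse-table range-minimum structure, so that the
#' longest common extension of any two text positions is answered in constant
#' time. `rc(X)` uses the simple complement at every position, which makes
#' literal text equality a sound under-approximation of both matching schemes;
#' degenerate matches that literal equality misses are adjudicated against the
#' match matrix during [kangaroo_lce()] walks.
#'
#' @param seq An [iupac_seq()] object.
#' @return An object of class `ir_index`: list with `name`, `n`, `codes`,
#'   `text` (integer codes of the concatenation; sentinels are -1 and -2),
#'   `sa`, `inv`, `lcp` (0-based suffix array, its inverse and the LCP array)
#'   and the RMQ sparse table.
#' @examples
#' idx <- build_index(iupac_seq("ACGTACGT"))
#' lce_literal(idx, 1, 5)
#' @export
build_index <- function(seq) {
  stopifnot(inherits(seq, "iupac_seq"))
  n <- length(seq$codes)
  if (n < 1) stop("empty sequence", call. = FALSE)
  text <- c(seq$codes, -1L, rev(.COMP_CODE[seq$codes]), -2L)
  built <- cpp_build_index(text)
  structure(list(name = seq$name, n = n, codes = seq$codes, text = text,
                 sa = built$sa, inv = built$inv, lcp = built$lcp,
                 sp = built$sp, logt = built$logt, levels = built$levels),
            class = "ir_index")
}

#' @export
print.ir_index <- function(x, ...) {
  cat(sprintf("LCE index of '%s': %d symbols (text length %d)\n",
              x$name, x$n, length(x$text)))
  invisible(x)
}

.check_index <- function(idx) {
  if (!inherits(idx, "ir_index")) stop("expected an 'ir_index' object", call. = FALSE)
}

#' Literal longest common extension
#'
#' Length of the longest common prefix of the suffixes of the indexed text
#' starting at positions `i` and `j` (1-based, over the full concatenated
#' text of length `2n + 2`), under literal symbol identity. Computed as a
#' range minimum over the LCP array; `i == j` returns the remaining suffix
#' length.
#'
#' @param idx An [build_index()] result.
#' @param i,j 1-based text positions.
#' @return Integer extension length.
#' @export
lce_literal <- function(idx, i, j) {
  .check_index(idx)
  N <- length(idx$text)
  i <- as.integer(i); j <- as.integer(j)
  if (is.na(i) || is.na(j) || i < 1L || j < 1L || i > N || j > N)
    stop(sprintf("text positions must lie in 1..%d", N), call. = FALSE)
  cpp_lce(idx$text, idx$inv, idx$sp, idx$logt, i - 1L, j - 1L)
}

#' Mismatch-budgeted longest common extension (kangaroo method)
#'
#' Walks outward comparing the forward segment from position `fwd_pos` of `X`
#' with the reverse-complement segment from position `rc_pos` of `rc(X)`
#' (both 1-based within their segments), by repeated constant-time literal
#' LCE jumps. At every literal stop the pair of underlying sequence symbols
#' is adjudicated against `matrix`: a scheme match continues the walk without
#' consuming budget; a true mismatch consumes one unit. The walk ends after
#' `budget + 1` true mismatches, at `max_pairs` compared pairs, or at a
#' segment end.
#'
#' Offset `t` of the walk pairs `X[fwd_pos + t]` with the symbol underlying
#' `rc(X)[rc_pos + t]`, i.e. `X[n + 1 - rc_pos - t]`.
#'
#' @param idx An [build_index()] result.
#' @param fwd_pos 1-based position in the forward copy of the sequence.
#' @param rc_pos 1-based position in the reverse-complement copy.
#' @param budget Maximum number of true mismatches to skip over (>= 0).
#' @param matrix A [match_matrix()] (default degenerate).
#' @param max_pairs Cap on the number of compared pairs (default: no cap).
#' @return List with `matched_length` (length of the longest prefix
#'   containing at most `budget` true mismatches) and `mismatch_offsets`
#'   (1-based offsets of the true mismatches encountered, including the
#'   stopping one when the budget is exhausted — hence at most
#'   `budget + 1` of them).
#' @examples
#' idx <- build_index(iupac_seq("RAC"))
#' # pair 1: R vs underlying C -- degenerate match, walk continues for free
#' kangaroo_lce(idx, 1, 1, budget = 0)
#' @export
kangaroo_lce <- function(idx, fwd_pos, rc_pos, budget = 0L,
                         matrix = match_matrix("degenerate"),
                         max_pairs = Inf) {
  .check_index(idx)
  cap <- if (is.finite(max_pairs)) as.integer(max_pairs) else -1L
  res <- cpp_kangaroo(idx$text, idx$n, idx$inv, idx$sp, idx$logt,
                      .mat_codes(matrix), as.integer(fwd_pos) - 1L,
                      as.integer(rc_pos) - 1L, as.integer(budget), cap)
  res$mismatch_offsets <- res$mismatch_offsets + 1L
  res
}

# centre label (half-integer in [1, n]) -> twice_centre in 0..2n-2
.centre_tc <- function(centre, n) {
  tc2 <- round(2 * centre)
  if (abs(2 * centre - tc2) > 1e-9)
    stop("centre must be a multiple of 0.5", call. = FALSE)
  tc <- as.integer(tc2) - 2L
  if (tc < 0L || tc > 2L * n - 2L)
    stop(sprintf("centre must lie in [1, %d]", n), call. = FALSE)
  tc
}
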