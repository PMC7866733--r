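#' Search parameters for inverted-repeat detection
#'
#' Bundles the four EMBOSS-style constraints plus the matching scheme.
#' Defaults are the conventional genome-scan settings (minimum arm 10,
#' maximum arm 100, maximum gap 100, no mismatches, degenerate matching).
#'
#' @param min_arm Minimum arm length `m` (>= 1).
#' @param max_arm Maximum arm length `M` (>= `min_arm`).
#' @param max_gap Maximum length of the central gap (>= 0).
#' @param max_mismatch Mismatch budget `k` (>= 0): maximum Hamming distance
#'   between one arm and the reverse complement of the other.
#' @param scheme Matching scheme, `"degenerate"` or `"simple"`; see
#'   [match_matrix()].
#' @return An object of class `ir_params`.
#' @examples
#' search_params(min_arm = 3, max_gap = 5, max_mismatch = 1)
#' @export
search_params <- function(min_arm = 10L, max_arm = 100L, max_gap = 100L,
                          max_mismatch = 0L,
                          scheme = c("degenerate", "simple")) {
  scheme <- match.arg(scheme)
  p <- list(min_arm = as.integer(min_arm), max_arm = as.integer(max_arm),
            max_gap = as.integer(max_gap), max_mismatch = as.integer(max_mismatch),
            scheme = scheme)
  if (anyNA(unlist(p[1:4]))) stop("parameters must be integers", call. = FALSE)
  if (p$min_arm < 1L) stop("min_arm must be >= 1", call. = FALSE)
  if (p$max_arm < p$min_arm)
    stop(sprintf("max_arm (%d) must be >= min_arm (%d)", p$max_arm, p$min_arm),
         call. = FALSE)
  if (p$max_gap < 0L) stop("max_gap must be >= 0", call. = FALSE)
  if (p$max_mismatch < 0L) stop("max_mismatch must be >= 0", call. = FALSE)
  structure(p, class = "ir_params")
}

#' @export
print.ir_params <- function(x, ...) {
  cat(sprintf(
    "IR search parameters: arm %d..%d, gap <= %d, mismatches <= %d, %s matching\n",
    x$min_arm, x$max_arm, x$max_gap, x$max_mismatch, x$scheme))
  invisible(x)
}

.as_params <- function(params) {
  if (inherits(params, "ir_params")) return(params)
  do.call(search_params, as.list(params))
}

# shared result assembly: C++ / oracle rows (0-based half-open) -> ir_set
.ir_df <- function(ls, le, rs, re, nm, seq, params) {
  df <- data.frame(left_start = ls + 1L, left_end = le,
                   right_start = rs + 1L, right_end = re,
                   arm_len = le - ls, gap_len = rs - le,
                   mismatches = nm)
  key <- paste(df$left_start, df$left_end, df$right_start, df$right_end)
  df <- df[!duplicated(key), , drop = FALSE]
  df <- df[order(df$left_start, -df$right_end, df$gap_len), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, seq_name = seq$name, n = length(seq$codes), params = params,
            class = c("ir_set", "data.frame"))
}

#' Find all maximal gapped inverted repeats
#'
#' Exhaustively enumerates, over all `2n - 1` half-integer centres of the
#' sequence, every maximal inverted repeat `W G rc(W)` satisfying the
#' constraints in `params`: arm length within `[min_arm, max_arm]`, gap
#' length at most `max_gap`, and at most `max_mismatch` symbol pairs failing
#' the complement-match matrix. At each centre the enumeration starts from the
#' minimal gap of the centre's parity and repeatedly grows the gap to just
#' beyond the next true mismatch (swallowing it), each time extending the arms
#' outward to just inside the first mismatch beyond the budget, the arm cap or
#' the sequence boundary, and trimming inward so the outermost pair matches.
#' Emitted repeats are therefore maximal: extending both arms outward by one
#' pair would exceed the budget, the arm cap or the boundary.
#'
#' @param seq An [iupac_seq()] object.
#' @param params An [search_params()] object (or a list coercible to one).
#' @return An `ir_set` data frame, one row per repeat, 1-based inclusive
#'   coordinates: `left_start`, `left_end`, `right_start`, `right_end`,
#'   `arm_len`, `gap_len`, `mismatches`. Sorted by `left_start`, then
#'   `right_end` descending, then `gap_len`; rows are unique on the arm
#'   interval pair.
#' @examples
#' irs <- find_inverted_repeats(iupac_seq("AAATTT"),
#'                              search_params(min_arm = 3, max_gap = 10))
#' irs
#' @export
find_inverted_repeats <- function(seq, params = search_params()) {
  stopifnot(inherits(seq, "iupac_seq"))
  p <- .as_params(params)
  idx <- build_index(seq)
  mat <- .mat_codes(match_matrix(p$scheme))
  res <- cpp_search(idx$text, idx$n, idx$inv, idx$sp, idx$logt, mat,
                    p$min_arm, p$max_arm, p$max_gap, p$max_mismatch)
  .ir_df(res[, 1L], res[, 2L], res[, 3L], res[, 4L], res[, 5L], seq, p)
}

#' Enumerate inverted repeats at a single centre
#'
#' The per-centre step of [find_inverted_repeats()], exposed for inspection
#' and testing. `centre` is a half-integer in `[1, n]`: an integer value sits
#' on a symbol (one unpaired central symbol, so gaps are odd), a half value
#' sits between two symbols (even gaps).
#'
#' @inheritParams find_inverted_repeats
#' @param idx An [build_index()] result.
#' @param centre Half-integer centre label.
#' @return An `ir_set` data frame (possibly empty).
#' @export
enumerate_irs_at_centre <- function(idx, centre, params = search_params()) {
  .check_index(idx)
  p <- .as_params(params)
  tc <- .centre_tc(centre, idx$n)
  mat <- .mat_codes(match_matrix(p$scheme))
  res <- cpp_enumerate_centre(idx$text, idx$n, idx$inv, idx$sp, idx$logt, mat,
                              tc, p$min_arm, p$max_arm, p$max_gap, p$max_mismatch)
  seq_like <- list(name = idx$name, codes = idx$codes)
  .ir_df(res[, 1L], res[, 2L], res[, 3L], res[, 4L], res[, 5L], seq_like, p)
}

#' Lazily locate the mismatching pairs around a centre
#'
#' Returns, in increasing distance from the centre, the 1-based pair indices
#' (innermost possible pair = 1) of the first `needed` symbol pairs that are
#' true mismatches under `matrix` — fewer if the sequence boundary intervenes.
#' Pair `t` compares the symbols `t - 1` steps outward from the innermost
#' pair of the centre. Computed with kangaroo LCE restarts, so only the
#' requested mismatches are ever located.
#'
#' @inheritParams enumerate_irs_at_centre
#' @param needed Number of mismatching pairs wanted (>= 1).
#' @param matrix A [match_matrix()].
#' @return Integer vector of at most `needed` pair indices.
#' @export
mismatch_pairs_for_centre <- function(idx, centre, needed,
                                      matrix = match_matrix("degenerate")) {
  .check_index(idx)
  tc <- .centre_tc(centre, idx$n)
  off <- cpp_centre_mismatches(idx$text, idx$n, idx$inv, idx$sp, idx$logt,
                               .mat_codes(matrix), tc, as.integer(needed))
  off + 1L
}

#' @export
print.ir_set <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("%d inverted repeat(s) in '%s' (%d bp; arm %d..%d, gap <= %d, mismatches <= %d, %s matching)\n",
              nrow(x), attr(x, "seq_name"), attr(x, "n"),
              p$min_arm, p$max_arm, p$max_gap, p$max_mismatch, p$scheme))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more row(s)\n", nrow(x) - 10L))
  invisible(x)
}

#' @export
summary.ir_set <- function(object, ...) {
  cat(sprintf("%d inverted repeats; arm lengths %s; gaps %s; mismatches %s\n",
              nrow(object),
              if (nrow(object)) paste(range(object$arm_len), collapse = "..") else "-",
              if (nrow(object)) paste(range(object$gap_len), collapse = "..") else "-",
              if (nrow(object)) paste(range(object$mismatches), collapse = "..") else "-"))
  invisible(object)
}

#' Independently re-validate a set of inverted repeats
#'
#' Re-checks every repeat directly against the sequence and the match matrix,
#' without using the LCE index: equal arm lengths and coordinate sanity, arm
#' and gap bounds, the recount of mismatching pairs, the outermost-pair match
#' rule, and outward maximality (a repeat not capped by the arm limit or the
#' sequence boundary must gain a `k+1`-th mismatch when both arms grow one
#' pair outward).
#'
#' @param seq The [iupac_seq()] the repeats were found in.
#' @param irs An `ir_set` data frame.
#' @param params The [search_params()] used (defaults to the set's own).
#' @return A logical data frame, one row per repeat, columns `geometry`,
#'   `bounds`, `mismatch_count`, `outermost_match`, `maximal`; all-`TRUE`
#'   means the repeat passes.
#' @export
validate_irs <- function(seq, irs, params = attr(irs, "params")) {
  stopifnot(inherits(seq, "iupac_seq"))
  p <- .as_params(params)
  mm <- unclass(match_matrix(p$scheme))
  codes <- seq$codes
  n <- length(codes)
  chk <- function(i) {
    ls <- irs$left_start[i]; le <- irs$left_end[i]
    rs <- irs$right_start[i]; re <- irs$right_end[i]
    L <- le - ls + 1L
    geometry <- L == (re - rs + 1L) && ls <= le && le < rs && rs <= re &&
      ls >= 1L && re <= n && irs$arm_len[i] == L &&
      irs$gap_len[i] == rs - le - 1L
    if (!geometry)
      return(c(geometry = FALSE, bounds = FALSE, mismatch_count = FALSE,
               outermost_match = FALSE, maximal = FALSE))
    pm <- mm[cbind(codes[ls:le], codes[re:rs])]   # outermost pair first
    nm <- sum(!pm)
    bounds <- L >= p$min_arm && L <= p$max_arm &&
      (rs - le - 1L) <= p$max_gap && nm <= p$max_mismatch
    mismatch_count <- nm == irs$mismatches[i]
    outermost <- pm[1L]
    # maximal: no reportable strict outward extension exists, i.e. no t >= 1
    # with a matching outermost pair (ls - t, re + t) whose total mismatch
    # count stays within budget, inside the arm cap and the boundary.
    maximal <- TRUE
    extra <- 0L
    t <- 1L
    while (L + t <= p$max_arm && ls - t >= 1L && re + t <= n) {
      pair_ok <- mm[codes[ls - t], codes[re + t]]
      if (!pair_ok) extra <- extra + 1L
      if (nm + extra > p$max_mismatch) break
      if (pair_ok) { maximal <- FALSE; break }
      t <- t + 1L
    }
    c(geometry = TRUE, bounds = bounds, mismatch_count = mismatch_count,
      outermost_match = outermost, maximal = maximal)
  }
  if (!nrow(irs))
    return(data.frame(geometry = logical(0), bounds = logical(0),
                      mismatch_count = logical(0), outermost_match = logical(0),
                      maximal = logical(0)))
  out <- t(vapply(seq_len(nrow(irs)), chk, logical(5)))
  as.data.frame(out)
}
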