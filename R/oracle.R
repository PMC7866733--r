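#' Generate a random IUPAC-encoded DNA sequence
#'
#' Seeded, reproducible generator emulating variant-annotated genomes, where
#' most positions are solid bases and ambiguity codes mark polymorphic sites.
#' Each position is solid (uniform over A,C,G,T) with probability
#' `solid_fraction`, otherwise drawn from `degenerate_weights` over the 11
#' ambiguity codes. The default weights put 90% of the degenerate mass on the
#' six two-base codes (R,Y,S,W,K,M), the biallelic-SNP signature of
#' population-consensus genomes, and the remainder on B,D,H,V,N.
#'
#' @param n Sequence length (>= 1).
#' @param solid_fraction Probability that a position is a solid base.
#' @param degenerate_weights Named nonnegative weights over the 11 non-solid
#'   codes, summing to 1.
#' @param seed Optional integer seed; when supplied the generator is
#'   deterministic (the caller's RNG state is restored afterwards).
#' @param name Record identifier.
#' @return An [iupac_seq()] object.
#' @examples
#' s <- random_iupac_sequence(50, solid_fraction = 0.9, seed = 1)
#' s
#' @export
random_iupac_sequence <- function(n, solid_fraction = 0.9,
                                  degenerate_weights = NULL, seed = NULL,
                                  name = "random_seq") {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  if (!is.numeric(solid_fraction) || solid_fraction < 0 || solid_fraction > 1)
    stop("solid_fraction must lie in [0, 1]", call. = FALSE)
  degen <- setdiff(.IUPAC, c("A", "C", "G", "T"))
  if (is.null(degenerate_weights)) {
    degenerate_weights <- c(R = 0.15, Y = 0.15, S = 0.15, W = 0.15, K = 0.15,
                            M = 0.15, B = 0.02, D = 0.02, H = 0.02, V = 0.02,
                            N = 0.02)
  }
  if (is.null(names(degenerate_weights)) ||
      !setequal(names(degenerate_weights), degen))
    stop("degenerate_weights must be named with the 11 non-solid IUPAC codes",
         call. = FALSE)
  w <- degenerate_weights[degen]
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("degenerate_weights must be nonnegative and sum to 1", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  solid <- stats::runif(n) < solid_fraction
  chars <- character(n)
  chars[solid] <- sample(c("A", "C", "G", "T"), sum(solid), replace = TRUE)
  if (any(!solid))
    chars[!solid] <- sample(degen, sum(!solid), replace = TRUE, prob = w)
  iupac_seq(chars, name = name)
}

#' Brute-force reference search for inverted repeats
#'
#' Independent reference implementation of [find_inverted_repeats()] for
#' verification: at every centre the full outward pair-match profile is
#' computed by direct lookup in the match matrix (no suffix array, LCP, RMQ
#' or kangaroo machinery), and the same gap-swallowing emission, trimming,
#' uniqueness and ordering rules are applied. Quadratic in the sequence
#' length; intended for sequences up to a few hundred symbols.
#'
#' @inheritParams find_inverted_repeats
#' @return An `ir_set` data frame with the same columns and ordering as
#'   [find_inverted_repeats()].
#' @export
brute_force_find_irs <- function(seq, params = search_params()) {
  stopifnot(inherits(seq, "iupac_seq"))
  p <- .as_params(params)
  codes <- seq$codes
  n <- length(codes)
  mm <- unclass(match_matrix(p$scheme))
  g <- p$max_gap; k <- p$max_mismatch; m <- p$min_arm; M <- p$max_arm
  acc_ls <- integer(0); acc_le <- integer(0); acc_rs <- integer(0)
  acc_re <- integer(0); acc_nm <- integer(0)
  for (tc in 0:(2L * n - 2L)) {
    if (tc %% 2L == 0L) { l0 <- tc %/% 2L - 1L; r0 <- tc %/% 2L + 1L; par <- 1L }
    else { l0 <- (tc - 1L) %/% 2L; r0 <- (tc + 1L) %/% 2L; par <- 0L }
    if (l0 < 0L || r0 > n - 1L) next
    tmax <- min(l0, n - 1L - r0)
    ts <- 0:tmax
    ok <- mm[cbind(codes[l0 - ts + 1L], codes[r0 + ts + 1L])]
    mis <- ts[!ok]
    j <- 0L
    repeat {
      if (j == 0L) s <- 0L
      else {
        if (length(mis) < j) break
        s <- mis[j] + 1L
      }
      gap <- 2L * s + par
      if (gap > g) break
      if (s > tmax) break
      e <- if (length(mis) >= j + k + 1L) mis[j + k + 1L] - 1L else tmax
      e <- min(e, s + M - 1L)
      while (e >= s && !ok[e + 1L]) e <- e - 1L
      L <- e - s + 1L
      if (L >= m) {
        acc_ls <- c(acc_ls, l0 - e); acc_le <- c(acc_le, l0 - s + 1L)
        acc_rs <- c(acc_rs, r0 + s); acc_re <- c(acc_re, r0 + e + 1L)
        acc_nm <- c(acc_nm, sum(!ok[(s:e) + 1L]))
      }
      j <- j + 1L
    }
  }
  .ir_df(acc_ls, acc_le, acc_rs, acc_re, acc_nm, seq, p)
}

#' Compare two inverted-repeat reports
#'
#' Parses two result files — either EMBOSS-style block reports written by
#' [write_palindrome_output()] or their tab-separated sidecars — into
#' coordinate tuples and reports the intersection and the differences.
#'
#' @param path_a,path_b Paths to the two reports.
#' @return An object of class `ir_comparison`: list with data frames
#'   `common`, `only_a`, `only_b` and a `counts` vector. Swapping the
#'   arguments swaps `only_a` and `only_b`.
#' @export
compare_outputs <- function(path_a, path_b) {
  a <- parse_palindrome_output(path_a)
  b <- parse_palindrome_output(path_b)
  key <- function(d) paste(d$left_start, d$left_end, d$right_start, d$right_end)
  ka <- key(a); kb <- key(b)
  out <- list(common = a[ka %in% kb, , drop = FALSE],
              only_a = a[!(ka %in% kb), , drop = FALSE],
              only_b = b[!(kb %in% ka), , drop = FALSE])
  out$counts <- c(common = nrow(out$common), only_a = nrow(out$only_a),
                  only_b = nrow(out$only_b))
  class(out) <- "ir_comparison"
  out
}

#' @export
print.ir_comparison <- function(x, ...) {
  cat(sprintf("IR report comparison: %d common, %d only in A, %d only in B\n",
              x$counts["common"], x$counts["only_a"], x$counts["only_b"]))
  if (nrow(x$only_a)) { cat("only in A:\n"); print.data.frame(x$only_a) }
  if (nrow(x$only_b)) { cat("only in B:\n"); print.data.frame(x$only_b) }
  invisible(x)
}
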