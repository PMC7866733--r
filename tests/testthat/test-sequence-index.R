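test_that("sequence container validates, normalizes and reports", {
  s <- iupac_seq("acgUryn*", name = "demo")
  expect_identical(as.character(s), "ACGTRYNN")
  expect_length(s, 8L)
  expect_error(iupac_seq("ACJT", name = "rec"), "'J' at position 3 in rec")
  expect_error(iupac_seq(character(0)), "length >= 1")
  rc <- reverse_complement(iupac_seq("ACGTR"))
  expect_identical(as.character(rc), "YACGT")
})

test_that("the indexed text is X . s1 . rc(X) . s2 with distinct low sentinels", {
  code <- function(x) match(x, iupac_chars())
  idx <- build_index(iupac_seq("A"))
  expect_identical(idx$text, c(code("A"), -1L, code("T"), -2L))
  expect_setequal(idx$sa, 0:3)
  # ACGT is its own reverse complement
  idx2 <- build_index(iupac_seq("ACGT"))
  expect_identical(idx2$text[1:4], idx2$text[6:9])
  expect_true(all(idx2$text[c(5, 10)] < min(code(iupac_chars()))))
  expect_identical(idx2$text[5], -1L)
  expect_identical(idx2$text[10], -2L)
})

test_that("suffix array and LCP match naive constructions on random sequences", {
  for (n in c(1L, 2L, 3L, 5L, 10L, 37L, 100L, 200L)) {
    for (sf in c(1, 0.9)) {
      s <- random_iupac_sequence(n, sf, seed = 1000L + n + round(sf * 10))
      idx <- build_index(s)
      sa <- naive_sa(idx$text)
      expect_identical(idx$sa, sa, info = sprintf("SA n=%d sf=%g", n, sf))
      expect_identical(idx$lcp, naive_lcp(idx$text, sa),
                       info = sprintf("LCP n=%d sf=%g", n, sf))
    }
  }
})

test_that("literal LCE equals a direct scan, including the identity case", {
  s <- random_iupac_sequence(150, 0.85, seed = 77)
  idx <- build_index(s)
  N <- length(idx$text)
  expect_identical(lce_literal(idx, 5, 5), N - 5L + 1L)
  set.seed(4)
  for (q in seq_len(400)) {
    i <- sample.int(N, 1)
    j <- sample.int(N, 1)
    expect_identical(lce_literal(idx, i, j), naive_lce(idx$text, i, j),
                     info = sprintf("i=%d j=%d", i, j))
  }
  expect_error(lce_literal(idx, 0, 1), "positions")
  expect_error(lce_literal(idx, 1, N + 1), "positions")
})

test_that("kangaroo walk adjudicates degenerate matches without consuming budget", {
  # X = RAC: pair 1 compares R with the symbol underlying rc-text G, i.e. C;
  # literal R != G, but R contains G = complement of C, so the walk continues
  # for free; pair 2 (A against A) is the first true mismatch.
  idx <- build_index(iupac_seq("RAC"))
  res <- kangaroo_lce(idx, 1, 1, budget = 0)
  expect_identical(res$matched_length, 1L)
  expect_identical(res$mismatch_offsets, 2L)
  # under the simple scheme the R:C pair already mismatches
  res_sim <- kangaroo_lce(idx, 1, 1, budget = 0, matrix = match_matrix("simple"))
  expect_identical(res_sim$matched_length, 0L)
  expect_identical(res_sim$mismatch_offsets, 1L)
  # fully complementary solid arms, zero budget
  idx2 <- build_index(iupac_seq("AAATTT"))
  res2 <- kangaroo_lce(idx2, 4, 4, budget = 0)
  expect_identical(res2$matched_length, 3L)
  expect_identical(res2$mismatch_offsets, integer(0))
})

test_that("kangaroo walk equals the naive matrix scan over random queries", {
  for (sf in c(1, 0.7)) {
    s <- random_iupac_sequence(60, sf, seed = 300 + round(sf * 10))
    idx <- build_index(s)
    for (scheme in c("degenerate", "simple")) {
      mm <- match_matrix(scheme)
      mmu <- unclass(mm)
      set.seed(9)
      for (q in seq_len(120)) {
        f <- sample.int(60, 1)
        rc <- sample.int(60, 1)
        b <- sample(0:4, 1)
        got <- kangaroo_lce(idx, f, rc, budget = b, matrix = mm)
        want <- naive_kangaroo(s, f, rc, b, mmu)
        expect_identical(got, want, info = sprintf("sf=%g %s f=%d rc=%d b=%d",
                                                   sf, scheme, f, rc, b))
        # structural invariants
        expect_true(all(diff(got$mismatch_offsets) > 0))
        expect_lte(length(got$mismatch_offsets), b + 1L)
      }
    }
  }
  idx <- build_index(random_iupac_sequence(20, 1, seed = 5))
  expect_error(kangaroo_lce(idx, 0, 1), "fwd_pos")
  expect_error(kangaroo_lce(idx, 1, 21), "rc_pos")
  expect_error(kangaroo_lce(idx, 1, 1, budget = -1), "budget")
})
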