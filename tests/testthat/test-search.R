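test_that("parameter validation catches contradictions before the search", {
  expect_error(search_params(min_arm = 20, max_arm = 10), "max_arm")
  expect_error(search_params(min_arm = 0), "min_arm")
  expect_error(search_params(max_gap = -1), "max_gap")
  expect_error(search_params(max_mismatch = -1), "max_mismatch")
  expect_error(search_params(scheme = "fuzzy"))
  p <- search_params(3, 10, 5, 1, "simple")
  expect_s3_class(p, "ir_params")
  expect_identical(p$scheme, "simple")
})

test_that("canonical small cases produce the expected repeats", {
  p <- search_params(min_arm = 3, max_arm = 100, max_gap = 100, max_mismatch = 0)
  irs <- find_inverted_repeats(iupac_seq("AAATTT"), p)
  expect_identical(sorted_plain(irs),
                   data.frame(left_start = 1L, left_end = 3L, right_start = 4L,
                              right_end = 6L, arm_len = 3L, gap_len = 0L,
                              mismatches = 0L))
  # ACGT is self-reverse-complementary
  irs2 <- find_inverted_repeats(iupac_seq("ACGT"),
                                search_params(2, 100, 0, 0))
  expect_identical(irs2$left_start, 1L)
  expect_identical(irs2$right_end, 4L)
  expect_identical(irs2$arm_len, 2L)
  # A never complement-matches A: a homopolymer has no inverted repeats
  polyA <- iupac_seq(strrep("A", 40))
  expect_identical(nrow(find_inverted_repeats(polyA, search_params(1, 100, 100, 2))), 0L)
  # too short to hold two minimum arms
  expect_identical(nrow(find_inverted_repeats(iupac_seq("ACGTA"),
                                              search_params(3, 100, 100, 0))), 0L)
})

test_that("gap swallowing yields one repeat per swallowed-mismatch count", {
  # built so the centre between positions 6|7 has true mismatches exactly at
  # pair offsets 2 and 4 (counting outward, 1-based)
  s <- iupac_seq("ACGTACGAAGGT")
  mm <- unclass(match_matrix("degenerate"))
  expect_identical(naive_centre_mismatches(s, 6.5, mm), c(2L, 4L))
  idx <- build_index(s)
  p <- search_params(min_arm = 1, max_arm = 100, max_gap = 100, max_mismatch = 1)
  at_centre <- enumerate_irs_at_centre(idx, 6.5, p)
  expect_identical(nrow(at_centre), 3L)
  expect_identical(sort(at_centre$gap_len), c(0L, 4L, 8L))      # even-gap centre
  expect_true(all(at_centre$mismatches <= 1L))
  expect_true(all(at_centre$left_start + at_centre$right_end == 13L)) # same centre
  # each larger gap excludes one more mismatch, permitting a new extension
  whole <- find_inverted_repeats(s, p)
  expect_true(all(ir_key(at_centre) %in% ir_key(whole)))
  expect_identical(sorted_plain(whole), sorted_plain(brute_force_find_irs(s, p)))
})

test_that("mismatch pair location agrees with a naive outward scan", {
  seqs <- list(iupac_seq("CTCGCAGTCACCGGA"),            # worked IR figure sequence
               random_iupac_sequence(41, 0.8, seed = 11))
  for (s in seqs) {
    n <- length(s)
    idx <- build_index(s)
    for (scheme in c("degenerate", "simple")) {
      mm <- match_matrix(scheme)
      mmu <- unclass(mm)
      for (centre in seq(1, n, by = 0.5)) {
        full <- naive_centre_mismatches(s, centre, mmu)
        for (needed in c(1L, 2L, 4L, 6L)) {
          got <- mismatch_pairs_for_centre(idx, centre, needed, matrix = mm)
          expect_identical(got, full[seq_len(min(needed, length(full)))],
                           info = sprintf("%s centre=%g needed=%d", scheme, centre, needed))
        }
      }
    }
  }
  idx <- build_index(iupac_seq("ACGT"))
  expect_error(mismatch_pairs_for_centre(idx, 0.5, 1), "centre")
  expect_error(mismatch_pairs_for_centre(idx, 1.25, 1), "multiple of 0.5")
  expect_error(mismatch_pairs_for_centre(idx, 2, 0), "needed")
})

test_that("the whole-sequence search is the union of the per-centre enumerations", {
  s <- random_iupac_sequence(70, 0.9, seed = 21)
  p <- search_params(2, 30, 10, 1)
  idx <- build_index(s)
  per_centre <- do.call(rbind, lapply(seq(1, 70, by = 0.5), function(ct)
    sorted_plain(enumerate_irs_at_centre(idx, ct, p))))
  expect_identical(sorted_plain(find_inverted_repeats(s, p)),
                   sorted_plain(per_centre))
})

test_that("emitted repeats survive independent re-validation", {
  s <- random_iupac_sequence(130, 0.85, seed = 33)
  for (k in c(0L, 2L)) {
    p <- search_params(2, 25, 40, k)
    irs <- find_inverted_repeats(s, p)
    expect_gt(nrow(irs), 0L)
    v <- validate_irs(s, irs, p)
    expect_true(all(as.matrix(v)))
  }
})
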