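# Naive reference constructions used as independent oracles. These never
# touch the package's suffix-array machinery: suffixes are sorted as strings,
# extensions are found by direct character scans, and centre pair profiles by
# direct matrix lookup.

# map the internal integer text (sentinels -1/-2, codes 1..15) to characters
# whose byte order preserves the integer order, so radix string sort matches
naive_text_string <- function(text) {
  alph <- c("!", "#", "%", LETTERS[1:15])
  paste(alph[text + 3L], collapse = "")
}

naive_sa <- function(text) {
  full <- naive_text_string(text)
  N <- nchar(full)
  order(substring(full, 1:N), method = "radix") - 1L # 0-based, like the index
}

naive_lcp <- function(text, sa) {
  N <- length(text)
  lcp <- integer(N)
  for (r in 2:N) {
    i <- sa[r - 1L] + 1L
    j <- sa[r] + 1L
    h <- 0L
    while (i + h <= N && j + h <= N && text[i + h] == text[j + h]) h <- h + 1L
    lcp[r] <- h
  }
  lcp
}

naive_lce <- function(text, i, j) {
  N <- length(text)
  h <- 0L
  while (i + h <= N && j + h <= N && text[i + h] == text[j + h]) h <- h + 1L
  h
}

# direct pair-by-pair kangaroo: compare X[fwd + t] with the symbol underlying
# rc(X)[rc + t], i.e. X[n - rc - t + 1], using the match matrix (1-based)
naive_kangaroo <- function(seq, fwd, rcpos, budget, mm, max_pairs = Inf) {
  ch <- iupac_chars()[seq$codes]
  n <- length(ch)
  limit <- min(n - fwd + 1L, n - rcpos + 1L, max_pairs)
  mis <- integer(0)
  t <- 0L
  while (t < limit) {
    if (!mm[ch[fwd + t], ch[n - rcpos - t + 1L]]) {
      mis <- c(mis, t + 1L)
      if (length(mis) == budget + 1L) break
    }
    t <- t + 1L
  }
  matched <- if (length(mis) == budget + 1L) mis[length(mis)] - 1L else t
  list(matched_length = matched, mismatch_offsets = mis)
}

# 1-based indices of all mismatching pairs outward from a centre
naive_centre_mismatches <- function(seq, centre, mm) {
  ch <- iupac_chars()[seq$codes]
  n <- length(ch)
  tc <- as.integer(round(2 * centre)) - 2L
  if (tc %% 2L == 0L) { l0 <- tc %/% 2L - 1L; r0 <- tc %/% 2L + 1L }
  else { l0 <- (tc - 1L) %/% 2L; r0 <- (tc + 1L) %/% 2L }
  if (l0 < 0L || r0 > n - 1L) return(integer(0))
  ts <- 0:min(l0, n - 1L - r0)
  which(!mm[cbind(ch[l0 - ts + 1L], ch[r0 + ts + 1L])])
}

ir_key <- function(d) paste(d$left_start, d$left_end, d$right_start, d$right_end)

# mirror an IR set through the centre of a length-n sequence
mirror_irs <- function(irs, n) {
  d <- data.frame(left_start = n + 1L - irs$right_end,
                  left_end = n + 1L - irs$right_start,
                  right_start = n + 1L - irs$left_end,
                  right_end = n + 1L - irs$left_start,
                  arm_len = irs$arm_len, gap_len = irs$gap_len,
                  mismatches = irs$mismatches)
  d[order(d$left_start, -d$right_end, d$gap_len), , drop = FALSE]
}

sorted_plain <- function(irs) {
  cols <- c("left_start", "left_end", "right_start", "right_end",
            "arm_len", "gap_len", "mismatches")
  d <- data.frame(lapply(cols, function(cl) as.integer(irs[[cl]])))
  names(d) <- cols
  d <- d[order(d$left_start, -d$right_end, d$gap_len), , drop = FALSE]
  rownames(d) <- NULL
  d
}
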