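#' Read one record from a FASTA file
#'
#' Reads a (possibly multi-record, line-wrapped) FASTA file and returns the
#' record whose header token — the first whitespace-delimited word after
#' `>` — equals `name`, validated and normalized to canonical IUPAC codes.
#'
#' @param path Path to a FASTA file.
#' @param name Record identifier; may be omitted when the file holds a single
#'   record. An unknown name raises an error listing the available names.
#' @return An [iupac_seq()] object.
#' @export
read_fasta <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop(sprintf("no FASTA records in %s", path), call. = FALSE)
  ids <- vapply(strsplit(names(recs), "[ \t]+"), `[`, "", 1L)
  if (is.null(name)) {
    if (length(recs) > 1L)
      stop(sprintf("file has %d records; specify one of: %s",
                   length(recs), paste(ids, collapse = ", ")), call. = FALSE)
    sel <- 1L
  } else {
    sel <- match(name, ids)
    if (is.na(sel))
      stop(sprintf("sequence '%s' not found; available: %s",
                   name, paste(ids, collapse = ", ")), call. = FALSE)
  }
  s <- gsub("[ \t\r\n]", "", as.character(recs[[sel]]))
  if (nchar(s) < 1L)
    stop(sprintf("record '%s' is empty", ids[sel]), call. = FALSE)
  iupac_seq(s, name = ids[sel])
}

# one three-line block for a single repeat, EMBOSS palindrome style:
#   <left start>    <left arm>          <left end>
#                   <alignment bars>
#   <right end>     <right arm, 3'->5'> <right start>
# The start coordinate is right-justified to the wider of the two block
# coordinates; field separators are a fixed four spaces.
.format_block <- function(chars, ls, le, rs, re, mm) {
  left <- chars[ls:le]
  partner <- chars[re:rs]
  bars <- paste(ifelse(mm[cbind(left, partner)], "|", " "), collapse = "")
  w <- max(nchar(as.character(ls)), nchar(as.character(re)))
  c(sprintf("%*d    %s    %d", w, ls, paste(left, collapse = ""), le),
    paste0(strrep(" ", w + 4L), bars),
    sprintf("%*d    %s    %d", w, re, paste(partner, collapse = ""), rs))
}

#' Write an EMBOSS-palindrome-style report
#'
#' Writes a header (sequence name, length and parameter echo, in the style of
#' the EMBOSS palindrome preamble) followed by one three-line block per
#' repeat: the left arm with its 1-based start and end positions, a line of
#' alignment bars (`|` where the symbol pair matches under `matrix`, space
#' where it mismatches), and the right arm written 3' to 5' — from its end
#' coordinate back to its start — so that the columns of the first and third
#' line are pairwise partner symbols. Blocks are separated by blank lines.
#' The output is fully deterministic.
#'
#' @param seq The [iupac_seq()] the repeats belong to.
#' @param irs An `ir_set` data frame (1-based coordinates).
#' @param path Output file path.
#' @param matrix Match matrix used for the bar line; defaults to the scheme
#'   stored in `irs`' parameters.
#' @param sidecar If `TRUE`, also write `<path>.tsv`, a tab-separated table
#'   of the coordinates (machine-readable sidecar).
#' @return Invisibly, `path`.
#' @export
write_palindrome_output <- function(seq, irs, path,
                                    matrix = NULL, sidecar = FALSE) {
  stopifnot(inherits(seq, "iupac_seq"))
  p <- attr(irs, "params")
  if (is.null(matrix)) {
    scheme <- if (!is.null(p)) p$scheme else "degenerate"
    matrix <- match_matrix(scheme)
  }
  mm <- unclass(matrix)
  chars <- .IUPAC[seq$codes]
  n <- length(chars)
  hdr <- c(paste0("Palindromes of: ", seq$name),
           paste0("Sequence length is: ", n),
           "Start at position: 1",
           paste0("End at position: ", n),
           if (!is.null(p)) c(
             paste0("Minimum length of Palindromes is: ", p$min_arm),
             paste0("Maximum length of Palindromes is: ", p$max_arm),
             paste0("Maximum gap between elements is: ", p$max_gap),
             paste0("Number of mismatches allowed in Palindrome: ", p$max_mismatch),
             paste0("Matching scheme: ", p$scheme)),
           "", "Palindromes:")
  blocks <- character(0)
  if (nrow(irs)) {
    blocks <- unlist(lapply(seq_len(nrow(irs)), function(i) {
      c(.format_block(chars, irs$left_start[i], irs$left_end[i],
                      irs$right_start[i], irs$right_end[i], mm), "")
    }))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, blocks), con)
  if (sidecar) {
    utils::write.table(as.data.frame(irs), paste0(path, ".tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Parse an inverted-repeat report back to coordinates
#'
#' Inverse of [write_palindrome_output()]: reads either a block-format report
#' or its tab-separated sidecar and returns the 1-based coordinates, arm and
#' gap lengths, and the mismatch count recovered from the bar lines.
#'
#' @param path Path to a report file.
#' @return A data frame with columns `left_start`, `left_end`, `right_start`,
#'   `right_end`, `arm_len`, `gap_len`, `mismatches`.
#' @export
parse_palindrome_output <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  empty <- data.frame(left_start = integer(0), left_end = integer(0),
                      right_start = integer(0), right_end = integer(0),
                      arm_len = integer(0), gap_len = integer(0),
                      mismatches = integer(0))
  if (length(lines) && grepl("^left_start\t", lines[1L])) {
    df <- utils::read.table(path, header = TRUE, sep = "\t")
    return(df[, names(empty), drop = FALSE])
  }
  start <- match("Palindromes:", lines)
  body <- if (is.na(start)) lines else lines[-seq_len(start)]
  arm_re <- "^(\\s*)(\\d+)(\\s+)(\\S+)\\s+(\\d+)\\s*$"
  rows <- empty
  i <- 1L
  while (i <= length(body)) {
    if (!nzchar(trimws(body[i]))) { i <- i + 1L; next }
    if (i + 2L > length(body))
      stop(sprintf("malformed block at line %d: truncated", i + (start %||% 0L)),
           call. = FALSE)
    l1 <- body[i]; l2 <- body[i + 1L]; l3 <- body[i + 2L]
    if (!grepl(arm_re, l1) || !grepl(arm_re, l3))
      stop(sprintf("malformed block at line %d", i + (start %||% 0L)), call. = FALSE)
    g1 <- regmatches(l1, regexec(arm_re, l1))[[1L]]
    g3 <- regmatches(l3, regexec(arm_re, l3))[[1L]]
    arm <- g1[5L]
    arm_col <- nchar(g1[2L]) + nchar(g1[3L]) + nchar(g1[4L]) + 1L
    bars <- substr(paste0(l2, strrep(" ", nchar(arm))), arm_col,
                   arm_col + nchar(arm) - 1L)
    ls <- as.integer(g1[3L]); le <- as.integer(g1[6L])
    rend <- as.integer(g3[3L]); rstart <- as.integer(g3[6L])
    rows <- rbind(rows, data.frame(
      left_start = ls, left_end = le, right_start = rstart, right_end = rend,
      arm_len = le - ls + 1L, gap_len = rstart - le - 1L,
      mismatches = nchar(arm) - lengths(regmatches(bars, gregexpr("|", bars, fixed = TRUE)))))
    i <- i + 3L
  }
  rownames(rows) <- NULL
  rows
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
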