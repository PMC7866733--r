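#' IUPAC-encoded DNA sequence
#'
#' Validates and stores a DNA sequence over the 15-letter IUPAC alphabet.
#' Input is normalized first (`U -> T`, `* -> N`, case folded); any other
#' character is an error reporting its position. Internally the sequence is
#' kept as integer codes in alphabetical IUPAC order.
#'
#' @param x A single string, or a character vector of single characters.
#' @param name Record identifier (default `"seq"`).
#' @return An object of class `iupac_seq`: a list with elements `name` and
#'   `codes` (integer vector, one code per position).
#' @examples
#' s <- iupac_seq("ACGTRYN", name = "demo")
#' length(s)
#' as.character(s)
#' @export
iupac_seq <- function(x, name = "seq") {
  if (length(x) == 1L && nchar(x) != 1L) x <- strsplit(x, "", fixed = TRUE)[[1]]
  if (length(x) < 1L) stop("sequence must have length >= 1", call. = FALSE)
  chars <- normalize_iupac(x, context = name)
  structure(list(name = as.character(name), codes = .iupac_code(chars)),
            class = "iupac_seq")
}

#' @export
length.iupac_seq <- function(x) length(x$codes)

#' @export
as.character.iupac_seq <- function(x, ...) paste(.IUPAC[x$codes], collapse = "")

#' @export
print.iupac_seq <- function(x, ...) {
  n <- length(x$codes)
  solid <- sum(.IUPAC[x$codes] %in% c("A", "C", "G", "T"))
  cat(sprintf("IUPAC sequence '%s': %d symbols (%d solid, %d degenerate)\n",
              x$name, n, solid, n - solid))
  s <- as.character(x)
  if (n > 60) s <- paste0(substr(s, 1, 60), "...")
  cat(" ", s, "\n")
  invisible(x)
}

#' Reverse complement of an IUPAC sequence
#'
#' Applies the simple (unique-symbol) complement at every position and
#' reverses, e.g. `rc("ACGTR") = "YACGT"`.
#'
#' @param seq An [iupac_seq()] object.
#' @return An `iupac_seq` of the same length.
#' @export
reverse_complement <- function(seq) {
  stopifnot(inherits(seq, "iupac_seq"))
  structure(list(name = paste0(seq$name, "_rc"),
                 codes = rev(.COMP_CODE[seq$codes])),
            class = "iupac_seq")
}
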