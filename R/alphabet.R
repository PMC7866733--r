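#' @useDynLib irscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# The 15 IUPAC nucleotide codes as nonempty subsets of {A,C,G,T},
# alphabetical code order. This order fixes the integer encoding (1..15)
# used everywhere else in the package.
.IUPAC_BASES <- list(
  A = "A",
  B = c("C", "G", "T"),
  C = "C",
  D = c("A", "G", "T"),
  G = "G",
  H = c("A", "C", "T"),
  K = c("G", "T"),
  M = c("A", "C"),
  N = c("A", "C", "G", "T"),
  R = c("A", "G"),
  S = c("C", "G"),
  T = "T",
  V = c("A", "C", "G"),
  W = c("A", "T"),
  Y = c("C", "T")
)

.IUPAC <- names(.IUPAC_BASES)

.DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A")

# set -> code lookup (key: sorted bases pasted together)
.SET_KEY <- vapply(.IUPAC_BASES, function(s) paste(sort(s), collapse = ""), "")

# simple (unique-symbol) complement of each code: complement the base set
# elementwise, then map the resulting set back to its code. An involution.
.IUPAC_COMP <- vapply(.IUPAC_BASES, function(s) {
  key <- paste(sort(unname(.DNA_COMP[s])), collapse = "")
  .IUPAC[match(key, .SET_KEY)]
}, "")

# integer code of each IUPAC character
.iupac_code <- function(chars) match(chars, .IUPAC)

# complement as a code permutation, used to build the reverse-complement text
.COMP_CODE <- match(.IUPAC_COMP, .IUPAC)

#' The IUPAC nucleotide alphabet
#'
#' `iupac_chars()` returns the 15 canonical IUPAC nucleotide codes;
#' `iupac_base_sets()` returns, for each code, the nonempty subset of
#' `{A,C,G,T}` it stands for (e.g. `R` = purine = `{A,G}`, `N` = any base).
#' The aliases `U` (for `T`) and `*` (for `N`) are accepted on input by
#' [normalize_iupac()] but never appear in canonical form.
#'
#' @return A character vector of length 15, or a named list of base sets.
#' @examples
#' iupac_chars()
#' iupac_base_sets()$B
#' @export
iupac_chars <- function() .IUPAC

#' @rdname iupac_chars
#' @export
iupac_base_sets <- function() .IUPAC_BASES

#' Normalize characters to canonical IUPAC codes
#'
#' Folds lower case to upper case and applies the aliases `U -> T` and
#' `* -> N`. Any character outside the IUPAC alphabet raises an error naming
#' the character and its (1-based) position, prefixed with `context` when the
#' caller supplies one (e.g. a FASTA record name).
#'
#' @param x Character vector of single characters.
#' @param context Optional string describing where `x` came from, used in
#'   error messages.
#' @return Character vector of canonical IUPAC codes, same length as `x`.
#' @examples
#' normalize_iupac(c("u", "n", "a"))
#' @export
normalize_iupac <- function(x, context = NULL) {
  up <- toupper(as.character(x))
  up[up == "U"] <- "T"
  up[up == "*"] <- "N"
  bad <- which(!(up %in% .IUPAC))
  if (length(bad)) {
    where <- if (is.null(context)) "" else paste0(" in ", context)
    stop(sprintf("invalid IUPAC symbol '%s' at position %d%s",
                 x[bad[1]], bad[1], where), call. = FALSE)
  }
  up
}

#' Simple (unique-symbol) complement of IUPAC codes
#'
#' Complements each code's base set elementwise under the Watson-Crick map
#' `A <-> T`, `C <-> G`; the result is always another IUPAC code (the map is
#' an involution on the alphabet, e.g. `B <-> V`, `N <-> N`).
#'
#' @param x Character vector of IUPAC symbols (aliases and lower case
#'   accepted).
#' @return Character vector of complement codes.
#' @examples
#' iupac_complement(c("A", "B", "R", "N"))
#' @export
iupac_complement <- function(x) {
  unname(.IUPAC_COMP[normalize_iupac(x)])
}

#' Complement-match matrix over the IUPAC alphabet
#'
#' Builds the 15x15 boolean relation saying which pairs of IUPAC symbols are
#' considered complementary, under one of two schemes:
#'
#' * `"simple"`: each symbol has a single unique complement (elementwise
#'   complement of its base set); `a` matches `b` iff `b` is exactly that
#'   complement symbol. This is the EMBOSS palindrome convention.
#' * `"degenerate"`: `a` matches `b` iff some base in `a`'s set is the
#'   Watson-Crick complement of some base in `b`'s set, i.e. the sets admit at
#'   least one complementary base pairing (so e.g. `R` = `{A,G}` matches `C`
#'   because `R` contains `G`).
#'
#' Both relations are symmetric, the simple relation is a subset of the
#' degenerate one, and restricted to the solid bases `A,C,G,T` the two
#' coincide (exactly the pairs A:T and C:G). The search algorithm is
#' matrix-agnostic: any symmetric logical 15x15 matrix with IUPAC dimnames can
#' be passed where a match matrix is expected.
#'
#' @param scheme `"degenerate"` (default) or `"simple"`.
#' @return A logical 15x15 matrix with IUPAC dimnames, class
#'   `iupac_match_matrix`, attribute `scheme`.
#' @examples
#' mm <- match_matrix("degenerate")
#' mm["R", "C"]   # TRUE: R contains G, the complement of C
#' match_matrix("simple")["R", "C"]  # FALSE
#' @export
match_matrix <- function(scheme = c("degenerate", "simple")) {
  scheme <- match.arg(scheme)
  m <- matrix(FALSE, 15L, 15L, dimnames = list(.IUPAC, .IUPAC))
  if (scheme == "simple") {
    for (a in .IUPAC) m[a, .IUPAC_COMP[[a]]] <- TRUE
  } else {
    for (a in .IUPAC) {
      comp_a <- unname(.DNA_COMP[.IUPAC_BASES[[a]]])
      for (b in .IUPAC) {
        m[a, b] <- length(intersect(comp_a, .IUPAC_BASES[[b]])) > 0L
      }
    }
  }
  structure(m, scheme = scheme, class = c("iupac_match_matrix", "matrix", "array"))
}

# coerce a user-supplied matrix to the integer 0/1 form the C++ core expects
.mat_codes <- function(mat) {
  if (is.null(mat)) mat <- match_matrix("degenerate")
  m <- unclass(mat)
  if (!is.matrix(m) || !all(dim(m) == c(15L, 15L)))
    stop("match matrix must be a 15x15 logical matrix", call. = FALSE)
  if (!is.null(rownames(m)) && !identical(rownames(m), .IUPAC))
    m <- m[.IUPAC, .IUPAC]
  storage.mode(m) <- "integer"
  # C++ indexes row-major by first symbol
  as.integer(t(m))
}
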