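# Nucleotide alphabet: A,C,G,T plus U (stored as T), the IUPAC ambiguity codes
# and inosine (I). Symbols are encoded as 4-bit masks (A=1, C=2, G=4, T=8) so
# that two symbols are compatible iff their masks intersect.

NT_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L, I = 15L
)

NT_ALPHABET <- names(NT_MASK)

# complement table; I is its own complement (pairs with everything either way)
NT_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", U = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N", I = "I"
)

#' Expand a nucleotide symbol to its set of concrete bases
#'
#' IUPAC ambiguity codes expand to their defined base sets (R = \{A,G\},
#' N = \{A,C,G,T\}, ...). Inosine (`I`), a universal-pairing base used in
#' degenerate primers such as FR1, expands to all four bases. `U` expands
#' to `T`.
#'
#' @param symbol single character in the accepted alphabet.
#' @return Character vector: subset of `c("A","C","G","T")`.
#' @examples
#' base_set("R")
#' base_set("I")
#' @export
base_set <- function(symbol) {
  stopifnot(is.character(symbol), length(symbol) == 1L)
  if (nchar(symbol) != 1L) stop("expected a single symbol, got '", symbol, "'")
  m <- NT_MASK[toupper(symbol)]
  if (is.na(m)) stop("unknown nucleotide symbol: '", symbol, "'")
  c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
}

# Encode a residue string as an integer mask vector, validating the alphabet.
# Errors name the offending symbol and its 1-based position.
encode_residues <- function(residues, id = NULL) {
  chars <- strsplit(toupper(residues), "", fixed = TRUE)[[1L]]
  m <- unname(NT_MASK[chars])
  if (anyNA(m)) {
    pos <- which(is.na(m))[1L]
    stop("illegal symbol '", chars[pos], "' at position ", pos,
         if (!is.null(id)) paste0(" in sequence '", id, "'") else "")
  }
  m
}

# Uppercase and normalize U -> T; validates nothing else.
normalize_residues <- function(residues) {
  chartr("U", "T", toupper(residues))
}

#' Reverse complement of a nucleotide string
#'
#' Works over the full alphabet: ambiguity codes map to their complementary
#' codes (R to Y, B to V, ...), `S`, `W` and `N` are self-complementary, and
#' inosine (`I`) complements to itself. Vectorized over its argument.
#'
#' @param seq character vector of sequences over the accepted alphabet.
#' @return Character vector of reverse-complemented sequences (uppercase).
#' @examples
#' reverse_complement("AAR")   # "YTT"
#' reverse_complement("ACGT")  # "ACGT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  up <- toupper(seq)
  bad <- gsub(paste0("[", paste(NT_ALPHABET, collapse = ""), "]"), "", up)
  if (any(nzchar(bad))) {
    stop("unknown symbol(s) in sequence: '",
         substr(bad[nzchar(bad)][1L], 1L, 1L), "'")
  }
  flipped <- chartr(paste(NT_ALPHABET, collapse = ""),
                    paste(NT_COMPLEMENT, collapse = ""), up)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1L))
}

#' Count mismatches between a primer window and a target window
#'
#' A position mismatches when the base sets of the two symbols do not
#' intersect (optimistic matching, the usual in-silico PCR convention). With
#' `strict = TRUE` a position matches only when the target symbol's base set
#' is contained in the primer symbol's set, so an `N` in the target no longer
#' matches a specific primer base.
#'
#' @param primer_window,target_window equal-length strings over the alphabet.
#' @param strict logical; use containment instead of intersection matching.
#' @return Integer mismatch count (Hamming-style; substitutions only).
#' @examples
#' mismatch_count("ACGT", "ACGT")  # 0
#' mismatch_count("R", "C")        # 1
#' @export
mismatch_count <- function(primer_window, target_window, strict = FALSE) {
  p <- encode_residues(primer_window)
  t <- encode_residues(target_window)
  if (length(p) != length(t)) {
    stop("windows differ in length (", length(p), " vs ", length(t), ")")
  }
  if (strict) {
    sum(bitwAnd(t, bitwAnd(bitwNot(p), 15L)) != 0L)
  } else {
    sum(bitwAnd(p, t) == 0L)
  }
}

# Evaluate `code` under a temporary RNG state seeded with `seed`
# (restores the caller's .Random.seed afterwards). NULL seed = no-op.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
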