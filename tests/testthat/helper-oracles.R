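# Independent oracles and fixture builders shared across the test files.

# IUPAC expansion oracle from Biostrings' code map (independent of the
# package's own mask table); inosine treated as universal, U as T.
oracle_sets <- local({
  map <- lapply(as.list(Biostrings::IUPAC_CODE_MAP),
                function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  map$I <- c("A", "C", "G", "T")
  map$U <- "T"
  map
})

oracle_mismatch <- function(primer, window) {
  p <- strsplit(primer, "", fixed = TRUE)[[1L]]
  w <- strsplit(window, "", fixed = TRUE)[[1L]]
  stopifnot(length(p) == length(w))
  sum(mapply(function(a, b) {
    length(intersect(oracle_sets[[a]], oracle_sets[[b]])) == 0L
  }, p, w))
}

# brute-force all-window scan of a literal primer text on one sequence
oracle_scan_text <- function(text, seq, k_max) {
  m <- nchar(text)
  L <- nchar(seq)
  out <- list()
  if (L >= m) {
    for (s in seq_len(L - m + 1L)) {
      mm <- oracle_mismatch(text, substr(seq, s, s + m - 1L))
      if (mm <= k_max) {
        out[[length(out) + 1L]] <- data.frame(start = s, end = s + m - 1L,
                                              mismatches = mm)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else {
    data.frame(start = integer(0L), end = integer(0L),
               mismatches = integer(0L))
  }
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

ff390 <- function() primer_spec("FF390", "CGATAACGAACGAGACCT", "forward")
fr1 <- function() primer_spec("FR1", "AICCATTCAATCGGTAIT", "reverse")
fr1_ff390 <- function() primer_set_spec("FR1_FF390", ff390(), fr1())

# standard 3-group planted community used by several screening tests
demo_community <- function(seed = 42L, n = 20L) {
  make_community_db(
    list(group_spec("Asco", n, 600L, is_fungal = TRUE,
                    fwd_prop = 0.9, rev_prop = 0.9),
         group_spec("Basidio", n, 600L, is_fungal = TRUE,
                    fwd_prop = 0.5, rev_prop = 0.5),
         group_spec("Metazoa", n, 600L, is_fungal = FALSE, fwd_prop = 0)),
    fr1_ff390(), seed = seed)
}
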