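# Mismatch-tolerant primer search and amplicon prediction.
#
# Coordinates are 1-based and inclusive throughout (the R/Biostrings
# convention): a site of an m-mer primer starting at `start` ends at
# `end = start + m - 1`, and a primer-inclusive product spanning
# [product_start, product_end] has length product_end - product_start + 1.

#' Define a degenerate primer
#'
#' @param name primer name.
#' @param sequence 5'-to-3' sequence over ACGT, IUPAC ambiguity codes and
#'   inosine (`I`); at least 10 nt. `U` is normalized to `T`.
#' @param orientation `"forward"` or `"reverse"` (relative to the sense strand
#'   of the target gene).
#' @return Object of class `primer_spec`.
#' @examples
#' primer_spec("FF390", "CGATAACGAACGAGACCT", "forward")
#' primer_spec("FR1", "AICCATTCAATCGGTAIT", "reverse")
#' @export
primer_spec <- function(name, sequence, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- normalize_residues(sequence)
  encode_residues(sequence, id = name)
  if (nchar(sequence) < 10L) {
    stop("primer '", name, "' is shorter than 10 nt")
  }
  structure(list(name = name, sequence = sequence, orientation = orientation),
            class = "primer_spec")
}

#' @export
print.primer_spec <- function(x, ...) {
  cat(sprintf("Primer %s (%s): 5'-%s-3' [%d nt]\n",
              x$name, x$orientation, x$sequence, nchar(x$sequence)))
  invisible(x)
}

#' Define a primer set (one forward + one reverse primer)
#'
#' @param name set name.
#' @param forward,reverse [primer_spec()] objects with matching orientations.
#' @return Object of class `primer_set_spec`.
#' @export
primer_set_spec <- function(name, forward, reverse) {
  stopifnot(inherits(forward, "primer_spec"), inherits(reverse, "primer_spec"))
  if (forward$orientation != "forward") {
    stop("'forward' primer of set '", name, "' has orientation ",
         forward$orientation)
  }
  if (reverse$orientation != "reverse") {
    stop("'reverse' primer of set '", name, "' has orientation ",
         reverse$orientation)
  }
  structure(list(name = name, forward = forward, reverse = reverse),
            class = "primer_set_spec")
}

#' @export
print.primer_set_spec <- function(x, ...) {
  cat(sprintf("Primer set %s: %s / %s\n", x$name,
              x$forward$name, x$reverse$name))
  invisible(x)
}

# Search texts (as mask vectors) for a primer, keyed by the strand of the
# stored sequence on which the primer's written 5'->3' text aligns.
primer_search_texts <- function(primer, search_mode) {
  as_written <- encode_residues(primer$sequence)
  flipped <- encode_residues(reverse_complement(primer$sequence))
  if (primer$orientation == "forward") {
    texts <- list(sense = as_written)
    if (search_mode == "auto_both") texts$antisense <- flipped
  } else {
    texts <- list(antisense = flipped)
    if (search_mode == "auto_both") texts$sense <- as_written
  }
  texts
}

# All full-length windows of mask vector s matching mask vector p at
# <= k_max mismatches. Returns 1-based inclusive coordinates.
window_hits <- function(p, s, k_max, strict = FALSE) {
  m <- length(p)
  n <- length(s) - m + 1L
  if (n < 1L) {
    return(data.frame(start = integer(0L), end = integer(0L),
                      mismatches = integer(0L)))
  }
  mism <- integer(n)
  offs <- 0L:(n - 1L)
  notmask <- bitwAnd(bitwNot(p), 15L)
  for (j in seq_len(m)) {
    tj <- s[offs + j]
    bad <- if (strict) bitwAnd(tj, notmask[j]) != 0L else bitwAnd(tj, p[j]) == 0L
    mism <- mism + bad
  }
  keep <- which(mism <= k_max)
  data.frame(start = keep, end = keep + m - 1L, mismatches = mism[keep])
}

#' Scan sequences for primer binding sites
#'
#' Finds every full-length (no-overhang) alignment of the primer with at most
#' `k_max` mismatches, under substitution-only (Hamming) counting. Forward
#' primers are searched as written on the stored (sense) strand; reverse
#' primers are searched as their reverse complement, i.e. their text aligns on
#' the antisense strand. With `search_mode = "auto_both"` the opposite
#' representation is searched as well, for collections whose strand is
#' unknown.
#'
#' @param primer a [primer_spec()].
#' @param seqs named character vector of sequences or a [seq_collection()].
#' @param k_max maximum mismatches allowed (>= 0).
#' @param search_mode `"sense_only"` (default; SSU gene databases store sense
#'   strands) or `"auto_both"`.
#' @param strict use containment matching for target ambiguity codes (see
#'   [mismatch_count()]).
#' @return `data.frame` with columns `sequence_id`, `start`, `end` (1-based
#'   inclusive), `strand` (strand on which the primer text aligns) and
#'   `mismatches`, sorted by sequence, start, then mismatches. Sequences
#'   shorter than the primer contribute no rows and raise a warning.
#' @export
scan_primer <- function(primer, seqs, k_max = 0L,
                        search_mode = c("sense_only", "auto_both"),
                        strict = FALSE) {
  search_mode <- match.arg(search_mode)
  stopifnot(inherits(primer, "primer_spec"),
            is.numeric(k_max), length(k_max) == 1L, k_max >= 0)
  if (inherits(seqs, "seq_collection")) seqs <- seqs$seqs
  stopifnot(is.character(seqs))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))

  plen <- nchar(primer$sequence)
  texts <- primer_search_texts(primer, search_mode)
  empty <- data.frame(sequence_id = character(0L), start = integer(0L),
                      end = integer(0L), strand = character(0L),
                      mismatches = integer(0L), stringsAsFactors = FALSE)
  pieces <- lapply(names(seqs), function(id) {
    if (nchar(seqs[[id]]) < plen) {
      warning("primer '", primer$name, "' is longer than sequence '", id, "'")
      return(empty)
    }
    s <- encode_residues(seqs[[id]], id = id)
    hits <- lapply(names(texts), function(strand) {
      h <- window_hits(texts[[strand]], s, k_max, strict)
      if (!nrow(h)) return(empty)
      data.frame(sequence_id = id, start = h$start, end = h$end,
                 strand = strand, mismatches = h$mismatches,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, hits)
  })
  out <- do.call(rbind, pieces)
  if (!nrow(out)) return(empty)
  ord <- order(match(out$sequence_id, names(seqs)), out$start, out$mismatches)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict amplicons of a primer set on sequences
#'
#' Each forward site (primer text on the sense strand) is paired with the
#' nearest downstream antisense site of the reverse primer; the product is
#' primer-inclusive, spanning from the forward site's start to the reverse
#' site's end. Primer sites may not overlap (the reverse site must start at or
#' after the forward site's end + 1). With `search_mode = "auto_both"`,
#' mirror-image pairs on the antisense strand are predicted as well, so
#' predictions are invariant under reverse-complementing a record.
#'
#' @inheritParams scan_primer
#' @param pset a [primer_set_spec()].
#' @param k_max maximum mismatches allowed per primer.
#' @return `data.frame` with one row per predicted product: `sequence_id`,
#'   `fwd_start`, `fwd_end`, `fwd_mismatches`, `rev_start`, `rev_end`,
#'   `rev_mismatches`, `product_start`, `product_end`, `product_length`,
#'   `strand` (strand carrying the forward primer text). Empty when no valid
#'   pairing exists.
#' @export
predict_amplicons <- function(pset, seqs, k_max = 0L,
                              search_mode = c("sense_only", "auto_both"),
                              strict = FALSE) {
  search_mode <- match.arg(search_mode)
  stopifnot(inherits(pset, "primer_set_spec"))
  if (inherits(seqs, "seq_collection")) seqs <- seqs$seqs
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  fwd <- scan_primer(pset$forward, seqs, k_max, search_mode, strict)
  rev <- scan_primer(pset$reverse, seqs, k_max, search_mode, strict)

  empty <- data.frame(
    sequence_id = character(0L), fwd_start = integer(0L),
    fwd_end = integer(0L), fwd_mismatches = integer(0L),
    rev_start = integer(0L), rev_end = integer(0L),
    rev_mismatches = integer(0L), product_start = integer(0L),
    product_end = integer(0L), product_length = integer(0L),
    strand = character(0L), stringsAsFactors = FALSE
  )

  pair_up <- function(id, f, r, strand) {
    # f: sites whose text is 5' on this strand; r: the partner sites.
    # On "sense": forward text sites paired downstream with reverse antisense
    # sites. On "antisense": reverse text (sense) sites lie 5' of forward
    # antisense sites; product runs from the reverse site to the forward site.
    rows <- lapply(seq_len(nrow(f)), function(i) {
      cand <- r[r$start >= f$end[i] + 1L, , drop = FALSE]
      if (!nrow(cand)) return(NULL)
      j <- which.min(cand$start)
      if (strand == "sense") {
        data.frame(sequence_id = id,
                   fwd_start = f$start[i], fwd_end = f$end[i],
                   fwd_mismatches = f$mismatches[i],
                   rev_start = cand$start[j], rev_end = cand$end[j],
                   rev_mismatches = cand$mismatches[j],
                   product_start = f$start[i], product_end = cand$end[j],
                   stringsAsFactors = FALSE)
      } else {
        data.frame(sequence_id = id,
                   fwd_start = cand$start[j], fwd_end = cand$end[j],
                   fwd_mismatches = cand$mismatches[j],
                   rev_start = f$start[i], rev_end = f$end[i],
                   rev_mismatches = f$mismatches[i],
                   product_start = f$start[i], product_end = cand$end[j],
                   stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, rows)
  }

  pieces <- lapply(names(seqs), function(id) {
    fs <- fwd[fwd$sequence_id == id, , drop = FALSE]
    rs <- rev[rev$sequence_id == id, , drop = FALSE]
    out <- pair_up(id, fs[fs$strand == "sense", , drop = FALSE],
                   rs[rs$strand == "antisense", , drop = FALSE], "sense")
    if (!is.null(out) && nrow(out)) out$strand <- "sense"
    if (search_mode == "auto_both") {
      flip <- pair_up(id, rs[rs$strand == "sense", , drop = FALSE],
                      fs[fs$strand == "antisense", , drop = FALSE], "antisense")
      if (!is.null(flip) && nrow(flip)) {
        flip$strand <- "antisense"
        out <- rbind(out, flip)
      }
    }
    out
  })
  out <- do.call(rbind, pieces)
  if (is.null(out) || !nrow(out)) return(empty)
  out$product_length <- out$product_end - out$product_start + 1L
  out <- out[out$product_length > 0L, , drop = FALSE]
  out <- out[, names(empty)]
  rownames(out) <- NULL
  out
}
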