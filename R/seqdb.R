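# Reading, validating and grouping taxonomically annotated sequence
# collections. Sequences are stored as uppercase character strings (U
# normalized to T) so that inosine and all IUPAC codes are representable.

#' Read a FASTA file into a named vector of normalized sequences
#'
#' Residues are uppercased and `U` is normalized to `T`; every symbol must be
#' in the accepted alphabet (ACGT, IUPAC ambiguity codes, inosine). Entry
#' order is preserved and ids must be unique.
#'
#' @param path path to a FASTA file (multi-line sequences allowed).
#' @return Named character vector of sequences (names are the FASTA ids, the
#'   first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       set.attributes = FALSE),
    error = function(e) list()
  )
  if (length(raw) == 0L) {
    warning("empty FASTA file: ", path)
    return(character(0L))
  }
  ids <- names(raw)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  seqs <- normalize_residues(unlist(raw, use.names = FALSE))
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[[i]])) stop("empty sequence for id '", ids[[i]], "'")
    encode_residues(seqs[[i]], id = ids[[i]])
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param line_width residues per line.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path, line_width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  seqinr::write.fasta(as.list(unname(seqs)), names(seqs), file.out = path,
                      nbchar = line_width)
  invisible(path)
}

#' Load a taxonomy table and assign one group label per sequence
#'
#' Reads a two-column TSV (`id<TAB>lineage`, lineage as semicolon-separated
#' taxon labels, root first, Silva style). The group label is taken either
#' from a fixed lineage `rank` (1 = root) or from an explicit `group_map`
#' (named character vector, taxon -> group label; the deepest lineage taxon
#' present in the map wins). Sequences whose lineage is shorter than the
#' requested rank fall back to their deepest label and are flagged; with a
#' `group_map`, lineages with no mapped taxon get `NA` and are flagged.
#'
#' @param path taxonomy TSV; `#`-prefixed lines are ignored.
#' @param rank integer lineage position to aggregate at.
#' @param group_map named character vector mapping taxon to group label.
#' @return `data.frame` with columns `id`, `lineage`, `group_label`, `flagged`.
#' @export
load_taxonomy <- function(path, rank = NULL, group_map = NULL) {
  if (is.null(rank) && is.null(group_map)) {
    stop("provide an aggregation 'rank' or an explicit 'group_map'")
  }
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lineno <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("malformed taxonomy line ", lineno[bad[1L]],
         ": expected 'id<TAB>lineage'")
  }
  ids <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate taxonomy id(s): ", ids[duplicated(ids)][1L])
  }
  lineages <- lapply(strsplit(vapply(parts, `[[`, character(1L), 2L),
                              ";", fixed = TRUE), trimws)
  empty <- which(vapply(lineages, function(l) !length(l) || !any(nzchar(l)),
                        logical(1L)))
  if (length(empty)) stop("empty lineage at line ", lineno[empty[1L]])

  pick <- function(lin) {
    if (!is.null(group_map)) {
      hit <- lin[lin %in% names(group_map)]
      if (length(hit)) {
        list(label = unname(group_map[[hit[length(hit)]]]), flagged = FALSE)
      } else {
        list(label = NA_character_, flagged = TRUE)
      }
    } else if (length(lin) >= rank) {
      list(label = lin[[rank]], flagged = FALSE)
    } else {
      list(label = lin[[length(lin)]], flagged = TRUE)
    }
  }
  picked <- lapply(lineages, pick)
  data.frame(
    id = ids,
    lineage = vapply(lineages, paste, character(1L), collapse = ";"),
    group_label = vapply(picked, function(p) p$label, character(1L)),
    flagged = vapply(picked, function(p) p$flagged, logical(1L)),
    stringsAsFactors = FALSE
  )
}

#' Build an annotated sequence collection
#'
#' Bundles sequences with their taxonomy assignments and derives the group
#' structure (one group per sequence at the chosen rank). Sequences without a
#' taxonomy entry (or with an `NA` group label) are kept but listed as
#' unassigned and excluded from every group denominator.
#'
#' @param seqs named character vector of sequences (as from [read_fasta()]).
#' @param taxonomy optional `data.frame` from [load_taxonomy()].
#' @param min_length_applied record of a previously applied length filter.
#' @return An object of class `seq_collection`: a list with elements `seqs`,
#'   `taxonomy`, `groups` (named list of id vectors), `unassigned`,
#'   `min_length_applied`.
#' @export
seq_collection <- function(seqs, taxonomy = NULL,
                           min_length_applied = NA_integer_) {
  stopifnot(is.character(seqs))
  if (length(seqs) && (is.null(names(seqs)) || any(!nzchar(names(seqs))))) {
    stop("sequences must be named by id")
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence id(s): ",
         names(seqs)[duplicated(names(seqs))][1L])
  }
  seqs <- normalize_residues(seqs)
  if (length(seqs)) names(seqs) <- names(seqs)  # keep names after chartr
  if (is.null(taxonomy)) {
    taxonomy <- data.frame(id = character(0L), lineage = character(0L),
                           group_label = character(0L), flagged = logical(0L),
                           stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "group_label") %in% names(taxonomy)))
  taxonomy <- taxonomy[taxonomy$id %in% names(seqs) &
                         !is.na(taxonomy$group_label), , drop = FALSE]
  rownames(taxonomy) <- NULL
  groups <- split(taxonomy$id, taxonomy$group_label)
  structure(
    list(seqs = seqs, taxonomy = taxonomy, groups = groups,
         unassigned = setdiff(names(seqs), taxonomy$id),
         min_length_applied = min_length_applied),
    class = "seq_collection"
  )
}

#' @export
print.seq_collection <- function(x, ...) {
  cat("Annotated sequence collection:", length(x$seqs), "sequences,",
      length(x$groups), "groups,", length(x$unassigned), "unassigned\n")
  if (!is.na(x$min_length_applied)) {
    cat("  length filter applied: >=", x$min_length_applied, "nt\n")
  }
  if (length(x$groups)) {
    sz <- group_sizes(x)
    cat("  ", paste(names(sz), sz, sep = ": ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Group sizes of a collection
#'
#' @param db a `seq_collection`.
#' @return Named integer vector of assigned-sequence counts per group.
#' @export
group_sizes <- function(db) {
  stopifnot(inherits(db, "seq_collection"))
  vapply(db$groups, length, integer(1L))
}

#' Drop sequences shorter than a minimum length
#'
#' Very short entries in public SSU databases carry too little signal for
#' primer-site screening; the default elsewhere in this package is to require
#' 900 nt for SSU collections. Group memberships and counts are rebuilt
#' consistently and the threshold is recorded in the returned collection so
#' report denominators stay auditable. Idempotent at a fixed threshold.
#'
#' @param db a `seq_collection`.
#' @param min_length minimum sequence length in nt (>= 0).
#' @return A filtered `seq_collection` with `min_length_applied` set.
#' @export
apply_length_filter <- function(db, min_length) {
  stopifnot(inherits(db, "seq_collection"),
            is.numeric(min_length), length(min_length) == 1L, min_length >= 0)
  keep <- nchar(db$seqs) >= min_length
  seq_collection(db$seqs[keep], db$taxonomy,
                 min_length_applied = as.integer(min_length))
}

#' Read a primer list from TSV
#'
#' Expects a header line `name<TAB>sequence<TAB>orientation` with orientation
#' `forward` or `reverse`.
#'
#' @param path primer TSV path.
#' @return Named list of [primer_spec()] objects.
#' @export
read_primers <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "sequence", "orientation")
  if (!all(need %in% names(tab))) {
    stop("primer TSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    primer_spec(tab$name[i], tab$sequence[i], tab$orientation[i])
  })
  names(out) <- tab$name
  out
}

#' Read primer-set definitions from TSV
#'
#' Expects a header line `set<TAB>forward_name<TAB>reverse_name`; primer names
#' must exist in `primers`.
#'
#' @param path primer-set TSV path.
#' @param primers named list of [primer_spec()] objects.
#' @return Named list of [primer_set_spec()] objects.
#' @export
read_primer_sets <- function(path, primers) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("set", "forward_name", "reverse_name")
  if (!all(need %in% names(tab))) {
    stop("primer-set TSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    fn <- tab$forward_name[i]; rn <- tab$reverse_name[i]
    if (is.null(primers[[fn]])) stop("unknown forward primer: ", fn)
    if (is.null(primers[[rn]])) stop("unknown reverse primer: ", rn)
    primer_set_spec(tab$set[i], primers[[fn]], primers[[rn]])
  })
  names(out) <- tab$set
  out
}
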