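# Primer-selection pipeline: per-primer yield profiles at 0-3 mismatches,
# k2/k0 ratio filtering, amplicon-length statistics and threshold filtering,
# per-group specificity/coverage matrices, and hierarchical clustering of
# primer-set hit profiles against a theoretical optimal set.

# per-sequence minimum mismatch count for a primer, as a named integer vector
min_mismatch_per_sequence <- function(primer, db, k_max, ...) {
  sites <- scan_primer(primer, db, k_max = k_max, ...)
  if (!nrow(sites)) return(integer(0L))
  vapply(split(sites$mismatches, sites$sequence_id), min, integer(1L))
}

# counts of assigned sequences hit at <= k, per group, from min-mismatch vector
group_hit_counts <- function(minmm, db, ks) {
  out <- sapply(ks, function(k) {
    ids <- names(minmm)[minmm <= k]
    vapply(db$groups, function(g) sum(g %in% ids), integer(1L))
  })
  out <- matrix(out, nrow = length(db$groups),
                dimnames = list(names(db$groups), as.character(ks)))
  out
}

#' Per-primer yield profile at several mismatch allowances
#'
#' For each mismatch allowance k, counts the sequences of each taxonomic group
#' with at least one binding site at <= k mismatches (a sequence is "hit"
#' once, via its minimum-mismatch site), and expresses them as percentages of
#' the group denominators. When `fungal_groups` is given, the profile also
#' carries the total fungal hit count per k, the quantity the k2/k0 primer
#' selection rule operates on.
#'
#' @param primer a [primer_spec()].
#' @param db a [seq_collection()] (apply any length filter first: denominators
#'   are the post-filter group sizes).
#' @param ks integer vector of mismatch allowances (default 0:3).
#' @param fungal_groups character vector of group labels counted as Fungi.
#' @param ... passed to [scan_primer()] (`search_mode`, `strict`).
#' @return Object of class `yield_profile`: list with `primer`, `table`
#'   (`group`, `k`, `count`, `denominator`, `frequency`), `fungal_total`
#'   (named by k), `ks`, `denominators`.
#' @export
primer_yield <- function(primer, db, ks = 0:3, fungal_groups = NULL, ...) {
  stopifnot(inherits(primer, "primer_spec"), inherits(db, "seq_collection"))
  if (!length(db$seqs)) stop("collection is empty")
  if (!length(db$groups)) stop("collection has no assigned groups")
  ks <- sort(unique(as.integer(ks)))
  stopifnot(length(ks) >= 1L, all(ks >= 0L))
  if (!is.null(fungal_groups)) {
    missing_g <- setdiff(fungal_groups, names(db$groups))
    if (length(missing_g)) {
      warning("fungal group(s) absent from collection: ",
              paste(missing_g, collapse = ", "))
      fungal_groups <- intersect(fungal_groups, names(db$groups))
    }
  }
  minmm <- min_mismatch_per_sequence(primer, db, max(ks), ...)
  counts <- group_hit_counts(minmm, db, ks)
  denom <- group_sizes(db)
  tab <- data.frame(
    group = rep(rownames(counts), times = ncol(counts)),
    k = rep(ks, each = nrow(counts)),
    count = as.vector(counts),
    denominator = rep(unname(denom[rownames(counts)]), times = ncol(counts)),
    stringsAsFactors = FALSE
  )
  tab$frequency <- ifelse(tab$denominator > 0L,
                          100 * tab$count / tab$denominator, NA_real_)
  fungal_total <- if (length(fungal_groups)) {
    colSums(counts[fungal_groups, , drop = FALSE])
  } else {
    stats::setNames(rep(NA_real_, length(ks)), as.character(ks))
  }
  structure(list(primer = primer$name, table = tab,
                 fungal_total = fungal_total, ks = ks,
                 fungal_groups = fungal_groups, denominators = denom),
            class = "yield_profile")
}

#' @export
print.yield_profile <- function(x, ...) {
  cat("Yield profile for primer", x$primer, "at k =",
      paste(x$ks, collapse = ","), "\n")
  print(x$table)
  invisible(x)
}

#' Select primers by the k2/k0 improvement ratio
#'
#' A primer that already matches nearly as many fungal sequences at exact
#' match (k = 0) as at two mismatches (k = 2) cannot be improved by adding
#' degeneracies; such primers are retained. The ratio is total fungal hits at
#' k = 2 over total fungal hits at k = 0, retained iff ratio <= `threshold`
#' (default 1.2). Primers with zero exact-match fungal hits are discarded and
#' flagged `zero-baseline`.
#'
#' @param profiles a [primer_yield()] profile or list of them, computed with
#'   `fungal_groups` set and ks covering 0 and 2.
#' @param threshold retention threshold on the k2/k0 ratio.
#' @return List with `retained` (primer names), `table` (primer, k0, k2,
#'   ratio, retained, flag) and `threshold`.
#' @export
k2k0_filter <- function(profiles, threshold = 1.2) {
  if (inherits(profiles, "yield_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    stopifnot(inherits(p, "yield_profile"))
    ft <- p$fungal_total
    if (!all(c("0", "2") %in% names(ft)) || anyNA(ft[c("0", "2")])) {
      stop("profile for '", p$primer,
           "' lacks fungal totals at k = 0 and k = 2 ",
           "(compute primer_yield with fungal_groups and ks covering 0 and 2)")
    }
    k0 <- unname(ft[["0"]]); k2 <- unname(ft[["2"]])
    ratio <- if (k0 > 0) k2 / k0 else NA_real_
    data.frame(primer = p$primer, k0 = k0, k2 = k2, ratio = ratio,
               retained = isTRUE(!is.na(ratio) && ratio <= threshold),
               flag = if (k0 == 0) "zero-baseline" else "",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(retained = tab$primer[tab$retained], table = tab,
       threshold = threshold)
}

#' Amplicon length statistics of a primer set over a collection
#'
#' Mean and sample standard deviation (n - 1 denominator) of the
#' primer-inclusive product length over all sequences with at least one
#' predicted amplicon; when a sequence yields several products the shortest is
#' used (the dominant product in PCR). `sd_length` is 0 when n = 1 and both
#' stats are `NA` when n = 0.
#'
#' @param pset a [primer_set_spec()].
#' @param db a [seq_collection()] or named character vector.
#' @param k_max mismatches allowed per primer (default 0, the published
#'   screening condition).
#' @param ... passed to [predict_amplicons()].
#' @return One-row `data.frame`: `set`, `n_sequences`, `mean_length`,
#'   `sd_length`.
#' @export
amplicon_length_stats <- function(pset, db, k_max = 0L, ...) {
  stopifnot(inherits(pset, "primer_set_spec"))
  amps <- predict_amplicons(pset, db, k_max = k_max, ...)
  if (!nrow(amps)) {
    return(data.frame(set = pset$name, n_sequences = 0L,
                      mean_length = NA_real_, sd_length = NA_real_,
                      stringsAsFactors = FALSE))
  }
  len <- vapply(split(amps$product_length, amps$sequence_id), min, integer(1L))
  n <- length(len)
  data.frame(set = pset$name, n_sequences = n,
             mean_length = mean(len),
             sd_length = if (n > 1L) stats::sd(len) else 0,
             stringsAsFactors = FALSE)
}

#' Retain primer sets whose mean amplicon is short enough for qPCR
#'
#' Short amplicons improve the accuracy and reproducibility of SYBR-Green
#' real-time PCR. Sets are retained iff their mean product length is strictly
#' below `threshold` (default 384 nt, the product length of the
#' nu-SSU-0817/nu-SSU-1196 reference set); sets with missing stats (no
#' predicted product) are excluded and flagged.
#'
#' @param stats `data.frame` of rows from [amplicon_length_stats()].
#' @param threshold length threshold in nt.
#' @param strict use `<` (default) rather than `<=`.
#' @return List with `retained` (set names), `table` (with `retained` and
#'   `flag` columns) and `threshold`.
#' @export
length_threshold_filter <- function(stats, threshold = 384, strict = TRUE) {
  stopifnot(is.data.frame(stats),
            all(c("set", "mean_length") %in% names(stats)),
            is.numeric(threshold), threshold > 0)
  cmp <- if (strict) `<` else `<=`
  ok <- !is.na(stats$mean_length) & cmp(stats$mean_length, threshold)
  tab <- stats
  tab$retained <- ok
  tab$flag <- ifelse(is.na(stats$mean_length), "no-product", "")
  list(retained = tab$set[ok], table = tab, threshold = threshold)
}

# ids of assigned sequences hit by a primer set at <= k mismatches
set_hit_ids <- function(pset, db, k, mode, ...) {
  if (mode == "amplicon") {
    unique(predict_amplicons(pset, db, k_max = k, ...)$sequence_id)
  } else {
    intersect(
      unique(scan_primer(pset$forward, db, k_max = k, ...)$sequence_id),
      unique(scan_primer(pset$reverse, db, k_max = k, ...)$sequence_id)
    )
  }
}

#' Hit-frequency (or count) matrix of primer sets by taxonomic group
#'
#' One row per primer set, one column per group. By default a set "hits" a
#' sequence iff it yields at least one predicted amplicon with both primer
#' sites at <= k mismatches (`mode = "amplicon"`); `mode = "per_primer"`
#' instead requires each primer to have a site anywhere in the sequence,
#' without pairing.
#'
#' @param sets a [primer_set_spec()] or list of them.
#' @param db a [seq_collection()].
#' @param k mismatches allowed per primer.
#' @param as_counts return raw matched-sequence counts instead of percentages.
#' @param mode hit definition, see above.
#' @param ... passed to the underlying matchers.
#' @return Numeric matrix (rows = sets, columns = groups) with attributes
#'   `k`, `form` (`"frequency"` or `"counts"`), `denominators`, `mode`.
#' @export
frequency_matrix <- function(sets, db, k = 0L, as_counts = FALSE,
                             mode = c("amplicon", "per_primer"), ...) {
  mode <- match.arg(mode)
  if (inherits(sets, "primer_set_spec")) sets <- list(sets)
  stopifnot(length(sets) >= 1L, inherits(db, "seq_collection"))
  denom <- group_sizes(db)
  if (!length(denom)) stop("collection has no assigned groups")
  id2group <- stats::setNames(db$taxonomy$group_label, db$taxonomy$id)
  set_names <- vapply(sets, function(s) s$name, character(1L))
  m <- matrix(0, nrow = length(sets), ncol = length(denom),
              dimnames = list(set_names, names(denom)))
  for (i in seq_along(sets)) {
    ids <- set_hit_ids(sets[[i]], db, k, mode, ...)
    counts <- table(factor(id2group[ids], levels = names(denom)))
    m[i, ] <- as.numeric(counts)
  }
  if (!as_counts) {
    m <- sweep(m, 2L, ifelse(denom > 0L, denom, NA_integer_), "/") * 100
  }
  structure(m, k = as.integer(k),
            form = if (as_counts) "counts" else "frequency",
            denominators = denom, mode = mode)
}

#' Theoretical optimal primer-set row
#'
#' The idealized profile of a primer set matching every fungal sequence and
#' nothing else: 100 on fungal columns and 0 elsewhere (or the full group
#' sizes and 0, in counts form). Used as the clustering anchor when ranking
#' candidate sets for fungal specificity and coverage.
#'
#' @param groups character vector of group labels (matrix column order).
#' @param fungal_groups subset of `groups` that are fungal.
#' @param as_counts emit counts instead of percentages.
#' @param group_sizes named group sizes, required when `as_counts = TRUE`.
#' @return Named numeric vector over `groups`.
#' @export
theoretical_optimal_row <- function(groups, fungal_groups, as_counts = FALSE,
                                    group_sizes = NULL) {
  stopifnot(is.character(groups))
  if (!all(fungal_groups %in% groups)) {
    stop("fungal_groups must be a subset of groups")
  }
  if (!length(fungal_groups)) {
    warning("no fungal groups: theoretical optimal row is all zero")
  }
  if (as_counts) {
    if (is.null(group_sizes)) stop("group_sizes required when as_counts = TRUE")
    v <- ifelse(groups %in% fungal_groups,
                as.numeric(group_sizes[groups]), 0)
  } else {
    v <- ifelse(groups %in% fungal_groups, 100, 0)
  }
  stats::setNames(v, groups)
}

# member sets (sorted leaf labels) of each internal node of an hclust tree
cluster_members <- function(hc) {
  n <- length(hc$labels)
  mem <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    pick <- function(x) if (x < 0L) hc$labels[-x] else mem[[x]]
    mem[[i]] <- sort(c(pick(hc$merge[i, 1L]), pick(hc$merge[i, 2L])))
  }
  mem
}

# z-score columns, drop zero-variance columns, cluster rows on 1 - Pearson r.
# Returns NULL when fewer than 2 usable columns remain.
hac_build <- function(m, linkage) {
  sdv <- apply(m, 2L, stats::sd)
  usable <- is.finite(sdv) & sdv > 0
  if (sum(usable) < 2L) return(NULL)
  z <- scale(m[, usable, drop = FALSE])
  cr <- suppressWarnings(stats::cor(t(z)))
  cr[!is.finite(cr)] <- 0  # zero-variance rows: guarded r = 0 against all
  diag(cr) <- 1
  stats::hclust(stats::as.dist(1 - cr), method = linkage)
}

#' Ascendant hierarchical classification of primer-set hit profiles
#'
#' Columns (groups) are centred and scaled (z-score across primer sets), rows
#' are clustered agglomeratively on the distance 1 - Pearson r between their
#' standardized profiles. Node support is estimated by a seeded bootstrap over
#' columns: groups are resampled with replacement `n_boot` times, the tree is
#' rebuilt, and each original cluster's support is the fraction of bootstrap
#' trees containing it. Clusters are called significant at level `alpha` when
#' their support reaches `1 - alpha`; the reported significant clusters are
#' the maximal such nodes (the root, trivially always present, is excluded).
#'
#' Rows are ordered lexicographically by name before clustering so the result
#' is invariant under permutation of the input rows.
#'
#' @param mat numeric matrix, rows = primer sets (>= 3, named), columns =
#'   groups (>= 2). Typically a [frequency_matrix()] with a
#'   [theoretical_optimal_row()] appended via `rbind`.
#' @param linkage agglomeration method (default `"average"`, i.e. UPGMA).
#' @param n_boot bootstrap replicates.
#' @param seed integer seed for the bootstrap (reproducibility).
#' @param alpha significance level.
#' @return Object of class `primer_set_clustering`: list with `hclust`,
#'   `support` (per-node table), `significant_clusters` (list of leaf-name
#'   sets), `n_significant`, `phylo` (ape tree with support node labels),
#'   plus the parameters used.
#' @export
cluster_primer_sets <- function(mat,
                                linkage = c("average", "single", "complete",
                                            "ward.D2"),
                                n_boot = 1000L, seed = NULL, alpha = 0.05) {
  linkage <- match.arg(linkage)
  mat <- as.matrix(mat)
  if (nrow(mat) < 3L) stop("need at least 3 rows (primer sets)")
  if (ncol(mat) < 2L) stop("need at least 2 columns (groups)")
  if (is.null(rownames(mat))) stop("matrix rows must be named")
  mat <- mat[order(rownames(mat)), , drop = FALSE]

  sdv0 <- apply(mat, 2L, stats::sd)
  const <- !(is.finite(sdv0) & sdv0 > 0)
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(mat)[const], collapse = ", "))
  }
  hc <- hac_build(mat, linkage)
  if (is.null(hc)) stop("fewer than 2 usable (non-constant) columns")

  clusters <- cluster_members(hc)
  keys <- vapply(clusters, paste, character(1L), collapse = "\r")
  counts <- integer(length(clusters))
  local_seed(seed, {
    for (b in seq_len(n_boot)) {
      bm <- mat[, sample.int(ncol(mat), replace = TRUE), drop = FALSE]
      bh <- hac_build(bm, linkage)
      if (is.null(bh)) next
      bk <- vapply(cluster_members(bh), paste, character(1L), collapse = "\r")
      counts <- counts + (keys %in% bk)
    }
  })
  support <- counts / n_boot
  nontrivial <- lengths(clusters) < nrow(mat)
  sig <- which(support >= 1 - alpha & nontrivial)
  maximal <- sig[!vapply(sig, function(i) {
    any(vapply(sig, function(j) {
      i != j && length(clusters[[i]]) < length(clusters[[j]]) &&
        all(clusters[[i]] %in% clusters[[j]])
    }, logical(1L)))
  }, logical(1L))]

  phy <- ape::as.phylo(hc)
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  phy$node.label <- vapply(pp, function(ix) {
    s <- support[match(paste(sort(labs[ix]), collapse = "\r"), keys)]
    if (is.na(s)) "" else sprintf("%.3f", s)
  }, character(1L))

  structure(
    list(hclust = hc,
         support = data.frame(
           node = seq_along(clusters), size = lengths(clusters),
           support = support,
           members = vapply(clusters, paste, character(1L), collapse = ","),
           stringsAsFactors = FALSE),
         significant_clusters = clusters[maximal],
         n_significant = length(maximal),
         phylo = phy, linkage = linkage, n_boot = n_boot, seed = seed,
         alpha = alpha),
    class = "primer_set_clustering"
  )
}

#' @export
print.primer_set_clustering <- function(x, ...) {
  cat("Hierarchical classification of", length(x$hclust$labels),
      "primer sets (", x$linkage, "linkage,", x$n_boot, "bootstraps )\n")
  cat(x$n_significant, "significant cluster(s) at alpha =", x$alpha, "\n")
  for (cl in x$significant_clusters) {
    cat("  {", paste(cl, collapse = ", "), "}\n")
  }
  invisible(x)
}

#' Per-group specificity/coverage table of one primer set across mismatch levels
#'
#' For each group and each k in `ks`, the percentage of sequences with a
#' predicted amplicon whose two primer sites both lie at <= k mismatches
#' (per-sequence representative: the product minimizing the worse of its two
#' primers' mismatch counts). Frequencies are non-decreasing in k within each
#' group by construction.
#'
#' @inheritParams frequency_matrix
#' @param pset a [primer_set_spec()].
#' @param ks mismatch allowances to tabulate.
#' @return Long `data.frame`: `group`, `k`, `count`, `denominator`,
#'   `frequency`.
#' @export
specificity_report <- function(pset, db, ks = 0:3, ...) {
  stopifnot(inherits(pset, "primer_set_spec"), inherits(db, "seq_collection"))
  if (!length(db$groups)) stop("collection has no assigned groups")
  ks <- sort(unique(as.integer(ks)))
  amps <- predict_amplicons(pset, db, k_max = max(ks), ...)
  minmm <- if (nrow(amps)) {
    vapply(split(pmax(amps$fwd_mismatches, amps$rev_mismatches),
                 amps$sequence_id), min, integer(1L))
  } else {
    integer(0L)
  }
  counts <- group_hit_counts(minmm, db, ks)
  denom <- group_sizes(db)
  tab <- data.frame(
    group = rep(rownames(counts), times = ncol(counts)),
    k = rep(ks, each = nrow(counts)),
    count = as.vector(counts),
    denominator = rep(unname(denom[rownames(counts)]), times = ncol(counts)),
    stringsAsFactors = FALSE
  )
  tab$frequency <- ifelse(tab$denominator > 0L,
                          100 * tab$count / tab$denominator, NA_real_)
  tab
}
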