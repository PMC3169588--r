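# Seeded generators: annotated 18S-like sequence collections with planted
# primer-binding sites at controlled mismatch counts, and qPCR plates drawn
# from a known standard curve. Every downstream statistic computed on the
# generated data can be checked against the emitted truth table exactly
# (noiseless cases) or within the stated stochastic tolerance.

#' Specify one taxonomic group for the community generator
#'
#' @param label group label (e.g. `"Ascomycota"`).
#' @param n number of sequences.
#' @param length sequence length in nt.
#' @param is_fungal whether the group counts as Fungi.
#' @param fwd_prop,rev_prop proportion of sequences carrying a forward /
#'   reverse primer site (sequences carrying both are the overlap
#'   `min(n_fwd, n_rev)`, so equal proportions give paired sites).
#' @param fwd_mismatch,rev_mismatch exact mismatch count to plant in each
#'   site (mutations go to bases outside the primer symbol's IUPAC set, so
#'   the planted count is exact under optimistic matching).
#' @param product_length primer-inclusive amplicon length for paired sites;
#'   default 368 nt (the FR1/FF390-scale product).
#' @return Object of class `group_spec`.
#' @export
group_spec <- function(label, n, length, is_fungal = FALSE,
                       fwd_prop = 0, rev_prop = fwd_prop,
                       fwd_mismatch = 0L, rev_mismatch = 0L,
                       product_length = 368L) {
  stopifnot(is.character(label), nzchar(label), n >= 1L, length >= 1L,
            fwd_prop >= 0, fwd_prop <= 1, rev_prop >= 0, rev_prop <= 1,
            fwd_mismatch >= 0L, rev_mismatch >= 0L, product_length >= 1L)
  structure(list(label = label, n = as.integer(n),
                 length = as.integer(length), is_fungal = isTRUE(is_fungal),
                 fwd_prop = fwd_prop, rev_prop = rev_prop,
                 fwd_mismatch = as.integer(fwd_mismatch),
                 rev_mismatch = as.integer(rev_mismatch),
                 product_length = as.integer(product_length)),
            class = "group_spec")
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Concrete realization of a degenerate primer text with exactly `mism`
# planted mismatches (substitutions to bases outside the symbol's set).
realize_primer_site <- function(primer_sequence, mism) {
  sets <- lapply(strsplit(primer_sequence, "", fixed = TRUE)[[1L]], base_set)
  base <- vapply(sets, function(s) s[sample.int(length(s), 1L)], character(1L))
  if (mism > 0L) {
    cand <- which(lengths(sets) < 4L)  # N and I cannot mismatch
    if (length(cand) < mism) {
      stop("primer too degenerate to plant ", mism, " mismatches")
    }
    pos <- cand[sample.int(length(cand), mism)]
    for (p in pos) {
      alt <- setdiff(c("A", "C", "G", "T"), sets[[p]])
      base[p] <- alt[sample.int(length(alt), 1L)]
    }
  }
  paste(base, collapse = "")
}

splice_in <- function(seq, fragment, at) {
  paste0(substr(seq, 1L, at - 1L), fragment,
         substr(seq, at + nchar(fragment), nchar(seq)))
}

# Generate one background sequence and plant the requested sites; verify by
# scanning that the realized sites (and nothing else) are found at <= k_guard
# with exactly the intended minimum mismatch counts. Retries on spurious
# background sites.
synth_sequence <- function(id, len, pset, plant_fwd, plant_rev,
                           fwd_mm, rev_mm, product_length, k_guard,
                           max_attempts) {
  flen <- nchar(pset$forward$sequence)
  rlen <- nchar(pset$reverse$sequence)
  if (plant_fwd && plant_rev && product_length < flen + rlen + 1L) {
    stop("product_length must exceed the two primer lengths")
  }
  for (attempt in seq_len(max_attempts)) {
    seq <- random_bases(len)
    fwd_start <- NA_integer_; rev_start <- NA_integer_
    if (plant_fwd && plant_rev) {
      span <- len - product_length + 1L
      if (span < 1L) stop("sequences too short for requested product length")
      fwd_start <- sample.int(span, 1L)
      rev_start <- fwd_start + product_length - rlen
      seq <- splice_in(seq, realize_primer_site(pset$forward$sequence, fwd_mm),
                       fwd_start)
      seq <- splice_in(
        seq,
        reverse_complement(realize_primer_site(pset$reverse$sequence, rev_mm)),
        rev_start)
    } else if (plant_fwd) {
      span <- len - flen + 1L
      if (span < 1L) stop("sequences too short for the forward primer")
      fwd_start <- sample.int(span, 1L)
      seq <- splice_in(seq, realize_primer_site(pset$forward$sequence, fwd_mm),
                       fwd_start)
    } else if (plant_rev) {
      span <- len - rlen + 1L
      if (span < 1L) stop("sequences too short for the reverse primer")
      rev_start <- sample.int(span, 1L)
      seq <- splice_in(
        seq,
        reverse_complement(realize_primer_site(pset$reverse$sequence, rev_mm)),
        rev_start)
    }
    s <- stats::setNames(seq, id)
    f_sites <- scan_primer(pset$forward, s, k_max = k_guard)
    r_sites <- scan_primer(pset$reverse, s, k_max = k_guard)
    f_ok <- if (plant_fwd) {
      nrow(f_sites) == 1L && f_sites$start == fwd_start &&
        f_sites$mismatches == fwd_mm
    } else {
      nrow(f_sites) == 0L
    }
    r_ok <- if (plant_rev) {
      nrow(r_sites) == 1L && r_sites$start == rev_start &&
        r_sites$mismatches == rev_mm
    } else {
      nrow(r_sites) == 0L
    }
    if (f_ok && r_ok) {
      return(list(seq = seq, fwd_start = fwd_start, rev_start = rev_start))
    }
  }
  stop("rejection sampling failed after ", max_attempts,
       " attempts for '", id, "'; try longer sequences")
}

#' Generate an annotated community with planted primer sites
#'
#' Builds a seeded synthetic sequence collection emulating an annotated
#' 18S-like database: uniform-random backgrounds guaranteed (by rejection and
#' post-verification) to contain no unintended site at up to `k_guard`
#' mismatches for either primer of `pset`, plus planted sites realized from
#' the degenerate primer texts with exactly the requested mismatch counts.
#' Within each group the first `round(prop * n)` sequences carry sites;
#' sequences carrying both primers carry them as a pair with the requested
#' product length. Fully deterministic for a fixed seed.
#'
#' @param specs a [group_spec()] or list of them.
#' @param pset the [primer_set_spec()] whose sites are planted.
#' @param seed integer seed (mandatory: the truth table must be reproducible).
#' @param k_guard mismatch allowance up to which the background is guaranteed
#'   clean (default 3).
#' @param max_attempts rejection-sampling attempts per sequence.
#' @return List with `collection` (a [seq_collection()]), `truth` (per
#'   sequence: planted flags, mismatch counts, 1-based site starts, product
#'   length), `fungal_groups`, `pset`, `seed`, `k_guard`.
#' @export
make_community_db <- function(specs, pset, seed, k_guard = 3L,
                              max_attempts = 50L) {
  if (inherits(specs, "group_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1L, inherits(pset, "primer_set_spec"),
            is.numeric(seed))
  labels <- vapply(specs, function(s) s$label, character(1L))
  if (anyDuplicated(labels)) stop("duplicate group labels")

  local_seed(seed, {
    seqs <- character(0L)
    tax_rows <- list()
    truth_rows <- list()
    for (gs in specs) {
      n_fwd <- round(gs$fwd_prop * gs$n)
      n_rev <- round(gs$rev_prop * gs$n)
      n_pair <- min(n_fwd, n_rev)
      kingdom <- if (gs$is_fungal) "Fungi" else "Eukaryota_other"
      for (i in seq_len(gs$n)) {
        id <- sprintf("%s_%03d", gs$label, i)
        plant_fwd <- i <= n_fwd
        plant_rev <- i <= n_pair || (i > n_fwd && i <= n_fwd + (n_rev - n_pair))
        res <- synth_sequence(id, gs$length, pset, plant_fwd, plant_rev,
                              gs$fwd_mismatch, gs$rev_mismatch,
                              gs$product_length, k_guard, max_attempts)
        seqs[[id]] <- res$seq
        tax_rows[[id]] <- data.frame(
          id = id,
          lineage = paste("Eukaryota", kingdom, gs$label, sep = ";"),
          group_label = gs$label, flagged = FALSE, stringsAsFactors = FALSE)
        truth_rows[[id]] <- data.frame(
          id = id, group = gs$label, is_fungal = gs$is_fungal,
          fwd_planted = plant_fwd,
          fwd_mismatch = if (plant_fwd) gs$fwd_mismatch else NA_integer_,
          fwd_start = res$fwd_start,
          rev_planted = plant_rev,
          rev_mismatch = if (plant_rev) gs$rev_mismatch else NA_integer_,
          rev_start = res$rev_start,
          product_length = if (plant_fwd && plant_rev) gs$product_length
                           else NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
    taxonomy <- do.call(rbind, tax_rows)
    truth <- do.call(rbind, truth_rows)
    rownames(taxonomy) <- rownames(truth) <- NULL
    list(collection = seq_collection(seqs, taxonomy),
         truth = truth,
         fungal_groups = labels[vapply(specs, function(s) s$is_fungal,
                                       logical(1L))],
         pset = pset, seed = seed, k_guard = as.integer(k_guard))
  })
}

#' Write a synthetic community to FASTA + taxonomy + truth files
#'
#' @param db result of [make_community_db()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Named character vector of the emitted paths.
#' @export
write_community_db <- function(db, dir, prefix = "community") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(prefix, ".fasta"))
  taxonomy <- file.path(dir, paste0(prefix, "_taxonomy.tsv"))
  truth <- file.path(dir, paste0(prefix, "_truth.tsv"))
  write_fasta(db$collection$seqs, fasta)
  writeLines(paste(db$collection$taxonomy$id, db$collection$taxonomy$lineage,
                   sep = "\t"), taxonomy)
  utils::write.table(db$truth, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(fasta = fasta, taxonomy = taxonomy, truth = truth)
}

#' Simulate a qPCR plate from a known standard curve
#'
#' CT values are drawn as `slope * log10(copies) + intercept + N(0, noise_sd)`;
#' CTs beyond `max_cycle` are censored to undetected (`NA`). No-template
#' controls are emitted as undetected. The default dilution design mirrors a
#' plasmid standard series spanning 3x10^2 to 3x10^7 copies.
#'
#' @param slope,intercept true standard-curve parameters (cycles per log10
#'   copies; cycles). Defaults: perfect doubling (-3.3219) with intercept 38.
#' @param standards copies in the standard dilution series.
#' @param unknowns optional `data.frame` with columns `sample`, `copies`
#'   (true copies per reaction) and `template_ng` (ng DNA per reaction).
#' @param noise_sd Gaussian CT noise, in cycles.
#' @param n_replicates replicate wells per template.
#' @param n_ntc number of no-template control wells.
#' @param seed integer seed.
#' @param max_cycle last PCR cycle (censoring limit).
#' @return List with `plate` (`sample, well, role, quantity, ct, replicate`)
#'   and `truth` (the generating parameters).
#' @export
make_qpcr_plate <- function(slope = -1 / log10(2), intercept = 38,
                            standards = 3 * 10^(2:7), unknowns = NULL,
                            noise_sd = 0.15, n_replicates = 3L, n_ntc = 3L,
                            seed, max_cycle = 40) {
  stopifnot(slope < 0, noise_sd >= 0, n_replicates >= 1L,
            all(standards > 0), is.numeric(seed))
  local_seed(seed, {
    rows <- list()
    add <- function(sample, role, quantity, true_copies, rep_idx) {
      ct <- if (role == "ntc") {
        NA_real_
      } else {
        slope * log10(true_copies) + intercept +
          stats::rnorm(1L, 0, noise_sd)
      }
      if (!is.na(ct) && ct > max_cycle) ct <- NA_real_
      rows[[length(rows) + 1L]] <<- data.frame(
        sample = sample, role = role, quantity = quantity, ct = ct,
        replicate = rep_idx, stringsAsFactors = FALSE)
    }
    for (q in standards) {
      for (r in seq_len(n_replicates)) {
        add(sprintf("std_%g", q), "standard", q, q, r)
      }
    }
    if (!is.null(unknowns)) {
      stopifnot(all(c("sample", "copies", "template_ng") %in% names(unknowns)))
      for (i in seq_len(nrow(unknowns))) {
        for (r in seq_len(n_replicates)) {
          add(unknowns$sample[i], "unknown", unknowns$template_ng[i],
              unknowns$copies[i], r)
        }
      }
    }
    for (r in seq_len(n_ntc)) add("ntc", "ntc", NA_real_, NA_real_, r)
    plate <- do.call(rbind, rows)
    plate$well <- sprintf("W%03d", seq_len(nrow(plate)))
    plate <- plate[, c("sample", "well", "role", "quantity", "ct",
                       "replicate")]
    list(plate = plate,
         truth = list(slope = slope, intercept = intercept,
                      noise_sd = noise_sd, standards = standards,
                      unknowns = unknowns, max_cycle = max_cycle,
                      seed = seed))
  })
}
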