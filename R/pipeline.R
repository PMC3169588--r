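# Report assembly: each run_* function ties the modules together for one
# subcommand of the command-line front end (inst/scripts/fungiqpcr-cli.R),
# writes diff-able TSV reports with a '#'-prefixed metadata header, and drops
# a JSON run manifest so any run can be reproduced from its parameters.

#' Write a data frame as a TSV report with a metadata header
#'
#' @param df data frame to write.
#' @param path output path.
#' @param params named list echoed as `# key: value` header lines.
#' @return The path, invisibly.
#' @export
write_report <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(params)) {
    writeLines(sprintf("# %s: %s", nm,
                       paste(params[[nm]], collapse = ",")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV report written by [write_report()]
#'
#' @param path report path.
#' @return The data frame (header lines skipped).
#' @export
read_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

write_manifest <- function(out_dir, subcommand, params) {
  manifest <- c(list(tool = "fungiqpcr",
                     version = as.character(utils::packageVersion("fungiqpcr")),
                     subcommand = subcommand), params)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

load_collection <- function(fasta, taxonomy, rank = NULL, group_map = NULL,
                            min_length = 900) {
  seqs <- read_fasta(fasta)
  tax <- load_taxonomy(taxonomy, rank = rank, group_map = group_map)
  db <- seq_collection(seqs, tax)
  apply_length_filter(db, min_length)
}

#' Evaluate primers individually and apply the k2/k0 selection rule
#'
#' Loads a FASTA + taxonomy collection, applies the length filter, computes a
#' yield profile for every primer at the requested mismatch allowances and
#' the k2/k0 retention table. Writes `primer_yield.tsv`, `k2k0_ratios.tsv`
#' and `manifest.json` under `out_dir`.
#'
#' @param fasta,taxonomy,primers input paths (FASTA; `id<TAB>lineage` TSV;
#'   primer TSV with name/sequence/orientation).
#' @param out_dir output directory (created).
#' @param fungal_groups group labels counted as Fungi.
#' @param rank,group_map taxonomy aggregation, see [load_taxonomy()].
#' @param ks mismatch allowances.
#' @param ratio_threshold k2/k0 retention threshold.
#' @param min_length length-filter threshold in nt.
#' @param search_mode passed to [scan_primer()].
#' @return Invisibly, list with `profiles`, `ratio` and the output paths.
#' @export
run_evaluate_primers <- function(fasta, taxonomy, primers, out_dir,
                                 fungal_groups, rank = NULL, group_map = NULL,
                                 ks = 0:3, ratio_threshold = 1.2,
                                 min_length = 900,
                                 search_mode = "sense_only") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  db <- load_collection(fasta, taxonomy, rank, group_map, min_length)
  prim <- read_primers(primers)
  profiles <- lapply(prim, primer_yield, db = db, ks = ks,
                     fungal_groups = fungal_groups,
                     search_mode = search_mode)
  ratio <- k2k0_filter(profiles, threshold = ratio_threshold)
  yield_tab <- do.call(rbind, lapply(profiles, function(p) {
    cbind(primer = p$primer, p$table)
  }))
  rownames(yield_tab) <- NULL
  yield_tab$frequency <- round(yield_tab$frequency, 1L)  # 1 dp in reports
  params <- list(ks = ks, ratio_threshold = ratio_threshold,
                 min_length = min_length, search_mode = search_mode,
                 fungal_groups = fungal_groups,
                 n_sequences = length(db$seqs),
                 n_unassigned = length(db$unassigned))
  paths <- c(
    yield = write_report(yield_tab, file.path(out_dir, "primer_yield.tsv"),
                         params),
    ratios = write_report(ratio$table,
                          file.path(out_dir, "k2k0_ratios.tsv"), params),
    manifest = write_manifest(out_dir, "evaluate-primers",
                              c(list(fasta = fasta, taxonomy = taxonomy,
                                     primers = primers), params))
  )
  invisible(list(profiles = profiles, ratio = ratio, paths = paths))
}

#' Screen primer sets: amplicon lengths, length filter, frequency matrix
#'
#' Writes `amplicon_length_stats.tsv`, `frequency_matrix.tsv` (retained sets
#' as rows, groups as columns, theoretical optimal row appended) and
#' `manifest.json` under `out_dir`.
#'
#' @inheritParams run_evaluate_primers
#' @param sets primer-set TSV (`set<TAB>forward_name<TAB>reverse_name`).
#' @param k mismatch allowance for the frequency matrix.
#' @param length_threshold amplicon-length threshold in nt (strictly below).
#' @param as_counts emit counts instead of percentages in the matrix.
#' @return Invisibly, list with `stats`, `length_filter`, `matrix`, paths.
#' @export
run_screen_sets <- function(fasta, taxonomy, primers, sets, out_dir,
                            fungal_groups, rank = NULL, group_map = NULL,
                            k = 0L, length_threshold = 384,
                            min_length = 900, as_counts = FALSE,
                            search_mode = "sense_only") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  db <- load_collection(fasta, taxonomy, rank, group_map, min_length)
  prim <- read_primers(primers)
  psets <- read_primer_sets(sets, prim)
  stats_tab <- do.call(rbind, lapply(psets, amplicon_length_stats, db = db,
                                     k_max = k, search_mode = search_mode))
  rownames(stats_tab) <- NULL
  lf <- length_threshold_filter(stats_tab, threshold = length_threshold)
  retained <- psets[lf$retained]
  mat <- NULL
  if (length(retained)) {
    mat <- frequency_matrix(retained, db, k = k, as_counts = as_counts,
                            search_mode = search_mode)
    opt <- theoretical_optimal_row(colnames(mat), fungal_groups,
                                   as_counts = as_counts,
                                   group_sizes = group_sizes(db))
    mat <- rbind(mat, theoretical_optimal = opt)
  }
  params <- list(k = k, length_threshold = length_threshold,
                 min_length = min_length, as_counts = as_counts,
                 search_mode = search_mode, fungal_groups = fungal_groups,
                 n_sequences = length(db$seqs))
  paths <- c(
    stats = write_report(lf$table,
                         file.path(out_dir, "amplicon_length_stats.tsv"),
                         params),
    manifest = write_manifest(out_dir, "screen-sets",
                              c(list(fasta = fasta, taxonomy = taxonomy,
                                     primers = primers, sets = sets), params))
  )
  if (!is.null(mat)) {
    mat_out <- if (as_counts) mat else round(mat, 1L)  # 1 dp in reports
    mat_df <- data.frame(set = rownames(mat), as.data.frame(mat_out),
                         check.names = FALSE)
    paths <- c(paths,
               matrix = write_report(mat_df,
                                     file.path(out_dir,
                                               "frequency_matrix.tsv"),
                                     params))
  }
  invisible(list(stats = stats_tab, length_filter = lf, matrix = mat,
                 paths = paths))
}

#' Cluster a frequency matrix of primer sets
#'
#' Reads a frequency-matrix TSV (first column = set names, as written by
#' [run_screen_sets()]), runs the hierarchical classification and writes
#' `dendrogram.nwk` (Newick, bootstrap support as internal node labels),
#' `cluster_support.tsv`, `significant_clusters.tsv` and `manifest.json`.
#'
#' @param matrix_tsv input matrix TSV.
#' @param out_dir output directory.
#' @param linkage,n_boot,seed,alpha see [cluster_primer_sets()].
#' @return Invisibly, list with `clustering` and paths.
#' @export
run_cluster_sets <- function(matrix_tsv, out_dir, linkage = "average",
                             n_boot = 1000L, seed = 1L, alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- read_report(matrix_tsv)
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(mat) <- tab[[1L]]
  cl <- cluster_primer_sets(mat, linkage = linkage, n_boot = n_boot,
                            seed = seed, alpha = alpha)
  params <- list(linkage = linkage, n_boot = n_boot, seed = seed,
                 alpha = alpha)
  sig <- data.frame(
    cluster = seq_along(cl$significant_clusters),
    members = vapply(cl$significant_clusters, paste, character(1L),
                     collapse = ","),
    stringsAsFactors = FALSE)
  nwk <- file.path(out_dir, "dendrogram.nwk")
  ape::write.tree(cl$phylo, nwk)
  paths <- c(
    newick = nwk,
    support = write_report(cl$support,
                           file.path(out_dir, "cluster_support.tsv"), params),
    clusters = write_report(sig,
                            file.path(out_dir, "significant_clusters.tsv"),
                            params),
    manifest = write_manifest(out_dir, "cluster-sets",
                              c(list(matrix_tsv = matrix_tsv), params))
  )
  invisible(list(clustering = cl, paths = paths))
}

#' Quantify unknowns on a qPCR plate
#'
#' Fits the standard curve from the plate's standard wells, estimates copies
#' per reaction for every detected unknown well, aggregates per sample (mean
#' copies, CV of CT and of copies, copies per ng of template) and, when a DNA
#' yield table is given (`sample,dna_yield_ng_per_g` CSV), converts to copies
#' per gram of dry soil. Also reports the detection limit from the NTC wells.
#' Writes `standard_curve.tsv`, `abundance.tsv` and `manifest.json`.
#'
#' @param plate_csv plate CSV, see [read_plate()].
#' @param out_dir output directory.
#' @param dna_yield_csv optional CSV `sample,dna_yield_ng_per_g`.
#' @param delta CT separation for the detection limit, in cycles.
#' @param max_cycle censoring cycle for undetected NTCs.
#' @return Invisibly, list with `curve`, `abundance`, `limit`, paths.
#' @export
run_qpcr_quantify <- function(plate_csv, out_dir, dna_yield_csv = NULL,
                              delta = 3.3, max_cycle = 40) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  plate <- read_plate(plate_csv)
  std <- plate[plate$role == "standard" & !is.na(plate$ct), , drop = FALSE]
  curve <- fit_standard_curve(std$quantity, std$ct)
  ntc <- plate[plate$role == "ntc", , drop = FALSE]
  limit <- if (nrow(ntc)) {
    detection_limit(std, ntc$ct, delta = delta, max_cycle = max_cycle)
  }
  unk <- plate[plate$role == "unknown", , drop = FALSE]
  abundance <- NULL
  if (nrow(unk)) {
    unk$copies <- estimate_copies(unk$ct, curve)
    yields <- if (!is.null(dna_yield_csv)) {
      utils::read.csv(dna_yield_csv, stringsAsFactors = FALSE,
                      comment.char = "#")
    }
    abundance <- do.call(rbind, lapply(split(unk, unk$sample), function(w) {
      det <- w[!is.na(w$ct), , drop = FALSE]
      mean_copies <- if (nrow(det)) mean(det$copies) else NA_real_
      template_ng <- unique(w$quantity)[1L]
      out <- data.frame(
        sample = w$sample[1L],
        n_detected = nrow(det),
        mean_ct = if (nrow(det)) mean(det$ct) else NA_real_,
        cv_ct = if (nrow(det) >= 2L) replicate_cv(det$ct) else NA_real_,
        copies_per_reaction = mean_copies,
        cv_copies = if (nrow(det) >= 2L) replicate_cv(det$copies)
                    else NA_real_,
        copies_per_ng = mean_copies / template_ng,
        stringsAsFactors = FALSE)
      if (!is.null(yields)) {
        y <- yields$dna_yield_ng_per_g[match(out$sample, yields$sample)]
        out$copies_per_g_dry_soil <- if (!is.na(y) && !is.na(mean_copies)) {
          copies_per_gram(mean_copies, template_ng, y)
        } else {
          NA_real_
        }
      }
      out
    }))
    rownames(abundance) <- NULL
  }
  params <- list(delta = delta, max_cycle = max_cycle,
                 slope = curve$slope, intercept = curve$intercept,
                 r_squared = curve$r_squared,
                 efficiency_pct = efficiency_percent(curve$slope),
                 detection_limit = if (!is.null(limit)) limit$limit else NA)
  curve_df <- data.frame(slope = curve$slope, intercept = curve$intercept,
                         r_squared = curve$r_squared,
                         efficiency_pct = efficiency_percent(curve$slope),
                         n_points = curve$n)
  paths <- c(
    curve = write_report(curve_df, file.path(out_dir, "standard_curve.tsv"),
                         params),
    manifest = write_manifest(out_dir, "qpcr-quantify",
                              c(list(plate_csv = plate_csv,
                                     dna_yield_csv = dna_yield_csv), params))
  )
  if (!is.null(abundance)) {
    paths <- c(paths,
               abundance = write_report(abundance,
                                        file.path(out_dir, "abundance.tsv"),
                                        params))
  }
  invisible(list(curve = curve, abundance = abundance, limit = limit,
                 paths = paths))
}

#' Ecology statistics: abundance vs land use and soil variables
#'
#' Joins a per-sample abundance table (`sample,copies_per_g` CSV) with a soil
#' descriptor table (`sample` plus physico-chemical columns and a `land_use`
#' column), runs a Kruskal-Wallis test of abundance across land-use types
#' with Dunn/Bonferroni letters, and a Pearson correlation screen of
#' abundance against every numeric soil variable. Writes
#' `kruskal_wallis.tsv`, `pairwise_comparisons.tsv`, `correlations.tsv` and
#' `manifest.json`.
#'
#' @param abundance_csv CSV with columns `sample`, `copies_per_g`.
#' @param soil_csv CSV with `sample`, `land_use` and numeric variables.
#' @param out_dir output directory.
#' @param alpha significance level.
#' @return Invisibly, list with `kw`, `correlations`, paths.
#' @export
run_ecology_stats <- function(abundance_csv, soil_csv, out_dir,
                              alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ab <- utils::read.csv(abundance_csv, stringsAsFactors = FALSE,
                        comment.char = "#")
  soil <- utils::read.csv(soil_csv, stringsAsFactors = FALSE,
                          comment.char = "#")
  stopifnot(all(c("sample", "copies_per_g") %in% names(ab)),
            "sample" %in% names(soil))
  merged <- merge(ab, soil, by = "sample")
  if (!nrow(merged)) stop("no samples shared between abundance and soil tables")
  kw <- NULL
  if ("land_use" %in% names(merged)) {
    kw <- kruskal_wallis(merged$copies_per_g, merged$land_use, alpha = alpha)
  }
  vars <- merged[, setdiff(names(merged), c("sample", "copies_per_g")),
                 drop = FALSE]
  corr <- pearson_correlations(merged$copies_per_g, vars, alpha = alpha)
  params <- list(alpha = alpha, n_samples = nrow(merged))
  paths <- c(manifest = write_manifest(out_dir, "ecology-stats",
                                       c(list(abundance_csv = abundance_csv,
                                              soil_csv = soil_csv), params)))
  if (!is.null(kw)) {
    kw_df <- data.frame(statistic = kw$statistic, df = kw$df,
                        p_value = kw$p_value)
    paths <- c(paths,
               kw = write_report(kw_df, file.path(out_dir,
                                                  "kruskal_wallis.tsv"),
                                 params),
               pairwise = write_report(kw$pairwise,
                                       file.path(out_dir,
                                                 "pairwise_comparisons.tsv"),
                                       params),
               groups = write_report(kw$group_summary,
                                     file.path(out_dir,
                                               "group_summary.tsv"),
                                     params))
  }
  paths <- c(paths,
             correlations = write_report(corr,
                                         file.path(out_dir,
                                                   "correlations.tsv"),
                                         params))
  invisible(list(kw = kw, correlations = corr, paths = paths))
}

#' Simulate a community and/or qPCR plate from a config file
#'
#' The YAML config has an optional `community` section (`groups`: list of
#' [group_spec()] fields; `forward`/`reverse`: primer name + sequence) and an
#' optional `plate` section ([make_qpcr_plate()] fields). Both generators are
#' driven by `seed`. Emits FASTA/taxonomy/truth and/or `plate.csv` under
#' `out_dir` plus `manifest.json`.
#'
#' @param config_path YAML config path.
#' @param out_dir output directory.
#' @param seed integer seed (overrides any seed in the config).
#' @return Invisibly, list with the generated objects and paths.
#' @export
run_simulate <- function(config_path, out_dir, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- yaml::read_yaml(config_path)
  out <- list()
  paths <- character(0L)
  if (!is.null(cfg$community)) {
    cc <- cfg$community
    pset <- primer_set_spec(
      cc$set_name %||% "set1",
      primer_spec(cc$forward$name, cc$forward$sequence, "forward"),
      primer_spec(cc$reverse$name, cc$reverse$sequence, "reverse"))
    specs <- lapply(cc$groups, function(g) {
      names(g)[names(g) == "n_sequences"] <- "n"
      do.call(group_spec, g)
    })
    db <- make_community_db(specs, pset, seed = seed,
                            k_guard = cc$k_guard %||% 3L)
    paths <- c(paths, write_community_db(db, out_dir))
    out$community <- db
  }
  if (!is.null(cfg$plate)) {
    pc <- cfg$plate
    unknowns <- if (!is.null(pc$unknowns)) {
      do.call(rbind, lapply(pc$unknowns, as.data.frame))
    }
    plate <- make_qpcr_plate(
      slope = pc$slope %||% (-1 / log10(2)),
      intercept = pc$intercept %||% 38,
      standards = pc$standards %||% (3 * 10^(2:7)),
      unknowns = unknowns,
      noise_sd = pc$noise_sd %||% 0.15,
      n_replicates = pc$n_replicates %||% 3L,
      n_ntc = pc$n_ntc %||% 3L,
      seed = seed,
      max_cycle = pc$max_cycle %||% 40)
    plate_path <- file.path(out_dir, "plate.csv")
    utils::write.csv(plate$plate, plate_path, row.names = FALSE, quote = FALSE)
    paths <- c(paths, plate = plate_path)
    out$plate <- plate
  }
  paths <- c(paths,
             manifest = write_manifest(out_dir, "simulate",
                                       list(config = config_path,
                                            seed = seed)))
  out$paths <- paths
  invisible(out)
}
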