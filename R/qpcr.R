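# Real-time Q-PCR quantification: standard curves, amplification efficiency,
# detection limit, replicate variability, conversion to copies per gram of
# dry soil, and the nonparametric ecology statistics applied downstream.

#' Read a qPCR plate table
#'
#' CSV with columns `sample, well, role, quantity, ct, replicate`; `role` is
#' one of `standard` (quantity = template copies), `unknown` (quantity = ng of
#' DNA in the reaction) or `ntc`. Undetected CT values may be written as
#' empty, `NA` or `ND` and are read as missing.
#'
#' @param path plate CSV path.
#' @return `data.frame` with validated columns; `ct` numeric with `NA` for
#'   undetected wells.
#' @export
read_plate <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample", "well", "role", "quantity", "ct", "replicate")
  if (!all(need %in% names(tab))) {
    stop("plate CSV must have columns: ", paste(need, collapse = ", "))
  }
  bad_role <- setdiff(unique(tab$role), c("standard", "unknown", "ntc"))
  if (length(bad_role)) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  }
  tab$ct <- suppressWarnings(as.numeric(ifelse(tab$ct %in% c("", "ND", "nd"),
                                               NA, tab$ct)))
  tab$quantity <- suppressWarnings(as.numeric(tab$quantity))
  if (any(!is.na(tab$ct) & tab$ct <= 0)) stop("detected CT values must be > 0")
  pos <- tab$role != "ntc"
  if (any(pos & (is.na(tab$quantity) | tab$quantity <= 0))) {
    stop("standard and unknown wells must have quantity > 0")
  }
  tab
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of CT on log10(quantity). A valid dilution series
#' has a negative slope; the amplification efficiency is the per-cycle
#' amplification factor minus one, E = 10^(-1/slope) - 1 (E = 1, i.e. 100%,
#' means perfect doubling each cycle, slope = -1/log10(2) = -3.3219).
#'
#' @param quantity starting quantities (copies for standards, or ng of
#'   template); must cover at least 3 distinct positive values.
#' @param ct threshold cycles; undetected (`NA`) points are excluded.
#' @return Object of class `standard_curve`: list with `slope` (cycles per
#'   log10 quantity), `intercept` (cycles), `r_squared`, `efficiency`
#'   (fraction), `n`, `valid`.
#' @export
fit_standard_curve <- function(quantity, ct) {
  stopifnot(is.numeric(quantity), is.numeric(ct),
            length(quantity) == length(ct))
  ok <- is.finite(quantity) & is.finite(ct)
  quantity <- quantity[ok]; ct <- ct[ok]
  if (any(quantity <= 0)) stop("quantities must be positive")
  if (length(unique(quantity)) < 3L) {
    stop("need at least 3 distinct quantities (got ",
         length(unique(quantity)), ")")
  }
  fit <- stats::lm(ct ~ log10(quantity))
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn in summary.lm
  valid <- slope < 0
  if (!valid) warning("non-negative slope: standard curve flagged invalid")
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         efficiency = if (valid) 10^(-1 / slope) - 1 else NA_real_,
         n = length(ct), valid = valid),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "Standard curve: CT = %.4f log10(Q) + %.4f  (r2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n))
  if (x$valid) {
    cat(sprintf("  efficiency: %d%% (%.1f%%)\n",
                efficiency_percent(x$slope), 100 * x$efficiency))
  } else {
    cat("  INVALID (non-negative slope)\n")
  }
  invisible(x)
}

#' Amplification efficiency from a standard-curve slope
#'
#' E = 100 x (10^(-1/slope) - 1), in percent. Strictly decreasing in |slope|
#' for negative slopes and exactly 100% at slope = -1/log10(2).
#'
#' @param slope negative slope(s) in cycles per log10 quantity.
#' @return Numeric vector of efficiencies in percent (continuous; see
#'   [efficiency_percent()] for the integer reporting convention).
#' @examples
#' efficiency_from_slope(-3.3219)  # ~100
#' @export
efficiency_from_slope <- function(slope) {
  stopifnot(is.numeric(slope))
  if (any(!is.finite(slope) | slope >= 0)) {
    stop("slope must be finite and negative")
  }
  100 * (10^(-1 / slope) - 1)
}

#' Integer-percent amplification efficiency
#'
#' Integer efficiencies are reported by truncating the fractional part, the
#' conservative convention under which a slope of -3.24 reads as 103% and
#' -4.47 as 67%.
#'
#' @inheritParams efficiency_from_slope
#' @return Integer vector of efficiencies in percent.
#' @export
efficiency_percent <- function(slope) {
  as.integer(trunc(efficiency_from_slope(slope)))
}

#' Windowed efficiency diagnostic along a dilution series
#'
#' Slides a window of consecutive dilution levels along the series and
#' refits the curve in each window, exposing how apparent efficiency varies
#' with template quantity (e.g. inhibitor effects at high template loads in
#' soil DNA extracts). A diagnostic: window estimates are noisy and are not a
#' substitute for the full-series efficiency.
#'
#' @inheritParams fit_standard_curve
#' @param window number of consecutive distinct quantities per fit (>= 3).
#' @return `data.frame` with one row per window: `quantity_min`,
#'   `quantity_max`, `slope`, `efficiency_pct` (`NA` when a window's slope is
#'   non-negative).
#' @export
windowed_efficiency <- function(quantity, ct, window = 3L) {
  stopifnot(length(quantity) == length(ct), window >= 3L)
  ok <- is.finite(quantity) & is.finite(ct)
  quantity <- quantity[ok]; ct <- ct[ok]
  qs <- sort(unique(quantity))
  if (length(qs) < window) stop("fewer distinct quantities than the window")
  rows <- lapply(seq_len(length(qs) - window + 1L), function(i) {
    qw <- qs[i:(i + window - 1L)]
    sel <- quantity %in% qw
    fit <- stats::lm(ct[sel] ~ log10(quantity[sel]))
    slope <- unname(stats::coef(fit)[2L])
    data.frame(quantity_min = min(qw), quantity_max = max(qw), slope = slope,
               efficiency_pct = if (slope < 0) efficiency_percent(slope)
                                else NA_integer_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Estimate starting copies from a CT value
#'
#' Inverts the standard curve: copies = 10^((ct - intercept) / slope).
#' Undetected CT (`NA`) propagates to a missing estimate, never zero.
#'
#' @param ct threshold cycle(s).
#' @param curve a valid [fit_standard_curve()] result.
#' @return Numeric vector of estimated copies per reaction.
#' @export
estimate_copies <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!curve$valid) stop("standard curve is invalid (non-negative slope)")
  10^((ct - curve$intercept) / curve$slope)
}

#' Detection limit from standards and no-template controls
#'
#' The detection limit is the smallest standard quantity whose mean CT lies at
#' least `delta` cycles (default 3.3, one 10-fold dilution at 100%
#' efficiency) below the earliest no-template-control CT. Undetected NTC
#' wells are censored at `max_cycle`.
#'
#' @param standards `data.frame` with columns `quantity` and `ct` (standard
#'   wells; replicates allowed), spanning at least 2 quantities.
#' @param ntc_ct numeric vector of NTC threshold cycles (`NA` = undetected).
#' @param delta required CT separation in cycles.
#' @param max_cycle censoring value for undetected NTCs.
#' @return List with `limit` (copies; `NA` when no standard qualifies),
#'   `status` (`"ok"` or `"above largest tested dilution"`), `ntc_ct` (the
#'   censored minimum used) and `per_standard` (mean CT and qualification per
#'   quantity).
#' @export
detection_limit <- function(standards, ntc_ct, delta = 3.3, max_cycle = 40) {
  stopifnot(is.data.frame(standards),
            all(c("quantity", "ct") %in% names(standards)))
  if (!length(ntc_ct)) stop("need at least one no-template control")
  ntc <- ifelse(is.na(ntc_ct), max_cycle, ntc_ct)
  if (length(unique(standards$quantity)) < 2L) {
    stop("standards must span at least 2 quantities")
  }
  mean_ct <- tapply(standards$ct, standards$quantity, mean, na.rm = TRUE)
  q <- as.numeric(names(mean_ct))
  cutoff <- min(ntc) - delta
  qualifies <- as.numeric(mean_ct) <= cutoff
  per <- data.frame(quantity = q, mean_ct = as.numeric(mean_ct),
                    qualifies = qualifies)
  per <- per[order(per$quantity), , drop = FALSE]
  rownames(per) <- NULL
  if (!any(qualifies)) {
    list(limit = NA_real_, status = "above largest tested dilution",
         ntc_ct = min(ntc), per_standard = per)
  } else {
    list(limit = min(q[qualifies]), status = "ok",
         ntc_ct = min(ntc), per_standard = per)
  }
}

#' Coefficient of variation of replicate measurements
#'
#' 100 x sample standard deviation (n - 1 denominator) / mean. Invariant
#' under positive scaling of the values.
#'
#' @param values numeric vector, n >= 2, positive mean.
#' @return CV in percent.
#' @examples
#' replicate_cv(c(8, 10, 12))  # 20
#' @export
replicate_cv <- function(values) {
  stopifnot(is.numeric(values))
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 replicate values")
  m <- mean(values)
  if (m <= 0) stop("mean of replicate values must be positive")
  100 * stats::sd(values) / m
}

#' Convert copies per reaction to copies per gram of dry soil
#'
#' copies/g = (copies per reaction / ng of template DNA in the reaction) x
#' (ng of DNA extracted per g of dry soil). Linear in the DNA yield.
#'
#' @param copies_per_reaction estimated copies in the reaction.
#' @param template_ng_per_reaction ng of template DNA in the reaction.
#' @param dna_yield_ng_per_g ng of DNA extracted per gram of dry soil.
#' @return Copies per gram of dry soil.
#' @export
copies_per_gram <- function(copies_per_reaction, template_ng_per_reaction,
                            dna_yield_ng_per_g) {
  args <- list(copies_per_reaction, template_ng_per_reaction,
               dna_yield_ng_per_g)
  if (any(vapply(args, function(a) any(a <= 0, na.rm = TRUE), logical(1L)))) {
    stop("all inputs must be positive")
  }
  (copies_per_reaction / template_ng_per_reaction) * dna_yield_ng_per_g
}

# compact letter display from a "not significantly different" relation,
# via maximal cliques of the NSD graph; groups ordered by decreasing level
cld_letters <- function(group_order, pairs_nsd) {
  g <- igraph::graph_from_data_frame(
    pairs_nsd[pairs_nsd$nsd, c("group1", "group2"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = group_order, stringsAsFactors = FALSE)
  )
  cliques <- igraph::max_cliques(g)
  members <- lapply(cliques, function(cl) names(igraph::V(g))[as.integer(cl)])
  rank <- vapply(members, function(m) min(match(m, group_order)), integer(1L))
  members <- members[order(rank)]
  lab <- stats::setNames(rep("", length(group_order)), group_order)
  for (i in seq_along(members)) {
    lab[members[[i]]] <- paste0(lab[members[[i]]], letters[i])
  }
  vapply(lab, function(x) paste(sort(strsplit(x, "")[[1L]]), collapse = ""),
         character(1L))
}

#' Kruskal-Wallis test with Dunn pairwise comparisons and letters
#'
#' Tie-corrected Kruskal-Wallis H across groups, followed by Dunn's rank-based
#' z tests for all pairs with Bonferroni adjustment, summarized as a compact
#' letter display (groups sharing a letter do not differ significantly).
#' Rank-based throughout, hence invariant under any strictly monotone
#' transform of the values.
#'
#' @param values numeric response (e.g. 18S rRNA gene copies per g dry soil).
#' @param groups group labels (e.g. land-use types), same length as `values`.
#' @param alpha significance level for the letters.
#' @return List with `statistic` (H), `df`, `p_value`, `pairwise`
#'   (`group1`, `group2`, `z`, `p_value`, `p_adjusted`, `significant`),
#'   `letters` (named by group, ordered by decreasing group mean) and
#'   `group_summary`.
#' @export
kruskal_wallis <- function(values, groups, alpha = 0.05) {
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups)[ok]
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("excluding group(s) with n < 2: ", paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
    sizes <- table(groups)
  }
  if (length(sizes) < 2L) stop("need at least 2 groups with n >= 2")

  kt <- stats::kruskal.test(values, factor(groups))
  r <- rank(values)
  n_total <- length(values)
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (n_total - 1))
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  gl <- names(mean_rank)

  cmb <- utils::combn(gl, 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
    a <- cmb[1L, i]; b <- cmb[2L, i]
    se <- sqrt((n_total * (n_total + 1) / 12 - tie_corr) *
                 (1 / n_g[[a]] + 1 / n_g[[b]]))
    z <- (mean_rank[[a]] - mean_rank[[b]]) / se
    data.frame(group1 = a, group2 = b, z = z,
               p_value = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  }))
  pw$p_adjusted <- pmin(1, pw$p_value * nrow(pw))
  pw$significant <- pw$p_adjusted < alpha
  rownames(pw) <- NULL

  group_mean <- tapply(values, groups, mean)
  order_groups <- names(sort(group_mean, decreasing = TRUE))
  pw$nsd <- !pw$significant
  lets <- cld_letters(order_groups, pw)
  pw$nsd <- NULL

  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, pairwise = pw, letters = lets,
       group_summary = data.frame(
         group = order_groups,
         n = as.integer(n_g[order_groups]),
         mean = as.numeric(group_mean[order_groups]),
         median = as.numeric(tapply(values, groups, stats::median)[order_groups]),
         letter = unname(lets[order_groups]),
         stringsAsFactors = FALSE),
       alpha = alpha,
       method = "Kruskal-Wallis (tie-corrected) + Dunn/Bonferroni")
}

#' Pearson correlation screen of abundance against soil variables
#'
#' Two-sided Pearson correlation tests of one response (e.g. 18S rRNA gene
#' copies per g of dry soil) against each numeric column of a soil descriptor
#' table, on pairwise-complete observations. Constant variables or pairs with
#' fewer than 3 complete observations are reported as missing.
#'
#' @param x numeric response, one value per sample.
#' @param table `data.frame` of per-sample variables (non-numeric columns are
#'   ignored) or a single numeric vector.
#' @param alpha significance level.
#' @return `data.frame`: `variable`, `n`, `r`, `p_value`, `significant`.
#' @export
pearson_correlations <- function(x, table, alpha = 0.05) {
  stopifnot(is.numeric(x))
  if (!is.data.frame(table)) {
    table <- data.frame(variable = table)
  }
  num <- table[vapply(table, is.numeric, logical(1L))]
  if (!length(num)) stop("no numeric variables in table")
  rows <- lapply(names(num), function(v) {
    y <- num[[v]]
    stopifnot(length(y) == length(x))
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    miss <- data.frame(variable = v, n = n, r = NA_real_,
                       p_value = NA_real_, significant = NA,
                       stringsAsFactors = FALSE)
    if (n < 3L) return(miss)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(miss)
    ct <- stats::cor.test(x[ok], y[ok])
    data.frame(variable = v, n = n, r = unname(ct$estimate),
               p_value = ct$p.value, significant = ct$p.value < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
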