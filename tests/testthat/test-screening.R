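# Primer-selection pipeline: yield profiles, k2/k0 filter, amplicon-length
# stats, frequency matrices, theoretical optimal row, clustering.

test_that("primer_yield recovers planted per-group hit proportions", {
  db <- make_community_db(
    list(group_spec("Fungi", 20L, 400L, is_fungal = TRUE,
                    fwd_prop = 0.8, rev_prop = 0),
         group_spec("Other", 10L, 400L, fwd_prop = 0)),
    fr1_ff390(), seed = 77L)
  yp <- primer_yield(ff390(), db$collection, ks = 0:3,
                     fungal_groups = "Fungi")
  f0 <- subset(yp$table, group == "Fungi" & k == 0L)
  expect_identical(f0$count, 16L)
  expect_equal(f0$frequency, 80)
  expect_equal(unname(yp$fungal_total[["0"]]), 16)
  o0 <- subset(yp$table, group == "Other")
  expect_true(all(o0$count == 0L))
})

test_that("yield counts are non-decreasing in k on random collections", {
  db <- demo_community(seed = 19L, n = 10L)
  yp <- primer_yield(ff390(), db$collection, ks = 0:3,
                     fungal_groups = db$fungal_groups)
  for (g in unique(yp$table$group)) {
    cnt <- yp$table$count[yp$table$group == g][order(yp$table$k[yp$table$group == g])]
    expect_true(all(diff(cnt) >= 0L), label = g)
  }
  expect_error(primer_yield(ff390(), seq_collection(character(0L)), ks = 0L),
               "empty")
})

test_that("k2k0_filter applies the ratio rule and flags zero baselines", {
  mk <- function(name, k0, k2) {
    structure(list(primer = name,
                   fungal_total = c(`0` = k0, `1` = k0, `2` = k2, `3` = k2),
                   ks = 0:3), class = "yield_profile")
  }
  res <- k2k0_filter(list(mk("good", 100, 110), mk("poor", 50, 90),
                          mk("dead", 0, 40)), threshold = 1.2)
  expect_identical(res$retained, "good")
  expect_equal(res$table$ratio, c(1.1, 1.8, NA))
  expect_identical(res$table$flag, c("", "", "zero-baseline"))
})

test_that("amplicon_length_stats: planted constant product and arithmetic", {
  db <- make_community_db(
    group_spec("Fungi", 12L, 600L, is_fungal = TRUE, fwd_prop = 1,
               rev_prop = 1, product_length = 368L),
    fr1_ff390(), seed = 5L)
  st <- amplicon_length_stats(db$pset, db$collection)
  expect_identical(st$n_sequences, 12L)
  expect_equal(st$mean_length, 368)
  expect_equal(st$sd_length, 0)
})

test_that("sample sd with n-1 denominator on a known length set", {
  # products 350/360/370 planted via three single-sequence communities
  dbs <- lapply(c(350L, 360L, 370L), function(pl) {
    make_community_db(group_spec("G", 1L, 500L, fwd_prop = 1, rev_prop = 1,
                                 product_length = pl),
                      fr1_ff390(), seed = pl)
  })
  lens <- vapply(dbs, function(db) {
    amplicon_length_stats(db$pset, db$collection)$mean_length
  }, numeric(1L))
  expect_equal(lens, c(350, 360, 370))
  expect_equal(mean(lens), 360)
  expect_equal(sd(lens), 10)
  # single sequence: sd reported as 0, not NA
  one <- amplicon_length_stats(dbs[[1L]]$pset, dbs[[1L]]$collection)
  expect_identical(one$n_sequences, 1L)
  expect_equal(one$sd_length, 0)
})

test_that("length_threshold_filter retains strictly below the threshold", {
  stats <- data.frame(set = c("short", "edge", "long", "none"),
                      n_sequences = c(10L, 10L, 10L, 0L),
                      mean_length = c(135, 384, 523, NA),
                      sd_length = c(9, 1, 3, NA))
  res <- length_threshold_filter(stats, threshold = 384)
  expect_identical(res$retained, "short")
  expect_identical(res$table$flag, c("", "", "", "no-product"))
  all_in <- length_threshold_filter(stats, threshold = Inf)
  expect_identical(all_in$retained, c("short", "edge", "long"))
})

test_that("frequency_matrix equals the generator's planted proportions", {
  db <- demo_community(seed = 42L, n = 20L)
  fm <- frequency_matrix(list(db$pset), db$collection, k = 0L)
  expect_equal(fm["FR1_FF390", c("Asco", "Basidio", "Metazoa")],
               c(Asco = 90, Basidio = 50, Metazoa = 0))
  cnt <- frequency_matrix(list(db$pset), db$collection, k = 0L,
                          as_counts = TRUE)
  expect_equal(cnt["FR1_FF390", ], c(Asco = 18, Basidio = 10, Metazoa = 0))
})

test_that("a set-level hit requires both primers", {
  # forward planted everywhere, reverse nowhere -> set frequency 0
  db <- make_community_db(
    group_spec("G", 10L, 400L, fwd_prop = 1, rev_prop = 0),
    fr1_ff390(), seed = 13L)
  fm <- frequency_matrix(list(db$pset), db$collection, k = 0L)
  expect_equal(unname(fm["FR1_FF390", "G"]), 0)
  # and set-level frequency never exceeds either primer's own frequency
  db2 <- demo_community(seed = 21L, n = 10L)
  fm2 <- frequency_matrix(list(db2$pset), db2$collection, k = 0L)
  for (p in list(ff390(), fr1())) {
    yp <- primer_yield(p, db2$collection, ks = 0L)
    f <- yp$table$frequency[yp$table$k == 0L]
    names(f) <- yp$table$group[yp$table$k == 0L]
    expect_true(all(fm2[1L, names(f)] <= f + 1e-9), label = p$name)
  }
})

test_that("per-primer mode counts unpaired hits", {
  db <- make_community_db(
    group_spec("G", 10L, 400L, fwd_prop = 1, rev_prop = 0),
    fr1_ff390(), seed = 29L)
  fm <- frequency_matrix(list(db$pset), db$collection, k = 0L,
                         mode = "per_primer")
  expect_equal(unname(fm["FR1_FF390", "G"]), 0)  # reverse still absent
  db2 <- make_community_db(
    group_spec("G", 10L, 400L, fwd_prop = 1, rev_prop = 1,
               product_length = 368L),
    fr1_ff390(), seed = 31L)
  fm2 <- frequency_matrix(list(db2$pset), db2$collection, k = 0L,
                          mode = "per_primer")
  expect_equal(unname(fm2["FR1_FF390", "G"]), 100)
})

test_that("theoretical_optimal_row is 100 on fungal and 0 on other columns", {
  row <- theoretical_optimal_row(c("Asco", "Basidio", "Metazoa"),
                                 c("Asco", "Basidio"))
  expect_equal(row, c(Asco = 100, Basidio = 100, Metazoa = 0))
  expect_warning(zero <- theoretical_optimal_row(c("A", "B"), character(0L)),
                 "all zero")
  expect_equal(unname(zero), c(0, 0))
  expect_error(theoretical_optimal_row(c("A"), c("B")), "subset")
  cnts <- theoretical_optimal_row(c("A", "B"), "A", as_counts = TRUE,
                                  group_sizes = c(A = 40L, B = 7L))
  expect_equal(cnts, c(A = 40, B = 0))
})

test_that("identical rows merge first, and the optimal-like row joins optimal", {
  mat <- rbind(optimal = c(100, 100, 0, 0),
               twin = c(100, 100, 0, 0),
               anti = c(0, 0, 100, 100),
               noise = c(30, 70, 40, 60))
  colnames(mat) <- paste0("g", 1:4)
  cl <- cluster_primer_sets(mat, n_boot = 50L, seed = 2L)
  hc <- cl$hclust
  first <- sort(hc$labels[-hc$merge[1L, ]])
  expect_identical(first, c("optimal", "twin"))
  expect_equal(hc$height[1L], 0, tolerance = 1e-12)
})

test_that("cluster membership is invariant under row permutation", {
  set.seed(6)
  mat <- matrix(runif(7 * 5, 0, 100), nrow = 7,
                dimnames = list(paste0("set", 1:7), paste0("g", 1:5)))
  cl1 <- cluster_primer_sets(mat, n_boot = 30L, seed = 4L)
  cl2 <- cluster_primer_sets(mat[sample(7L), ], n_boot = 30L, seed = 4L)
  expect_identical(fungiqpcr:::cluster_members(cl1$hclust), fungiqpcr:::cluster_members(cl2$hclust))
  expect_identical(cl1$support$support, cl2$support$support)
})

test_that("planted orthogonal row blocks are recovered as the top split", {
  set.seed(8)
  ok <- 0L
  for (rep in 1:20) {
    block1 <- matrix(rep(c(100, 100, 0, 0, 0, 0), each = 3), nrow = 3,
                     byrow = FALSE) + matrix(rnorm(18, 0, 4), nrow = 3)
    block2 <- matrix(rep(c(0, 0, 0, 100, 100, 100), each = 3), nrow = 3,
                     byrow = FALSE) + matrix(rnorm(18, 0, 4), nrow = 3)
    mat <- rbind(block1, block2)
    dimnames(mat) <- list(paste0("s", 1:6), paste0("g", 1:6))
    cl <- cluster_primer_sets(mat, n_boot = 1L, seed = rep)
    top <- fungiqpcr:::cluster_members(cl$hclust)
    top <- top[lengths(top) == 3L]
    hit <- any(vapply(top, identical, logical(1L), y = c("s1", "s2", "s3")))
    ok <- ok + hit
  }
  expect_gte(ok, 19L)  # >= 95% of seeds
})

test_that("specificity_report is monotone in k and sees planted k=2 sites", {
  db <- make_community_db(
    list(group_spec("Exact", 10L, 500L, fwd_prop = 1, rev_prop = 1,
                    product_length = 300L),
         group_spec("TwoMM", 10L, 500L, fwd_prop = 1, rev_prop = 1,
                    fwd_mismatch = 2L, rev_mismatch = 2L,
                    product_length = 300L)),
    fr1_ff390(), seed = 91L)
  rep_tab <- specificity_report(db$pset, db$collection, ks = 0:3)
  freq <- function(g, k) {
    rep_tab$frequency[rep_tab$group == g & rep_tab$k == k]
  }
  expect_equal(freq("Exact", 0L), 100)
  expect_equal(freq("TwoMM", 0L), 0)
  expect_equal(freq("TwoMM", 1L), 0)
  expect_equal(freq("TwoMM", 2L), 100)
  expect_equal(freq("TwoMM", 3L), 100)
  for (g in c("Exact", "TwoMM")) {
    f <- vapply(0:3, freq, numeric(1L), g = g)
    expect_true(all(diff(f) >= 0), label = g)
  }
})
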