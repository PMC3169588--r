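# Standard curves, efficiency, detection limit, CVs, copies per gram, and
# the ecology statistics.

test_that("fit_standard_curve recovers an exact perfect-doubling curve", {
  q <- c(1e2, 1e3, 1e4, 1e5, 1e6)
  ct <- -3.3219 * log10(q) + 38
  curve <- fit_standard_curve(q, ct)
  expect_equal(curve$slope, -3.3219, tolerance = 1e-12)
  expect_equal(curve$intercept, 38, tolerance = 1e-10)
  expect_equal(curve$r_squared, 1, tolerance = 1e-12)
  expect_equal(100 * curve$efficiency, 100, tolerance = 0.02)
})

test_that("fit_standard_curve needs 3 distinct quantities and a negative slope", {
  expect_error(fit_standard_curve(c(10, 10, 10), c(30, 30.1, 29.9)),
               "3 distinct")
  expect_error(fit_standard_curve(c(10, 100), c(30, 27)), "3 distinct")
  expect_warning(bad <- fit_standard_curve(c(1e2, 1e3, 1e4), c(20, 25, 30)),
                 "invalid")
  expect_false(bad$valid)
})

test_that("efficiency follows E = 10^(-1/slope) - 1 with truncated reporting", {
  expect_identical(efficiency_percent(-3.24), 103L)
  expect_identical(efficiency_percent(-4.47), 67L)
  expect_identical(efficiency_percent(-1 / log10(2)), 100L)
  expect_error(efficiency_from_slope(3.3), "negative")
  # strictly decreasing in |slope|
  slopes <- -seq(2.5, 5, by = 0.1)
  eff <- efficiency_from_slope(slopes)
  expect_true(all(diff(eff) < 0))
})

test_that("windowed_efficiency tracks a quantity-dependent slope", {
  # two regimes: perfect doubling at low template, inhibited at high template
  q <- rep(c(0.5, 1, 2.5, 5, 10) * 1e3, each = 2L)
  slope_of <- function(qq) ifelse(qq > 2.5e3, -4.4, -3.3219)
  ct <- slope_of(q) * log10(q) + 36
  win <- windowed_efficiency(q, ct, window = 3L)
  expect_identical(nrow(win), 3L)
  expect_identical(win$efficiency_pct[1L], 100L)  # lowest three quantities
  expect_lt(win$efficiency_pct[3L], 100L)         # inhibited high-template end
  expect_error(windowed_efficiency(c(1, 10, 100), c(30, 27, 24), window = 4L),
               "fewer distinct")
})

test_that("estimate_copies inverts the curve and keeps undetected missing", {
  q <- 10^(2:6)
  curve <- fit_standard_curve(q, -3.5 * log10(q) + 36)
  expect_equal(estimate_copies(curve$intercept, curve), 1, tolerance = 1e-9)
  expect_equal(estimate_copies(-3.5 * log10(12345) + 36, curve), 12345,
               tolerance = 1e-6)
  expect_true(is.na(estimate_copies(NA_real_, curve)))
})

test_that("detection_limit applies the CT-separation rule", {
  std <- data.frame(quantity = c(3e2, 3e2, 3e3), ct = c(34.4, 34.6, 31.2))
  res <- detection_limit(std, ntc_ct = 38.0, delta = 3.3)
  expect_equal(res$limit, 3e2)
  expect_identical(res$status, "ok")
  # undetected NTC censored at the max cycle
  res40 <- detection_limit(std, ntc_ct = NA_real_, delta = 3.3,
                           max_cycle = 40)
  expect_equal(res40$ntc_ct, 40)
  expect_equal(res40$limit, 3e2)
  # nothing separated enough
  none <- detection_limit(data.frame(quantity = c(3e2, 3e3),
                                     ct = c(36.5, 35.9)),
                          ntc_ct = 38.0, delta = 3.3)
  expect_true(is.na(none$limit))
  expect_identical(none$status, "above largest tested dilution")
})

test_that("replicate_cv: known values and scale invariance", {
  expect_equal(replicate_cv(c(10, 10, 10)), 0)
  expect_equal(replicate_cv(c(8, 10, 12)), 20)
  set.seed(2)
  x <- rlnorm(10)
  for (c_ in c(0.01, 3, 1e6)) {
    expect_equal(replicate_cv(c_ * x), replicate_cv(x), tolerance = 1e-9)
  }
  expect_error(replicate_cv(5), "at least 2")
})

test_that("copies_per_gram does the ng-to-gram conversion linearly", {
  expect_equal(copies_per_gram(2.5e4, 2.5, 1e4), 1e8)
  expect_equal(copies_per_gram(2.5e4, 2.5, 2e4), 2e8)
  expect_error(copies_per_gram(-1, 2.5, 1e4), "positive")
  expect_error(copies_per_gram(2.5e4, 0, 1e4), "positive")
})

test_that("kruskal_wallis separates a shifted group and letters agree", {
  vals <- c(1:10, 101:110, 102:111)
  grp <- rep(c("low", "high1", "high2"), each = 10L)
  kw <- kruskal_wallis(vals, grp)
  expect_lt(kw$p_value, 0.001)
  pw <- kw$pairwise
  sig_low <- pw$significant[pw$group1 == "low" | pw$group2 == "low"]
  expect_true(all(sig_low))
  expect_false(all(pw$significant))  # high1 vs high2 not separated
  expect_identical(kw$letters[["high1"]], kw$letters[["high2"]])
  expect_false(kw$letters[["low"]] %in%
                 c(kw$letters[["high1"]], kw$letters[["high2"]]))
})

test_that("identical groups give p near 1 and a single shared letter", {
  vals <- rep(c(1, 2, 3, 4, 5), times = 3L)
  grp <- rep(c("a", "b", "c"), each = 5L)
  kw <- kruskal_wallis(vals, grp)
  expect_gt(kw$p_value, 0.95)
  expect_identical(unname(unique(kw$letters)), "a")
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(4)
  vals <- rlnorm(30, 10, 2)
  grp <- rep(c("x", "y", "z"), each = 10L)
  h0 <- kruskal_wallis(vals, grp)$statistic
  expect_equal(kruskal_wallis(log(vals), grp)$statistic, h0)
  expect_equal(kruskal_wallis(vals^3, grp)$statistic, h0)
  expect_equal(kruskal_wallis(rank(vals), grp)$statistic, h0)
})

test_that("small groups are excluded from the Kruskal-Wallis with a warning", {
  expect_warning(
    kw <- kruskal_wallis(c(1, 2, 3, 9, 10, 11, 5),
                         c("a", "a", "a", "b", "b", "b", "solo")),
    "solo")
  expect_identical(sort(names(kw$letters)), c("a", "b"))
})

test_that("pearson_correlations: exact cases and constant-variable handling", {
  x <- c(1, 2, 3, 4, 5, 6)
  res <- pearson_correlations(x, data.frame(double = 2 * x, neg = -x,
                                            flat = rep(7, 6),
                                            noise = c(2, 1, 4, 3, 6, 5)))
  expect_equal(res$r[res$variable == "double"], 1, tolerance = 1e-12)
  expect_equal(res$r[res$variable == "neg"], -1, tolerance = 1e-12)
  expect_true(is.na(res$r[res$variable == "flat"]))
  expect_identical(res$n, rep(6L, 4L))
})

test_that("read_plate validates roles and parses undetected CTs", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,well,role,quantity,ct,replicate",
               "std_300,W001,standard,300,34.5,1",
               "soilA,W002,unknown,2.5,27.1,1",
               "ntc,W003,ntc,,ND,1"), path)
  plate <- read_plate(path)
  expect_identical(nrow(plate), 3L)
  expect_true(is.na(plate$ct[3L]))
  writeLines(c("sample,well,role,quantity,ct,replicate",
               "x,W001,mystery,1,30,1"), path)
  expect_error(read_plate(path), "mystery")
})
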