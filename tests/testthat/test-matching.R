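# IUPAC/inosine matching, primer scanning and amplicon prediction.

test_that("base_set agrees with the IUPAC code map for every symbol", {
  for (sym in c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N", "I", "U")) {
    expect_identical(base_set(sym), sort(oracle_sets[[sym]]), label = sym)
  }
  expect_error(base_set("Z"), "unknown")
})

test_that("reverse_complement handles ambiguity codes and inosine", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("AAR"), "YTT")
  expect_identical(reverse_complement("I"), "I")
  expect_error(reverse_complement("AXG"), "unknown")
  # involution on random degenerate strings
  set.seed(3)
  alph <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N", "I")
  for (i in 1:100) {
    x <- paste(sample(alph, sample(5:40, 1L), replace = TRUE), collapse = "")
    expect_identical(reverse_complement(reverse_complement(x)), x)
  }
})

test_that("mismatch_count follows the set-intersection rule and is symmetric", {
  expect_identical(mismatch_count("ACGT", "ACGT"), 0L)
  expect_identical(mismatch_count("R", "A"), 0L)
  expect_identical(mismatch_count("R", "C"), 1L)
  expect_error(mismatch_count("ACG", "AC"), "length")

  set.seed(5)
  for (i in 1:50) {
    a <- random_dna(18L)
    m <- sample(0:4, 1L)
    b <- strsplit(a, "")[[1L]]
    pos <- sample(18L, m)
    for (p in pos) b[p] <- setdiff(c("A", "C", "G", "T"), b[p])[sample.int(3L, 1L)]
    b <- paste(b, collapse = "")
    expect_identical(mismatch_count(a, b), m)
    expect_identical(mismatch_count(b, a), m)
  }
})

test_that("strict mode stops target ambiguity matching specific primer bases", {
  expect_identical(mismatch_count("A", "N"), 0L)          # optimistic
  expect_identical(mismatch_count("A", "N", strict = TRUE), 1L)
  expect_identical(mismatch_count("N", "A", strict = TRUE), 0L)
})

test_that("scan_primer finds a planted exact FF390 site", {
  set.seed(9)
  site <- "CGATAACGAACGAGACCT"
  seqs <- c(rec = paste0(random_dna(60L), site, random_dna(60L)))
  # regenerate on collision with a spurious site
  while (nrow(oracle_scan_text(site, seqs[["rec"]], 0L)) != 1L) {
    seqs <- c(rec = paste0(random_dna(60L), site, random_dna(60L)))
  }
  hits <- scan_primer(ff390(), seqs, k_max = 0L)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 61L)
  expect_identical(hits$end, 78L)
  expect_identical(hits$mismatches, 0L)
  expect_identical(hits$strand, "sense")
})

test_that("scan_primer returns empty when nothing is in range and warns on short records", {
  seqs <- c(short = "ACGTACGT")
  expect_warning(hits <- scan_primer(ff390(), seqs, k_max = 3L), "longer")
  expect_identical(nrow(hits), 0L)
})

test_that("scan_primer matches the brute-force window oracle", {
  set.seed(17)
  fw <- ff390()
  rv <- fr1()
  rv_text <- reverse_complement(rv$sequence)
  for (i in 1:40) {
    seqs <- stats::setNames(random_dna(150L), paste0("r", i))
    for (k in 0:3) {
      got_f <- scan_primer(fw, seqs, k_max = k)
      exp_f <- oracle_scan_text(fw$sequence, seqs[[1L]], k)
      expect_identical(got_f[, c("start", "end", "mismatches")],
                       exp_f, label = sprintf("fwd i=%d k=%d", i, k))
      got_r <- scan_primer(rv, seqs, k_max = k)
      exp_r <- oracle_scan_text(rv_text, seqs[[1L]], k)
      expect_identical(got_r[, c("start", "end", "mismatches")],
                       exp_r, label = sprintf("rev i=%d k=%d", i, k))
    }
  }
})

test_that("sites at k_max = k are a subset of sites at k_max = k + 1", {
  set.seed(23)
  fw <- ff390()
  seqs <- stats::setNames(replicate(20L, random_dna(200L)), paste0("s", 1:20))
  for (k in 0:2) {
    lo <- scan_primer(fw, seqs, k_max = k)
    hi <- scan_primer(fw, seqs, k_max = k + 1L)
    key <- function(d) paste(d$sequence_id, d$start, d$strand)
    expect_true(all(key(lo) %in% key(hi)), label = paste("k =", k))
  }
})

test_that("predict_amplicons pairs planted sites into a 368-nt product", {
  set.seed(31)
  pset <- fr1_ff390()
  fwd_site <- "CGATAACGAACGAGACCT"               # FF390 as written
  rev_site <- reverse_complement("AICCATTCAATCGGTAIT")
  rev_site <- gsub("I", "A", rev_site)            # concrete realization
  # layout: fwd site at [101,118], rev antisense site at [451,468] -> 368 nt
  seqs <- c(rec = paste0(random_dna(100L), fwd_site, random_dna(332L),
                         rev_site, random_dna(132L)))
  amp <- predict_amplicons(pset, seqs, k_max = 0L)
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$fwd_start, 101L)
  expect_identical(amp$rev_end, 468L)
  expect_identical(amp$product_length, 368L)
})

test_that("a forward site alone yields no amplicon", {
  set.seed(37)
  seqs <- c(rec = paste0(random_dna(50L), "CGATAACGAACGAGACCT",
                         random_dna(200L)))
  amp <- predict_amplicons(fr1_ff390(), seqs, k_max = 0L)
  expect_identical(nrow(amp), 0L)
})

test_that("amplicon prediction is invariant under strand flip with auto_both", {
  db <- demo_community(seed = 55L, n = 8L)
  seqs <- db$collection$seqs
  fwd <- predict_amplicons(db$pset, seqs, k_max = 0L,
                           search_mode = "auto_both")
  flipped <- predict_amplicons(db$pset, reverse_complement(seqs),
                               k_max = 0L, search_mode = "auto_both")
  lens <- function(a) {
    lapply(split(a$product_length, a$sequence_id), sort)
  }
  expect_identical(lens(flipped), lens(fwd))
})
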