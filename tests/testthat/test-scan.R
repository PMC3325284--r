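test_that("retained_columns implements both deletion policies", {
  aln <- genus_alignment(c(a = "ACGTACGTAC", b = "ACG-ACGTNC"), "Toy")
  expect_equal(retained_columns(aln, 1, 10, "complete"),
               setdiff(1:10, c(4, 9)))
  expect_equal(retained_columns(aln, 1, 10, "pairwise"), 1:10)
  expect_equal(retained_columns(aln, 5, 8, "complete"), 5:8)
  expect_error(retained_columns(aln, 0, 5), "out of bounds")
  expect_error(retained_columns(aln, 5, 11), "out of bounds")

  # brute-force column oracle on random gapped windows
  gapped <- random_alignment(4, 300, seed = 5, gap_prob = 0.05,
                             amb_prob = 0.02)
  for (w in list(c(1, 50), c(101, 250), c(251, 300))) {
    got <- retained_columns(gapped, w[1], w[2], "complete")
    want <- (w[1]:w[2])[vapply(w[1]:w[2], function(cc) {
      all(gapped$seq[, cc] %in% BASES)
    }, TRUE)]
    expect_equal(got, want)
  }
})

test_that("segregating sites and diversity follow their definitions", {
  ident <- genus_alignment(c(a = strrep("ACGT", 25),
                             b = strrep("ACGT", 25)), "Toy")
  expect_equal(segregating_sites(ident, 1, 100), 0L)
  expect_equal(nucleotide_diversity(ident, 1, 100), 0)

  # 2 sequences differing at exactly 3 gap-free columns
  s <- strrep("A", 100)
  t <- s
  substr(t, 10, 10) <- "C"; substr(t, 50, 50) <- "G"
  substr(t, 90, 90) <- "T"
  pair <- genus_alignment(c(a = s, b = t), "Toy")
  expect_equal(segregating_sites(pair, 1, 100), 3L)
  # n = 2 closed form: 5 differences over 100 retained columns -> 0.05
  u <- s
  for (k in c(5, 20, 40, 60, 80)) substr(u, k, k) <- "G"
  pair5 <- genus_alignment(c(a = s, b = u), "Toy")
  expect_equal(nucleotide_diversity(pair5, 1, 100), 0.05)

  # three sequences: AAAA / AAAT / AATT -> (1 + 2 + 1) / (3 * 4)
  trio <- genus_alignment(c(a = "AAAA", b = "AAAT", c = "AATT"), "Toy")
  expect_equal(nucleotide_diversity(trio, 1, 4), 4 / 12)

  expect_error(nucleotide_diversity(ident, 1, 0), "out of bounds")
})

test_that("window statistics equal the brute-force oracle on random data", {
  aln <- random_alignment(4, 400, seed = 17, gap_prob = 0.04,
                          amb_prob = 0.02)
  set.seed(2)
  for (rep in 1:12) {
    s <- sample(1:320, 1)
    e <- s + sample(20:79, 1)
    for (pol in c("complete", "pairwise")) {
      want <- oracle_window_stats(aln, s, e, pol)
      expect_identical(segregating_sites(aln, s, e, pol),
                       want$S)
      expect_equal(length(retained_columns(aln, s, e, pol)),
                   want$L_retained)
      expect_equal(nucleotide_diversity(aln, s, e, pol), want$pi,
                   tolerance = 1e-12)
      expect_equal(indel_events(aln, s, e), want$indel_events)
    }
  }
})

test_that("indel events are maximal runs, shared runs collapse", {
  aln <- genus_alignment(
    c(a = "ACGTACGTACGTACGTACGT",
      b = "ACG-----ACGTACGTACGT", # one 5-column run
      c = "ACG-----ACGT--GTACGT"), # same run + a private run
    "Toy")
  expect_equal(indel_events(aln, 1, 20), 2L)
  expect_equal(indel_events(aln, 1, 3), 0L)
  expect_equal(indel_events(aln, 4, 10), 1L)   # counted at its start only
  expect_equal(indel_events(aln, 13, 20), 1L)
  nogap <- genus_alignment(c(a = "ACGT", b = "ACGT"), "Toy")
  expect_equal(indel_events(nogap, 1, 4), 0L)
})

test_that("window tiling arithmetic is exact", {
  a700 <- random_alignment(2, 700, seed = 1)
  p <- scan_windows(a700, 600, 50)
  expect_equal(p$windows$start, c(1L, 51L, 101L))
  expect_equal(p$windows$end, c(600L, 650L, 700L))

  a600 <- random_alignment(2, 600, seed = 2)
  expect_equal(nrow(scan_windows(a600, 600, 50)$windows), 1L)

  a10k <- random_alignment(2, 10000, seed = 3)
  p10k <- scan_windows(a10k, 600, 50)
  expect_equal(nrow(p10k$windows), 189L)
  expect_equal(nrow(p10k$windows), floor((10000 - 600) / 50) + 1)

  expect_error(scan_windows(random_alignment(2, 100, seed = 4), 600, 50),
               "lower the window")
})

test_that("profile summaries use max, mean and sample stdev", {
  expect_equal(summarize_profile(c(3, 3, 3)),
               list(S_max = 3, S_mean = 3, S_stdev = 0))
  two <- summarize_profile(c(0, 10))
  expect_equal(two$S_max, 10)
  expect_equal(two$S_mean, 5)
  expect_equal(two$S_stdev, 7.0710678, tolerance = 1e-6)
  set.seed(8)
  S <- sample(0:50, 40, replace = TRUE)
  sm <- summarize_profile(S)
  expect_equal(sm$S_mean, sum(S) / length(S))
  expect_equal(sm$S_stdev,
               sqrt(sum((S - mean(S))^2) / (length(S) - 1)))
  expect_error(summarize_profile(numeric()), "no windows")
})

test_that("for two sequences under complete deletion, pi * L equals S", {
  sim <- sim_separated(sim_config(seed = 21, genome_length = 12000L))
  p <- scan_windows(sim$alignment, 600, 50, "complete")
  w <- p$windows[p$windows$L_retained > 0, ]
  expect_true(all(abs(w$pi * w$L_retained - w$S) < 1e-9))
  expect_true(all(w$pi >= 0 & w$pi <= 1))
  expect_true(all(w$S <= w$L_retained))
  expect_equal(p$S_max, max(p$windows$S))
})

test_that("the scan is translation-consistent", {
  aln <- random_alignment(3, 1500, seed = 33, gap_prob = 0.02)
  p0 <- scan_windows(aln, 600, 50)
  k <- 2L
  pad <- strrep("T", k * 50L)
  shifted <- genus_alignment(
    stats::setNames(paste0(pad, apply(aln$seq, 1, paste, collapse = "")),
                    aln$taxa), "Rand")
  p1 <- scan_windows(shifted, 600, 50)
  m <- nrow(p0$windows)
  expect_equal(p1$windows$start[(k + 1):(m + k)] - k * 50L,
               p0$windows$start)
  expect_equal(p1$windows$S[(k + 1):(m + k)], p0$windows$S)
  expect_equal(p1$windows$pi[(k + 1):(m + k)], p0$windows$pi)
})

test_that("the fast scan equals a from-scratch per-window rescan", {
  sim <- sim_separated(sim_config(seed = 41, genome_length = 8000L,
                                  hotspot_count = 2L, gene_count = 10L))
  aln <- sim$alignment
  for (pol in c("complete", "pairwise")) {
    p <- scan_windows(aln, 600, 50, pol)
    for (i in seq_len(nrow(p$windows))) {
      s <- p$windows$start[i]; e <- p$windows$end[i]
      expect_identical(p$windows$S[i], segregating_sites(aln, s, e, pol))
      expect_equal(p$windows$pi[i], nucleotide_diversity(aln, s, e, pol),
                   tolerance = 1e-12)
      expect_equal(p$windows$indel_events[i], indel_events(aln, s, e))
    }
  }
})

test_that("profiles round-trip through TSV", {
  sim <- sim_separated(sim_config(seed = 55, genome_length = 4000L,
                                  hotspot_count = 1L, gene_count = 6L))
  p <- scan_windows(sim$alignment, 600, 50)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scan_profile(p, path)
  back <- read_scan_profile(path)
  expect_equal(back$windows$S, p$windows$S)
  expect_equal(back$windows$pi, p$windows$pi, tolerance = 1e-9)
  expect_equal(back$S_mean, p$S_mean, tolerance = 1e-12)
  expect_equal(back$window, p$window)
  expect_equal(back$genus, p$genus)
})
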