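# A scan profile built directly from window S values (summary optionally
# overridden, as for published statistics).
profile_from_S <- function(S, S_mean = NULL, S_stdev = NULL, step = 50L,
                           window = 600L) {
  starts <- 1L + step * (seq_along(S) - 1L)
  as_scan_profile(data.frame(start = starts, end = starts + window - 1L,
                             S = S),
                  window = window, step = step, genus_label = "fix",
                  S_mean = S_mean, S_stdev = S_stdev)
}

test_that("threshold selection applies S > mean + k * stdev strictly", {
  # published summary pair for the most variable congener set:
  # mean 9.67, stdev 9.00 -> cutoff at k = 2 is 27.67
  p <- profile_from_S(c(5, 27, 28, 49), S_mean = 9.67, S_stdev = 9.00)
  sel <- select_windows(p, k = 2)
  expect_equal(attr(sel, "cutoff"), 27.67)
  expect_equal(sel$S, c(28, 49))          # 28 qualifies, 27 does not

  # constant profile: stdev 0, strict inequality keeps nothing
  const <- profile_from_S(rep(7, 10))
  expect_equal(nrow(select_windows(const, 2)), 0L)

  expect_error(select_windows(p, k = -1), "non-negative")

  # random profile: naive filter oracle plus k-nestedness
  set.seed(12)
  S <- rpois(200, 6) + rbinom(200, 1, 0.05) * 40
  pr <- profile_from_S(S)
  for (k in c(1, 2, 3)) {
    got <- select_windows(pr, k)$S
    expect_equal(got, S[S > mean(S) + k * sd(S)])
  }
  q1 <- select_windows(pr, 1)$start
  q2 <- select_windows(pr, 2)$start
  q3 <- select_windows(pr, 3)$start
  expect_true(all(q2 %in% q1))
  expect_true(all(q3 %in% q2))
})

test_that("qualifying windows merge by overlap and bounded gaps", {
  w <- data.frame(start = c(1, 51), end = c(600, 650))
  m <- merge_windows(w, max_gap = 50)
  expect_equal(m$start, 1)
  expect_equal(m$end, 650)

  w2 <- data.frame(start = c(1, 2000), end = c(600, 2600))
  expect_equal(nrow(merge_windows(w2, 50)), 2L)

  # interval-union sweep oracle on random windows
  set.seed(9)
  for (rep in 1:5) {
    starts <- sort(sample(seq(1, 5000, by = 50), 50))
    w3 <- data.frame(start = starts, end = starts + 599)
    got <- merge_windows(w3, max_gap = 50)
    # oracle: mark covered positions with the gap tolerance
    covered <- rep(FALSE, 6000)
    for (i in seq_len(nrow(w3))) covered[w3$start[i]:w3$end[i]] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths); starts_r <- ends - r$lengths + 1L
    blocks <- data.frame(start = starts_r[r$values], end = ends[r$values])
    merged <- blocks[1, ]
    if (nrow(blocks) > 1) for (i in 2:nrow(blocks)) {
      if (blocks$start[i] - merged$end[nrow(merged)] - 1 <= 50) {
        merged$end[nrow(merged)] <- blocks$end[i]
      } else merged <- rbind(merged, blocks[i, ])
    }
    expect_equal(got$start, merged$start)
    expect_equal(got$end, merged$end)
  }
})

ft_fixture <- feature_table(
  name = c("trnH", "psbA", "ndhA", "ndhA", "ndhA", "ndhA", "ycf1"),
  kind = c("gene", "gene", "gene", "exon", "intron", "exon", "gene"),
  start = c(1L, 200L, 500L, 500L, 700L, 1100L, 1600L),
  end = c(80L, 400L, 1400L, 699L, 1099L, 1400L, 3000L))

aln_plain <- function(L = 3000L) {
  genus_alignment(stats::setNames(rep(strrep("ACGT", L / 4), 2),
                                  c("r", "s")), "Toy")
}

test_that("loci are classified and named from the annotation", {
  aln <- aln_plain()
  # fully inside the ndhA intron
  nm <- name_locus(750, 1050, ft_fixture, aln)
  expect_equal(nm$name, "ndhA intron")
  expect_equal(nm$category, "intron")
  # strictly between trnH and psbA
  nm2 <- name_locus(85, 195, ft_fixture, aln)
  expect_equal(nm2$name, "trnH-psbA")
  expect_equal(nm2$category, "intergenic_spacer")
  # mostly coding
  nm3 <- name_locus(1700, 2500, ft_fixture, aln)
  expect_equal(nm3$name, "ycf1")
  expect_equal(nm3$category, "coding")
  # empty feature table falls back to coordinates
  empty <- feature_table(character(), character(), integer(), integer())
  expect_warning(nm4 <- name_locus(10, 50, empty, aln), "empty feature")
  expect_equal(nm4$category, "mixed")
})

test_that("tRNA names carry anticodons only when paralogs make them ambiguous", {
  ft <- feature_table(
    name = c("trnS", "trnG", "trnS", "trnG", "psbZ"),
    kind = rep("gene", 5),
    start = c(100L, 600L, 2000L, 2200L, 2500L),
    end = c(180L, 680L, 2080L, 2280L, 2600L),
    anticodon = c("UGA", "UCC", "GCU", "GCC", NA))
  aln <- aln_plain()
  nm <- name_locus(200, 560, ft, aln)
  expect_equal(nm$name, "trnS^UGA^-trnG^UCC^")
  expect_equal(nm$category, "intergenic_spacer")
})

test_that("two disjoint loci in one gene get -a/-b suffixes", {
  # long gene hosting two variable regions; strong divergence in two
  # disjoint stretches of ycf1
  base <- strrep("ACGT", 750)
  other <- base
  for (k in seq(1701, 1901, by = 4)) substr(other, k, k) <- "T"
  for (k in seq(2601, 2801, by = 4)) substr(other, k, k) <- "C"
  aln <- genus_alignment(c(r = base, s = other), "Toy")
  prof <- scan_windows(aln, 200, 50)
  loci <- find_hotspots(prof, aln, ft_fixture, k = 2, max_gap = 50)
  ycf <- loci[grepl("^ycf1", loci$name), ]
  expect_equal(ycf$name, c("ycf1-a", "ycf1-b"))
  expect_true(all(diff(ycf$start) > 0))
})

test_that("hotspot loci carry recomputed statistics above the threshold", {
  sim <- sim_separated(sim_config(seed = 77))
  prof <- scan_windows(sim$alignment)
  loci <- find_hotspots(prof, sim$alignment, sim$features)
  expect_gt(nrow(loci), 0)
  cutoff <- prof$S_mean + 2 * prof$S_stdev
  expect_true(all(loci$S_locus > cutoff))
  expect_true(all(loci$threshold == cutoff))
  # pairwise non-overlapping, sorted
  if (nrow(loci) > 1) {
    expect_true(all(loci$start[-1] > loci$end[-nrow(loci)]))
  }
  # raising k never adds loci
  loci3 <- find_hotspots(prof, sim$alignment, sim$features, k = 3)
  expect_lte(nrow(loci3), nrow(loci))
  for (nm in loci3$name) {
    expect_true(any(intervals_overlap(loci$start, loci$end,
                                      loci3$start[loci3$name == nm],
                                      loci3$end[loci3$name == nm])))
  }
  # locus diversity well above the genome background
  bg_pi <- mean(prof$windows$pi, na.rm = TRUE)
  expect_true(all(loci$pi > bg_pi))
})

test_that("the locus report recomputes diversity and indicators", {
  sim <- sim_separated(sim_config(seed = 78))
  prof <- scan_windows(sim$alignment)
  loci <- find_hotspots(prof, sim$alignment, sim$features)
  controls <- data.frame(name = c("ctrl1", "ctrl2"),
                         start = c(1L, 1201L), end = c(600L, 1800L))
  rep_tab <- locus_report(loci, sim$alignment, controls = controls)
  expect_equal(nrow(rep_tab), nrow(loci) + 2L)
  expect_true(all(rep_tab$I == rep_tab$indel_events +
                    rep_tab$inversion_events))
  # single-window locus: report pi equals that window's pi
  w1 <- prof$windows[1, ]
  one <- locus_report(data.frame(name = "w1", category = "x",
                                 start = w1$start, end = w1$end),
                      sim$alignment)
  expect_equal(one$pi, w1$pi, tolerance = 1e-12)
  # an invariant locus scores zero on every indicator
  const <- genus_alignment(c(a = strrep("AC", 500),
                             b = strrep("AC", 500)), "Toy")
  z <- locus_report(data.frame(name = "flat", category = "x",
                               start = 1L, end = 1000L), const)
  expect_equal(z$pi, 0)
  expect_equal(z$I, 0L)
})

test_that("hotspot BED output is zero-based half-open", {
  loci <- data.frame(genus = "G", name = "x", category = "coding",
                     start = 101L, end = 700L, ref_start = 101L,
                     ref_end = 700L, length = 600L, n_windows = 3L,
                     S_locus = 30L, pi = 0.03, indel_events = 1L,
                     inversion_events = 0L, threshold = 20)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_hotspots(loci, bed_path = bed)
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(as.integer(fields[2:3]), c(100L, 700L))
})
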