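# Sliding-window variability scan: per-window segregating sites S,
# nucleotide diversity per site (pi) and indel/inversion event counts over
# an aligned set of congeneric genomes, with whole-profile summaries
# (S_max, mean, sample standard deviation) that feed the hotspot threshold.
#
# Two site-deletion policies are exposed. Under "complete" deletion a
# column is analyzed only if no sequence has a gap or ambiguity there
# (the conventional treatment of gapped sites in population-genetic
# software). Under "pairwise" deletion all columns are kept and each
# sequence pair is filtered separately inside the pi computation.

is_base <- function(chars) chars %in% DNA_BASES

check_window_range <- function(aln, start, end) {
  L <- alignment_length(aln)
  if (!is_count(start) || !is_count(end) || start < 1L || end > L ||
      start > end) {
    stop("window [", start, ",", end, "] out of bounds for alignment of ",
         "length ", L)
  }
}

#' Columns retained by a deletion policy
#'
#' @param aln A [genus_alignment].
#' @param start,end 1-based inclusive alignment coordinates.
#' @param policy `"complete"` (columns where no sequence has a gap or
#'   missing/ambiguous character) or `"pairwise"` (all columns; per-pair
#'   filtering happens inside [nucleotide_diversity]).
#' @return Integer vector of retained column indices.
#' @export
retained_columns <- function(aln, start, end,
                             policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  check_window_range(aln, start, end)
  idx <- start:end
  if (policy == "pairwise") return(idx)
  sub <- aln$seq[, idx, drop = FALSE]
  ok <- colSums(matrix(is_base(sub), nrow = nrow(sub))) == nrow(sub)
  idx[ok]
}

#' Count segregating (polymorphic) sites in a window
#'
#' A retained column is segregating when it shows at least two distinct
#' residue states among its non-missing characters.
#'
#' @inheritParams retained_columns
#' @return Integer count S.
#' @export
segregating_sites <- function(aln, start, end,
                              policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  idx <- retained_columns(aln, start, end, policy)
  if (length(idx) == 0L) return(0L)
  sub <- aln$seq[, idx, drop = FALSE]
  n_states <- 0L
  for (b in DNA_BASES) {
    n_states <- n_states + (colSums(matrix(sub == b, nrow = nrow(sub))) > 0L)
  }
  sum(n_states >= 2L)
}

#' Nucleotide diversity per site in a window
#'
#' Computes \eqn{\pi = \frac{2}{n(n-1)} \sum_{i<j} d_{ij} / L_{ij}} where
#' \eqn{d_{ij}} counts differing residues between sequences i and j over
#' the columns retained for that pair, and \eqn{L_{ij}} is the pair's
#' retained-column count (identical for all pairs under complete deletion).
#' Pairs with no analyzable columns are skipped and the pair count
#' adjusted; when no pair has analyzable columns the window's diversity is
#' undefined and `NA` is returned (never 0, which would fake conservation).
#'
#' @inheritParams retained_columns
#' @return Numeric \eqn{\pi \in [0,1]}, or `NA` when undefined.
#' @export
nucleotide_diversity <- function(aln, start, end,
                                 policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  n <- nrow(aln$seq)
  if (n < 2L) stop("nucleotide diversity needs >= 2 sequences")
  check_window_range(aln, start, end)
  pairs <- utils::combn(n, 2L)
  if (policy == "complete") {
    idx <- retained_columns(aln, start, end, "complete")
    if (length(idx) == 0L) return(NA_real_)
    sub <- aln$seq[, idx, drop = FALSE]
    d <- 0
    for (p in seq_len(ncol(pairs))) {
      d <- d + sum(sub[pairs[1L, p], ] != sub[pairs[2L, p], ])
    }
    return(d / (ncol(pairs) * length(idx)))
  }
  sub <- aln$seq[, start:end, drop = FALSE]
  ok <- matrix(is_base(sub), nrow = nrow(sub))
  total <- 0
  used <- 0L
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    both <- ok[i, ] & ok[j, ]
    L_ij <- sum(both)
    if (L_ij == 0L) next
    total <- total + sum(sub[i, both] != sub[j, both]) / L_ij
    used <- used + 1L
  }
  if (used == 0L) return(NA_real_)
  total / used
}

# Maximal gap runs across the alignment: one row per distinct (start, end)
# event. Runs with identical coordinates in several sequences are collapsed
# into a single event (they represent one shared indel).
gap_events <- function(aln) {
  ev <- list()
  for (i in seq_len(nrow(aln$seq))) {
    r <- rle(aln$seq[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    g <- which(r$values)
    if (length(g)) {
      ev[[length(ev) + 1L]] <- data.frame(start = starts[g], end = ends[g])
    }
  }
  if (length(ev) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  ev <- do.call(rbind, ev)
  ev <- unique(ev)
  ev[order(ev$start, ev$end), , drop = FALSE]
}

#' Count indel events in a window
#'
#' An indel event is a maximal run of gap characters in one sequence;
#' identical runs shared by several sequences count once. An event is
#' assigned to the window containing its first gap column, so each event is
#' counted exactly once across a profile's tiling.
#'
#' @inheritParams retained_columns
#' @return Integer event count.
#' @export
indel_events <- function(aln, start, end) {
  check_window_range(aln, start, end)
  ev <- gap_events(aln)
  sum(ev$start >= start & ev$start <= end)
}

# Inversion events recorded on the alignment whose first column lies in
# [start, end].
inversion_events <- function(aln, start, end) {
  inv <- aln$inversions
  if (is.null(inv) || nrow(inv) == 0L) return(0L)
  sum(inv$start >= start & inv$start <= end)
}

#' Sliding-window scan of a genus alignment
#'
#' Windows of `window` bp advance by `step` bp from position 1 on
#' alignment coordinates; a trailing stretch shorter than one full window
#' is not scanned (kept lengths comparable across windows; the skipped
#' length is stored in the result). The default window length of 600 bp is
#' the typical length of a DNA barcode read; the 50 bp step positions
#' variable regions to within one step.
#'
#' @param aln A [genus_alignment].
#' @param window Window length in bp (default 600).
#' @param step Step size in bp (default 50).
#' @param policy Site-deletion policy, see [retained_columns].
#' @return An object of class `scan_profile`: list with the per-window data
#'   frame `windows` (columns `start`, `end`, `midpoint`, `S`,
#'   `L_retained`, `pi`, `indel_events`, `inversion_events`) and the
#'   summaries `S_max`, `S_mean`, `S_stdev` (sample standard deviation).
#' @export
scan_windows <- function(aln, window = 600L, step = 50L,
                         policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  stopifnot(is_count(window), is_count(step), window >= 1L, step >= 1L,
            step <= window)
  L <- alignment_length(aln)
  if (L < window) {
    stop("alignment length ", L, " is shorter than the window (", window,
         " bp); lower the window length")
  }
  starts <- seq.int(1L, L - window + 1L, by = step)
  ends <- starts + window - 1L
  skipped <- L - ends[length(ends)]

  M <- aln$seq
  n <- nrow(M)
  ok <- matrix(is_base(M), nrow = n)
  valid_all <- colSums(ok) == n
  n_states <- 0L
  for (b in DNA_BASES) n_states <- n_states + (colSums(M == b) > 0L)
  seg <- n_states >= 2L

  cs <- function(x) c(0, cumsum(x))
  cs_valid <- cs(valid_all)
  cs_seg_valid <- cs(seg & valid_all)
  cs_seg <- cs(seg)

  pairs <- utils::combn(n, 2L)
  np <- ncol(pairs)
  if (policy == "complete") {
    diff_tot <- 0
    for (p in seq_len(np)) {
      diff_tot <- diff_tot + (M[pairs[1L, p], ] != M[pairs[2L, p], ])
    }
    cs_diff <- cs(diff_tot * valid_all)
    L_ret <- range_sum(cs_valid, starts, ends)
    S <- range_sum(cs_seg_valid, starts, ends)
    pi <- ifelse(L_ret > 0L, range_sum(cs_diff, starts, ends) / (np * L_ret),
                 NA_real_)
  } else {
    L_ret <- ends - starts + 1L
    S <- range_sum(cs_seg, starts, ends)
    num <- matrix(0, nrow = length(starts), ncol = np)
    den <- matrix(0L, nrow = length(starts), ncol = np)
    for (p in seq_len(np)) {
      i <- pairs[1L, p]; j <- pairs[2L, p]
      both <- ok[i, ] & ok[j, ]
      cs_b <- cs(both)
      cs_d <- cs(both & (M[i, ] != M[j, ]))
      den[, p] <- range_sum(cs_b, starts, ends)
      num[, p] <- range_sum(cs_d, starts, ends)
    }
    ratio <- num / den            # NaN where den == 0
    pi <- rowMeans(ratio, na.rm = TRUE)
    pi[rowSums(den > 0L) == 0L] <- NA_real_
  }

  ev <- gap_events(aln)
  ind <- vapply(seq_along(starts), function(w) {
    sum(ev$start >= starts[w] & ev$start <= ends[w])
  }, 0L)
  inv <- vapply(seq_along(starts), function(w) {
    inversion_events(aln, starts[w], ends[w])
  }, 0L)

  windows <- data.frame(start = starts, end = ends,
                        midpoint = (starts + ends) / 2,
                        S = as.integer(S), L_retained = as.integer(L_ret),
                        pi = as.numeric(pi), indel_events = ind,
                        inversion_events = inv)
  as_scan_profile(windows, window = window, step = step,
                  genus_label = aln$genus, policy = policy,
                  skipped_tail = skipped, n_taxa = n)
}

#' Assemble a scan profile from per-window statistics
#'
#' Normally produced by [scan_windows]; exposed so that profiles read back
#' from disk, or profiles known only through published summary statistics,
#' can be fed to the hotspot-selection stage. When `S_mean`/`S_stdev`/
#' `S_max` are supplied they override the values recomputed from `windows`
#' (use this to apply a published mean/stdev pair as the threshold basis).
#'
#' @param windows Data frame with at least columns `start`, `end`, `S`;
#'   ordered by `start` with consecutive starts differing by `step`.
#' @param window,step Window length and step size in bp.
#' @param genus_label Genus label.
#' @param policy Deletion policy the windows were computed under.
#' @param S_mean,S_stdev,S_max Optional summary overrides.
#' @param skipped_tail,n_taxa Bookkeeping fields.
#' @return A `scan_profile`.
#' @export
as_scan_profile <- function(windows, window, step, genus_label = "",
                            policy = "complete", S_mean = NULL,
                            S_stdev = NULL, S_max = NULL, skipped_tail = 0L,
                            n_taxa = NA_integer_) {
  stopifnot(is.data.frame(windows),
            all(c("start", "end", "S") %in% names(windows)))
  if (nrow(windows) == 0L) stop("a scan profile needs at least one window")
  if (is.unsorted(windows$start, strictly = TRUE)) {
    stop("windows must be ordered by start")
  }
  if (nrow(windows) > 1L && any(diff(windows$start) != step)) {
    stop("consecutive window starts must differ by the step size")
  }
  sm <- summarize_profile(windows$S)
  structure(
    list(genus = genus_label, window = as.integer(window),
         step = as.integer(step), policy = policy, windows = windows,
         S_max = S_max %||% sm$S_max, S_mean = S_mean %||% sm$S_mean,
         S_stdev = S_stdev %||% sm$S_stdev,
         skipped_tail = as.integer(skipped_tail), n_taxa = n_taxa),
    class = "scan_profile")
}

#' Summary statistics of a profile's segregating-site counts
#'
#' @param S Numeric vector of per-window segregating-site counts.
#' @return List with `S_max`, `S_mean` and `S_stdev` (sample standard
#'   deviation, n-1 denominator; 0 for a single window).
#' @export
summarize_profile <- function(S) {
  if (length(S) == 0L) stop("no windows to summarize")
  list(S_max = max(S), S_mean = mean(S),
       S_stdev = if (length(S) > 1L) stats::sd(S) else 0)
}

#' @export
print.scan_profile <- function(x, ...) {
  cat("scan_profile '", x$genus, "': ", nrow(x$windows), " windows (",
      x$window, " bp / step ", x$step, ", ", x$policy, " deletion)\n",
      "  S_max = ", x$S_max, ", S_mean = ", round(x$S_mean, 2),
      ", S_stdev = ", round(x$S_stdev, 2), "\n", sep = "")
  invisible(x)
}

#' Write / read a scan profile as TSV
#'
#' The file carries the per-window table plus `#`-prefixed header lines
#' with the scan parameters and summaries, so a profile round-trips.
#'
#' @param profile A `scan_profile`.
#' @param path File path.
#' @return `path` (write) or a `scan_profile` (read).
#' @export
write_scan_profile <- function(profile, path) {
  hdr <- sprintf("# %s=%s",
                 c("genus", "window", "step", "policy", "S_max", "S_mean",
                   "S_stdev", "skipped_tail", "n_taxa"),
                 c(profile$genus, profile$window, profile$step,
                   profile$policy, profile$S_max,
                   format(profile$S_mean, digits = 15),
                   format(profile$S_stdev, digits = 15),
                   profile$skipped_tail, profile$n_taxa))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(profile$windows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan_profile
#' @export
read_scan_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), "=", fixed = TRUE))
  meta <- stats::setNames(kv[, 2L], kv[, 1L])
  windows <- utils::read.table(text = lines[!grepl("^# ", lines)],
                               header = TRUE, sep = "\t")
  as_scan_profile(windows, window = as.integer(meta[["window"]]),
                  step = as.integer(meta[["step"]]),
                  genus_label = meta[["genus"]], policy = meta[["policy"]],
                  S_mean = as.numeric(meta[["S_mean"]]),
                  S_stdev = as.numeric(meta[["S_stdev"]]),
                  S_max = as.numeric(meta[["S_max"]]),
                  skipped_tail = as.integer(meta[["skipped_tail"]]),
                  n_taxa = as.integer(meta[["n_taxa"]]))
}
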