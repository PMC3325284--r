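# Hotspot loci: windows whose segregating-site count exceeds
# mean + k * stdev of the profile are merged into regions, mapped onto the
# reference annotation, and named the way variable plastome loci are named
# in the field: a gene name for mostly-coding regions, "<gene> intron" for
# introns, "<left>-<right>" for intergenic spacers (tRNA names carry their
# anticodon when paralogs make the bare name ambiguous), and "-a"/"-b"
# suffixes when one gene hosts several disjoint variable regions.

#' Select windows above the variability threshold
#'
#' Keeps windows with `S` strictly greater than `S_mean + k * S_stdev` of
#' the profile. With the default `k = 2` this isolates roughly the upper
#' tail of the window distribution - the "most variable loci" criterion.
#'
#' @param profile A `scan_profile`.
#' @param k Non-negative threshold multiplier (default 2).
#' @return The qualifying rows of `profile$windows`, order preserved, with
#'   the cutoff attached as attribute `"cutoff"`.
#' @export
select_windows <- function(profile, k = 2) {
  stopifnot(inherits(profile, "scan_profile"))
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0) {
    stop("threshold multiplier k must be a non-negative number")
  }
  cutoff <- profile$S_mean + k * profile$S_stdev
  out <- profile$windows[profile$windows$S > cutoff, , drop = FALSE]
  attr(out, "cutoff") <- cutoff
  out
}

#' Merge qualifying windows into candidate loci
#'
#' Overlapping windows, and windows separated by a gap of at most
#' `max_gap` bp, fuse into one interval covering their union. The default
#' gap equals the scan step: windows more than one step apart stay
#' distinct loci (this is what keeps two separate variable regions of one
#' long gene, the "-a"/"-b" situation, from being glued together, while
#' still bridging one-window staircase artifacts).
#'
#' @param windows Data frame with columns `start`, `end` (any extra
#'   columns are ignored); sorted internally by `start`.
#' @param max_gap Maximum gap in bp bridged when merging.
#' @return Data frame of merged intervals, sorted and non-overlapping,
#'   with an `n_windows` column.
#' @export
merge_windows <- function(windows, max_gap = 50L) {
  if (nrow(windows) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      n_windows = integer()))
  }
  w <- windows[order(windows$start, windows$end), , drop = FALSE]
  start <- w$start[1L]; end <- w$end[1L]; count <- 1L
  out <- list()
  for (i in seq_len(nrow(w))[-1L]) {
    gap <- w$start[i] - end - 1L
    if (gap <= max_gap) {
      end <- max(end, w$end[i])
      count <- count + 1L
    } else {
      out[[length(out) + 1L]] <- data.frame(start = start, end = end,
                                            n_windows = count)
      start <- w$start[i]; end <- w$end[i]; count <- 1L
    }
  }
  out[[length(out) + 1L]] <- data.frame(start = start, end = end,
                                        n_windows = count)
  do.call(rbind, out)
}

# Intergenic intervals (complement of the union of gene spans) with the
# display names of the flanking genes, on ungapped reference coordinates.
intergenic_intervals <- function(features, ref_len) {
  genes <- features[features$kind == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      name = character()))
  }
  disp <- gene_display_names(features)
  genes <- genes[order(genes$start, genes$end), , drop = FALSE]
  genes$display <- disp[paste0(genes$name, "@", genes$start)]
  # Union of gene spans, remembering the last gene of each merged block
  # and the first gene of the next.
  blocks <- list()
  bs <- genes$start[1L]; be <- genes$end[1L]
  first_g <- genes$display[1L]; last_g <- genes$display[1L]
  for (i in seq_len(nrow(genes))[-1L]) {
    if (genes$start[i] <= be + 1L) {
      if (genes$end[i] >= be) last_g <- genes$display[i]
      be <- max(be, genes$end[i])
    } else {
      blocks[[length(blocks) + 1L]] <- list(start = bs, end = be,
                                            first = first_g, last = last_g)
      bs <- genes$start[i]; be <- genes$end[i]
      first_g <- genes$display[i]; last_g <- genes$display[i]
    }
  }
  blocks[[length(blocks) + 1L]] <- list(start = bs, end = be,
                                        first = first_g, last = last_g)
  sp <- list()
  if (blocks[[1L]]$start > 1L) {
    sp[[1L]] <- data.frame(start = 1L, end = blocks[[1L]]$start - 1L,
                           name = paste0("start-", blocks[[1L]]$first))
  }
  if (length(blocks) > 1L) {
    for (i in seq_len(length(blocks) - 1L)) {
      sp[[length(sp) + 1L]] <- data.frame(
        start = blocks[[i]]$end + 1L, end = blocks[[i + 1L]]$start - 1L,
        name = paste0(blocks[[i]]$last, "-", blocks[[i + 1L]]$first))
    }
  }
  lastb <- blocks[[length(blocks)]]
  if (lastb$end < ref_len) {
    sp[[length(sp) + 1L]] <- data.frame(start = lastb$end + 1L,
                                        end = ref_len,
                                        name = paste0(lastb$last, "-end"))
  }
  if (length(sp) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      name = character()))
  }
  do.call(rbind, sp)
}

# Coding spans per gene: exons when annotated, otherwise the gene interval
# minus any annotated introns, otherwise the whole gene interval.
coding_spans <- function(features) {
  genes <- features[features$kind == "gene", , drop = FALSE]
  disp <- gene_display_names(features)
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    key <- paste0(g$name, "@", g$start)
    ex <- features[features$kind == "exon" & features$name == g$name &
                     features$start >= g$start & features$end <= g$end, ,
                   drop = FALSE]
    if (nrow(ex) > 0L) {
      spans <- ex[, c("start", "end")]
    } else {
      intr <- features[features$kind == "intron" & features$name == g$name &
                         features$start >= g$start & features$end <= g$end, ,
                       drop = FALSE]
      if (nrow(intr) == 0L) {
        spans <- data.frame(start = g$start, end = g$end)
      } else {
        intr <- intr[order(intr$start), , drop = FALSE]
        bounds_s <- c(g$start, intr$end + 1L)
        bounds_e <- c(intr$start - 1L, g$end)
        keep <- bounds_s <= bounds_e
        spans <- data.frame(start = bounds_s[keep], end = bounds_e[keep])
      }
    }
    spans$name <- disp[[key]]
    out[[length(out) + 1L]] <- spans
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      name = character()))
  }
  do.call(rbind, out)
}

#' Name and classify a candidate locus from the reference annotation
#'
#' The interval (alignment coordinates) is first mapped to ungapped
#' reference coordinates through the reference row's gap structure, then
#' classified by majority overlap: `coding` when at least half of it lies
#' in the coding spans of a single gene, `intron` when at least half lies
#' in one gene's intron, `intergenic_spacer` when at least half lies in
#' one spacer between genes, and `mixed` otherwise (named after the
#' dominant overlapped element). With an empty feature table the locus is
#' named by its coordinates and classified `mixed`.
#'
#' @param start,end Locus interval, 1-based inclusive alignment
#'   coordinates.
#' @param features A [feature_table] on the reference sequence.
#' @param aln The [genus_alignment] providing the reference gap structure.
#' @return List with `name`, `category`, `ref_start`, `ref_end`.
#' @export
name_locus <- function(start, end, features, aln) {
  ref <- map_to_ungapped(aln, start, end)
  coord_name <- function() {
    list(name = sprintf("region_%d_%d", start, end), category = "mixed",
         ref_start = ref[1L], ref_end = ref[2L])
  }
  if (is.na(ref[1L])) return(coord_name())
  if (nrow(features) == 0L) {
    warning("empty feature table: naming loci by coordinates")
    return(coord_name())
  }
  ref_len <- sum(aln$seq[aln$reference, ] != "-")
  len <- ref[2L] - ref[1L] + 1L

  cover <- function(tab) {
    if (nrow(tab) == 0L) return(numeric())
    ov <- overlap_length(ref[1L], ref[2L], tab$start, tab$end)
    tapply(ov, tab$name, sum)
  }
  cod <- cover(coding_spans(features))
  intr_tab <- features[features$kind == "intron", , drop = FALSE]
  intr <- cover(intr_tab)
  sp_tab <- intergenic_intervals(features, ref_len)
  spc <- if (nrow(sp_tab) == 0L) numeric() else {
    ov <- overlap_length(ref[1L], ref[2L], sp_tab$start, sp_tab$end)
    stats::setNames(ov, sp_tab$name)   # spacers are disjoint by construction
  }

  half <- len / 2
  if (length(cod) && max(cod) >= half) {
    return(list(name = names(cod)[which.max(cod)], category = "coding",
                ref_start = ref[1L], ref_end = ref[2L]))
  }
  if (length(intr) && max(intr) >= half) {
    return(list(name = paste(names(intr)[which.max(intr)], "intron"),
                category = "intron", ref_start = ref[1L], ref_end = ref[2L]))
  }
  if (length(spc) && max(spc) >= half) {
    return(list(name = names(spc)[which.max(spc)],
                category = "intergenic_spacer",
                ref_start = ref[1L], ref_end = ref[2L]))
  }
  # Mixed: dominant element of any kind.
  cand <- c(if (length(cod)) stats::setNames(as.numeric(cod), names(cod)),
            if (length(intr)) stats::setNames(as.numeric(intr),
                                              paste(names(intr), "intron")),
            if (length(spc)) stats::setNames(as.numeric(spc), names(spc)))
  if (length(cand) == 0L || max(cand) == 0) return(coord_name())
  list(name = names(cand)[which.max(cand)], category = "mixed",
       ref_start = ref[1L], ref_end = ref[2L])
}

# Deduplicate repeated locus names with -a/-b/... suffixes in coordinate
# order (the convention for two disjoint variable regions of one gene).
suffix_duplicates <- function(names, starts) {
  out <- names
  for (nm in unique(names[duplicated(names)])) {
    idx <- which(names == nm)
    idx <- idx[order(starts[idx])]
    out[idx] <- paste0(nm, "-", letters[seq_along(idx)])
  }
  out
}

#' Identify named hotspot loci in a scan profile
#'
#' Runs threshold selection ([select_windows]), merging
#' ([merge_windows]) and annotation-based naming ([name_locus]), then
#' recomputes per-locus statistics over each locus's full span.
#'
#' @param profile A `scan_profile` produced by [scan_windows].
#' @param aln The scanned [genus_alignment].
#' @param features A [feature_table] for the reference sequence.
#' @param k Threshold multiplier (default 2).
#' @param max_gap Merge gap in bp; defaults to the profile's step.
#' @return A data frame of class `hotspot_loci` with one row per locus:
#'   `genus`, `name`, `category`, `start`, `end` (alignment coordinates),
#'   `ref_start`, `ref_end`, `length`, `n_windows`, `S_locus` (maximum
#'   window S inside the locus), `pi` (recomputed over the locus span),
#'   `indel_events`, `inversion_events`, `threshold`.
#' @export
find_hotspots <- function(profile, aln, features, k = 2,
                          max_gap = profile$step) {
  stopifnot(inherits(profile, "scan_profile"),
            inherits(aln, "genus_alignment"))
  qual <- select_windows(profile, k)
  cutoff <- attr(qual, "cutoff")
  merged <- merge_windows(qual, max_gap = max_gap)
  if (nrow(merged) == 0L) {
    out <- data.frame(genus = character(), name = character(),
                      category = character(), start = integer(),
                      end = integer(), ref_start = integer(),
                      ref_end = integer(), length = integer(),
                      n_windows = integer(), S_locus = integer(),
                      pi = numeric(), indel_events = integer(),
                      inversion_events = integer(), threshold = numeric())
    class(out) <- c("hotspot_loci", "data.frame")
    return(out)
  }
  rows <- lapply(seq_len(nrow(merged)), function(i) {
    s <- merged$start[i]; e <- merged$end[i]
    nm <- name_locus(s, e, features, aln)
    inside <- profile$windows$start >= s & profile$windows$end <= e
    S_locus <- max(profile$windows$S[inside])
    data.frame(genus = aln$genus, name = nm$name, category = nm$category,
               start = s, end = e, ref_start = nm$ref_start,
               ref_end = nm$ref_end, length = e - s + 1L,
               n_windows = merged$n_windows[i], S_locus = S_locus,
               pi = nucleotide_diversity(aln, s, e, profile$policy),
               indel_events = indel_events(aln, s, e),
               inversion_events = inversion_events(aln, s, e),
               threshold = cutoff)
  })
  out <- do.call(rbind, rows)
  out$name <- suffix_duplicates(out$name, out$start)
  class(out) <- c("hotspot_loci", "data.frame")
  out
}

#' Per-locus statistics report
#'
#' Recomputes diversity and indel/inversion indicators over arbitrary
#' named intervals: the discovered loci plus, optionally, user-supplied
#' control loci (e.g. the canonical barcode candidates atpF-atpH, rbcL,
#' rpoB, rpoC1 given as alignment intervals) for side-by-side comparison.
#'
#' @param loci Data frame with columns `name`, `start`, `end` (alignment
#'   coordinates), typically a `hotspot_loci` object.
#' @param aln The [genus_alignment].
#' @param controls Optional data frame with columns `name`, `start`,
#'   `end`; reported with category `"control"`.
#' @param policy Deletion policy for the recomputed diversity.
#' @return Data frame with one row per locus: `name`, `category`,
#'   `start`, `end`, `length`, `S`, `pi`, `indel_events`,
#'   `inversion_events`, `I` (indels plus inversions).
#' @export
locus_report <- function(loci, aln, controls = NULL, policy = "complete") {
  tab <- data.frame(name = loci$name, category = loci$category %||%
                      rep("locus", nrow(loci)),
                    start = loci$start, end = loci$end)
  if (!is.null(controls)) {
    tab <- rbind(tab, data.frame(name = controls$name, category = "control",
                                 start = controls$start,
                                 end = controls$end))
  }
  stats_rows <- lapply(seq_len(nrow(tab)), function(i) {
    s <- tab$start[i]; e <- tab$end[i]
    ind <- indel_events(aln, s, e)
    inv <- inversion_events(aln, s, e)
    data.frame(name = tab$name[i], category = tab$category[i], start = s,
               end = e, length = e - s + 1L,
               S = segregating_sites(aln, s, e, policy),
               pi = nucleotide_diversity(aln, s, e, policy),
               indel_events = ind, inversion_events = inv, I = ind + inv)
  })
  do.call(rbind, stats_rows)
}

#' Write hotspot loci as BED and TSV
#'
#' The BED file is 0-based half-open per the BED standard; the TSV report
#' keeps 1-based inclusive coordinates like every other report in the
#' package.
#'
#' @param loci A `hotspot_loci` data frame.
#' @param tsv_path,bed_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_hotspots <- function(loci, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(loci, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = loci$genus, start = loci$start - 1L,
                      end = loci$end, name = loci$name,
                      score = loci$S_locus, strand = ".")
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(c(tsv_path, bed_path))
}
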