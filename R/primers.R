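# Universal primer design from conserved flanks. A primer candidate is a
# substring of a maximal run of alignment columns in which every sequence
# carries the same unambiguous residue, so by construction it matches
# every input sequence exactly (0 mismatches) at its binding site.
# Candidates are screened on length, GC fraction, melting temperature and
# homopolymer runs; the bounds are calibrated to the published universal
# plastome primer sets this module emulates (lengths 19-27 nt, GC up to
# ~0.74, a single 52 degC annealing temperature in the field protocol).

#' Default primer design constraints
#'
#' @param length_range Allowed primer lengths in nt (default 18-27).
#' @param gc_range Allowed GC fraction (default 0.30-0.75).
#' @param tm_range Allowed melting temperature in degC (default 50-65).
#' @param homopolymer_max Longest tolerated single-base run (default 4).
#' @param product_range Allowed product length in bp (default 300-2500,
#'   matching what a standard 2-minute extension amplifies comfortably).
#' @param tm_diff_max Maximum forward/reverse Tm difference in degC
#'   (default 5).
#' @return A list of class `primer_constraints`.
#' @export
primer_constraints <- function(length_range = c(18L, 27L),
                               gc_range = c(0.30, 0.75),
                               tm_range = c(50, 65),
                               homopolymer_max = 4L,
                               product_range = c(300L, 2500L),
                               tm_diff_max = 5) {
  structure(list(length_range = as.integer(length_range),
                 gc_range = gc_range, tm_range = tm_range,
                 homopolymer_max = as.integer(homopolymer_max),
                 product_range = as.integer(product_range),
                 tm_diff_max = tm_diff_max),
            class = "primer_constraints")
}

#' Basic melting temperature of a primer
#'
#' Uses the standard GC-content formula for primers longer than 13 nt:
#' \eqn{T_m = 64.9 + 41 (n_{GC} - 16.4) / L}. Parameter-free and easy to
#' reason about; swap in a nearest-neighbor model downstream if needed.
#'
#' @param seq Character vector of primer sequences over `{A,C,G,T}` (case
#'   insensitive; ambiguity codes are an error, candidates never contain
#'   them by construction).
#' @return Numeric vector of melting temperatures in degC.
#' @examples
#' melting_temperature("tggggcgtggccaagcggt")  # 59.72
#' @export
melting_temperature <- function(seq) {
  stopifnot(is.character(seq), all(nchar(seq) > 0L))
  up <- toupper(seq)
  if (any(grepl("[^ACGT]", up))) {
    stop("melting_temperature accepts unambiguous A/C/G/T sequences only")
  }
  L <- nchar(up)
  n_gc <- nchar(gsub("[AT]", "", up))
  64.9 + 41 * (n_gc - 16.4) / L
}

gc_fraction <- function(seq) {
  up <- toupper(seq)
  nchar(gsub("[AT]", "", up)) / nchar(up)
}

max_homopolymer <- function(seq) {
  vapply(strsplit(toupper(seq), "", fixed = TRUE), function(ch) {
    max(rle(ch)$lengths)
  }, 0L)
}

#' Maximal conserved runs over a set of aligned sequences
#'
#' A conserved run is a maximal block of consecutive alignment columns in
#' which all sequences carry the same unambiguous residue (no gaps, no
#' ambiguity codes). Runs shorter than `min_length` are dropped.
#'
#' @param aln A [genus_alignment] (or any character matrix of aligned
#'   residues).
#' @param start,end Flank interval in alignment coordinates.
#' @param min_length Minimum run length kept (default 18, the minimum
#'   primer length).
#' @return Data frame with columns `start`, `end`, `length`, `seq` (the
#'   shared sequence of the run).
#' @export
conserved_runs <- function(aln, start, end, min_length = 18L) {
  M <- if (inherits(aln, "genus_alignment")) aln$seq else aln
  L <- ncol(M)
  if (start < 1L) { warning("flank truncated at sequence start"); start <- 1L }
  if (end > L) { warning("flank truncated at sequence end"); end <- L }
  if (start > end) {
    return(data.frame(start = integer(), end = integer(),
                      length = integer(), seq = character()))
  }
  sub <- M[, start:end, drop = FALSE]
  same <- colSums(matrix(sub == rep(sub[1L, ], each = nrow(sub)),
                         nrow = nrow(sub))) == nrow(sub)
  cons <- same & is_base(sub[1L, ])
  r <- rle(cons)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  if (!any(keep)) {
    return(data.frame(start = integer(), end = integer(),
                      length = integer(), seq = character()))
  }
  out <- data.frame(start = start + starts[keep] - 1L,
                    end = start + ends[keep] - 1L)
  out$length <- out$end - out$start + 1L
  out$seq <- vapply(seq_len(nrow(out)), function(i) {
    paste(M[1L, out$start[i]:out$end[i]], collapse = "")
  }, "")
  out
}

#' Enumerate primer candidates within a conserved run
#'
#' All substrings whose length, GC fraction, melting temperature and
#' homopolymer content satisfy the constraints become candidates, in a
#' deterministic order (binding start, then length). A missing 3' G/C
#' clamp is a soft preference: such candidates are flagged
#' (`"no_gc_clamp"`), not dropped.
#'
#' @param run_seq The run's shared sequence (a character string).
#' @param ref_start Ungapped reference coordinate of the run's first base.
#' @param orientation `"forward"` or `"reverse"`. Reverse candidates bind
#'   the same top-strand site; their primer sequence is the reverse
#'   complement of the site.
#' @param constraints A [primer_constraints] list.
#' @return Data frame with columns `sequence` (5'->3'), `orientation`,
#'   `start`, `end` (ungapped reference, 1-based), `length`,
#'   `gc_fraction`, `tm`, `homopolymer_max`, `flags`.
#' @export
enumerate_candidates <- function(run_seq, ref_start = 1L,
                                 orientation = c("forward", "reverse"),
                                 constraints = primer_constraints()) {
  orientation <- match.arg(orientation)
  run_seq <- toupper(run_seq)
  L <- nchar(run_seq)
  empty <- data.frame(sequence = character(), orientation = character(),
                      start = integer(), end = integer(),
                      length = integer(), gc_fraction = numeric(),
                      tm = numeric(), homopolymer_max = integer(),
                      flags = character())
  lens <- constraints$length_range[1L]:constraints$length_range[2L]
  if (L < lens[1L]) return(empty)
  # deterministic enumeration order: binding start, then length
  st <- rep(seq_len(L), each = length(lens))
  len <- rep(lens, times = L)
  keep <- st + len - 1L <= L
  st <- st[keep]; len <- len[keep]
  if (length(st) == 0L) return(empty)
  site <- substring(run_seq, st, st + len - 1L)
  gc <- gc_fraction(site)
  tm <- melting_temperature(site)
  ok <- gc >= constraints$gc_range[1L] & gc <= constraints$gc_range[2L] &
    tm >= constraints$tm_range[1L] & tm <= constraints$tm_range[2L] &
    !grepl(sprintf("([ACGT])\\1{%d,}", constraints$homopolymer_max), site)
  if (!any(ok)) return(empty)
  st <- st[ok]; len <- len[ok]; site <- site[ok]; gc <- gc[ok]; tm <- tm[ok]
  primer <- if (orientation == "forward") site else
    vapply(site, revcomp, "", USE.NAMES = FALSE)
  three_prime <- substr(primer, len, len)
  data.frame(sequence = primer, orientation = orientation,
             start = ref_start + st - 1L, end = ref_start + st + len - 2L,
             length = len, gc_fraction = gc, tm = tm,
             homopolymer_max = max_homopolymer(site),
             flags = ifelse(three_prime %in% c("G", "C"), "",
                            "no_gc_clamp"))
}

#' Pair forward and reverse candidates around a target locus
#'
#' Valid pairs have the forward site strictly upstream of the reverse
#' site, a product that contains the entire target locus, a product length
#' within bounds, and a Tm difference within the cap. Pairs are ranked by
#' Tm difference (ascending), then product length (ascending); the order
#' is deterministic.
#'
#' @param forward,reverse Candidate data frames from
#'   [enumerate_candidates].
#' @param locus_ref Length-2 integer vector: the target locus on ungapped
#'   reference coordinates.
#' @param constraints A [primer_constraints] list.
#' @return Data frame of pairs (forward/reverse sequence and coordinates,
#'   `product_start`, `product_end`, `product_length`, `tm_difference`).
#'   When empty, attribute `"diagnostic"` names the constraint that
#'   failed most often.
#' @export
pair_primers <- function(forward, reverse, locus_ref,
                         constraints = primer_constraints()) {
  empty <- data.frame(fwd_seq = character(), rev_seq = character(),
                      fwd_start = integer(), fwd_end = integer(),
                      rev_start = integer(), rev_end = integer(),
                      product_start = integer(), product_end = integer(),
                      product_length = integer(), tm_difference = numeric(),
                      fwd_tm = numeric(), rev_tm = numeric())
  if (nrow(forward) == 0L || nrow(reverse) == 0L) {
    attr(empty, "diagnostic") <- "no candidates on one flank"
    return(empty)
  }
  # Bound the pairing pool: long fully conserved flanks can yield
  # thousands of interchangeable candidates per side. Candidates nearest
  # the locus are kept (they give the shortest products, which the
  # ranking prefers anyway); the cut is deterministic.
  cap <- 300L
  if (nrow(forward) > cap) {
    forward <- forward[order(-forward$start, forward$end), ][seq_len(cap), ]
  }
  if (nrow(reverse) > cap) {
    reverse <- reverse[order(reverse$end, reverse$start), ][seq_len(cap), ]
  }
  fi <- rep(seq_len(nrow(forward)), times = nrow(reverse))
  ri <- rep(seq_len(nrow(reverse)), each = nrow(forward))
  ok_orient <- forward$end[fi] < reverse$start[ri]
  ok_contain <- forward$start[fi] <= locus_ref[1L] &
    reverse$end[ri] >= locus_ref[2L]
  plen <- reverse$end[ri] - forward$start[fi] + 1L
  ok_plen <- plen >= constraints$product_range[1L] &
    plen <= constraints$product_range[2L]
  dtm <- abs(forward$tm[fi] - reverse$tm[ri])
  ok_tm <- dtm <= constraints$tm_diff_max
  keep <- ok_orient & ok_contain & ok_plen & ok_tm
  if (!any(keep)) {
    fails <- c(orientation = sum(!ok_orient),
               containment = sum(ok_orient & !ok_contain),
               product_length = sum(ok_orient & ok_contain & !ok_plen),
               tm_difference = sum(ok_orient & ok_contain & ok_plen &
                                     !ok_tm))
    attr(empty, "diagnostic") <- paste0("most frequent failure: ",
                                        names(which.max(fails)))
    return(empty)
  }
  fi <- fi[keep]; ri <- ri[keep]
  out <- data.frame(
    fwd_seq = forward$sequence[fi], rev_seq = reverse$sequence[ri],
    fwd_start = forward$start[fi], fwd_end = forward$end[fi],
    rev_start = reverse$start[ri], rev_end = reverse$end[ri],
    product_start = forward$start[fi], product_end = reverse$end[ri],
    product_length = plen[keep], tm_difference = dtm[keep],
    fwd_tm = forward$tm[fi], rev_tm = reverse$tm[ri])
  out[order(out$tm_difference, out$product_length, out$fwd_start,
            out$rev_start), , drop = FALSE]
}

#' Design universal primers bracketing a hotspot locus
#'
#' Looks for conserved runs in the flanks up to `flank_span` bp upstream
#' and downstream of the locus (alignment coordinates), enumerates
#' candidates on each side, and pairs them so the product contains the
#' whole locus. Because candidates come from columns identical across all
#' sequences, every emitted primer matches every input sequence exactly at
#' its binding site.
#'
#' @param aln A [genus_alignment]; may hold sequences from several genera
#'   when cross-genus universality is wanted.
#' @param locus_start,locus_end Target locus in alignment coordinates.
#' @param flank_span Flank width in bp searched on each side (default
#'   400).
#' @param constraints A [primer_constraints] list.
#' @return List of class `primer_design` with elements `pairs` (ranked
#'   pair table), `forward`, `reverse` (candidate tables) and `locus_ref`
#'   (the locus on ungapped reference coordinates).
#' @export
design_primers <- function(aln, locus_start, locus_end, flank_span = 400L,
                           constraints = primer_constraints()) {
  stopifnot(inherits(aln, "genus_alignment"))
  min_len <- constraints$length_range[1L]
  up <- conserved_runs(aln, locus_start - flank_span, locus_start - 1L,
                       min_length = min_len)
  down <- conserved_runs(aln, locus_end + 1L, locus_end + flank_span,
                         min_length = min_len)
  run_candidates <- function(runs, orientation) {
    if (nrow(runs) == 0L) {
      return(enumerate_candidates("", 1L, orientation, constraints)[0L, ])
    }
    do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
      ref <- map_to_ungapped(aln, runs$start[i], runs$end[i])
      enumerate_candidates(runs$seq[i], ref[1L], orientation, constraints)
    }))
  }
  fwd <- run_candidates(up, "forward")
  rev_ <- run_candidates(down, "reverse")
  locus_ref <- map_to_ungapped(aln, locus_start, locus_end)
  if (is.na(locus_ref[1L])) {
    stop("locus maps to no residue of the reference sequence")
  }
  pairs <- pair_primers(fwd, rev_, locus_ref, constraints)
  structure(list(pairs = pairs, forward = fwd, reverse = rev_,
                 locus_ref = locus_ref),
            class = "primer_design")
}

#' @export
print.primer_design <- function(x, ...) {
  cat("primer_design: ", nrow(x$forward), " forward and ", nrow(x$reverse),
      " reverse candidates, ", nrow(x$pairs), " valid pair(s)\n", sep = "")
  if (nrow(x$pairs) == 0L && !is.null(attr(x$pairs, "diagnostic"))) {
    cat("  ", attr(x$pairs, "diagnostic"), "\n", sep = "")
  }
  invisible(x)
}

#' Write a primer table
#'
#' One row per primer of the ranked pairs, in the conventional published
#' schema: locus, primer name, sequence 5'->3', orientation, Tm, GC
#' percentage and product length.
#'
#' @param design A `primer_design` (or a pair table).
#' @param locus_name Locus label used to build primer names
#'   (`<locus>-f` / `<locus>-r`).
#' @param path Output TSV path.
#' @param top How many ranked pairs to write (default 1).
#' @return The written table, invisibly.
#' @export
write_primer_table <- function(design, locus_name, path, top = 1L) {
  pairs <- if (inherits(design, "primer_design")) design$pairs else design
  pairs <- utils::head(pairs, top)
  if (nrow(pairs) == 0L) {
    tab <- data.frame(locus = character(), primer = character(),
                      sequence = character(), orientation = character(),
                      tm = numeric(), gc_percent = numeric(),
                      product_length = integer())
  } else {
    tab <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      p <- pairs[i, ]
      data.frame(
        locus = locus_name,
        primer = paste0(locus_name, c("-f", "-r")),
        sequence = c(tolower(p$fwd_seq), tolower(p$rev_seq)),
        orientation = c("forward", "reverse"),
        tm = round(c(p$fwd_tm, p$rev_tm), 2),
        gc_percent = round(100 * gc_fraction(c(p$fwd_seq, p$rev_seq)), 1),
        product_length = p$product_length)
    }))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}
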