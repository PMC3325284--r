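# Synthetic congener-genome generator. Emulates the features of aligned
# congeneric plastomes the scan has to cope with: a slowly diverging
# background with localized high-rate hotspots, single-taxon indels,
# (AT)n microsatellite tracts with taxon-specific repeat numbers, and
# small inversions - plus a gene/intron/spacer annotation track and a
# truth table, so every downstream stage is testable without external
# genome data.
#
# Mutations are applied in ancestral coordinates, so the emitted alignment
# is the TRUE alignment: no realignment step exists (or is needed)
# between simulation and scanning.

#' Simulation configuration
#'
#' Defaults describe a desk-scale congener pair: a 30 kb genome (one
#' plastome single-copy region, keeping runs fast), two taxa diverging by
#' 0.002 substitutions/site on each branch from their common ancestor
#' (typical congeneric plastome background divergence), and six 800 bp
#' hotspots evolving 10 times faster.
#'
#' @param seed Integer RNG seed; same seed, same output, byte for byte.
#' @param genome_length Ancestral genome length in bp (default 30000).
#' @param n_taxa Number of taxa, >= 2 (default 2). Taxa evolve on
#'   independent branches from the ancestor (a star phylogeny, which is
#'   all window statistics can see anyway).
#' @param background_branch_length Expected substitutions/site per branch
#'   outside hotspots (default 0.002).
#' @param hotspot_count Number of planted hotspots (default 6).
#' @param hotspot_length Hotspot length in bp (default 800).
#' @param hotspot_rate_multiplier Rate multiplier f >= 1 inside hotspots
#'   (default 10).
#' @param indel_rate Indel events per site per branch (default 2e-4).
#' @param indel_length_mean Mean indel length in bp, geometric (default 4).
#' @param microsat_count Number of (AT)n microsatellite tracts (default
#'   3); repeat numbers vary between taxa, producing the staggered-gap
#'   stutter pattern these tracts leave in real alignments.
#' @param inversion_count Number of small inversions (default 1).
#' @param inversion_length Inversion length in bp (default 30).
#' @param gene_count Number of genes tiling the annotation track (default
#'   40); every fifth gene carries an intron.
#' @param layout_seed Seed controlling the genome layout (gene tiling,
#'   hotspot/microsatellite/inversion placement). Defaults to `seed`.
#'   Give several configs the same `layout_seed` but different `seed`s to
#'   simulate different genera sharing one annotation layout, so their
#'   hotspot loci carry comparable names.
#' @param private_hotspot_count Extra hotspots placed from the
#'   evolution seed rather than the layout seed (default 0); with a shared
#'   `layout_seed` these are private to each simulated genus.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 30000L, n_taxa = 2L,
                       background_branch_length = 0.002,
                       hotspot_count = 6L, hotspot_length = 800L,
                       hotspot_rate_multiplier = 10,
                       indel_rate = 2e-4, indel_length_mean = 4,
                       microsat_count = 3L, inversion_count = 1L,
                       inversion_length = 30L, gene_count = 40L,
                       layout_seed = NULL, private_hotspot_count = 0L) {
  cfg <- list(seed = as.integer(seed),
              genome_length = as.integer(genome_length),
              n_taxa = as.integer(n_taxa),
              background_branch_length = background_branch_length,
              hotspot_count = as.integer(hotspot_count),
              hotspot_length = as.integer(hotspot_length),
              hotspot_rate_multiplier = hotspot_rate_multiplier,
              indel_rate = indel_rate,
              indel_length_mean = indel_length_mean,
              microsat_count = as.integer(microsat_count),
              inversion_count = as.integer(inversion_count),
              inversion_length = as.integer(inversion_length),
              gene_count = as.integer(gene_count),
              layout_seed = as.integer(layout_seed %||% seed),
              private_hotspot_count = as.integer(private_hotspot_count))
  with(cfg, {
    stopifnot(n_taxa >= 2L, genome_length >= 1L,
              background_branch_length >= 0, indel_rate >= 0,
              indel_length_mean >= 1, hotspot_rate_multiplier >= 1,
              hotspot_count >= 0L, private_hotspot_count >= 0L)
  })
  total_hot <- (cfg$hotspot_count + cfg$private_hotspot_count) *
    cfg$hotspot_length
  if (total_hot > cfg$genome_length) {
    stop("hotspots (", total_hot, " bp) exceed the genome (",
         cfg$genome_length, " bp)")
  }
  structure(cfg, class = "sim_config")
}

#' Expected pairwise divergence under Jukes-Cantor
#'
#' Closed-form expected proportion of differing sites between two
#' sequences separated by a total path of `t_total` substitutions/site:
#' \eqn{p = \frac{3}{4}\left(1 - e^{-4 t_{total}/3}\right)}. Used as the
#' independent oracle for parameter-recovery checks on simulated data.
#'
#' @param t_total Total path length in substitutions/site (for two taxa on
#'   a star, twice the branch length); must be >= 0.
#' @return Expected proportion of differing sites, in `[0, 0.75)`.
#' @export
expected_pairwise_divergence <- function(t_total) {
  if (any(t_total < 0)) stop("t_total must be non-negative")
  0.75 * (1 - exp(-4 * t_total / 3))
}

# Draw `n` non-overlapping intervals of length `len` inside [1, L],
# avoiding the intervals in `avoid` (data frame start/end). Rejection
# sampling with a cap; infeasible placement is a configuration error.
place_intervals <- function(n, len, L, avoid = NULL) {
  out <- data.frame(start = integer(), end = integer())
  taken <- if (is.null(avoid)) out else avoid[, c("start", "end")]
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(10000L)) {
      s <- sample.int(L - len + 1L, 1L)
      e <- s + len - 1L
      if (nrow(taken) == 0L ||
          all(overlap_length(s, e, taken$start, taken$end) == 0L)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place ", n, " intervals of ", len,
                  " bp in a ", L, " bp genome")
    out <- rbind(out, data.frame(start = s, end = e))
    taken <- rbind(taken, data.frame(start = s, end = e))
  }
  out
}

# Shared hotspots alternate between genic and intergenic contexts: odd
# hotspots are centered on a randomly chosen gene, even ones on a randomly
# chosen gap between genes. Non-overlap enforced by redrawing the anchor.
place_hotspots <- function(n, len, L, features, avoid = NULL) {
  genes <- features[features$kind == "gene", , drop = FALSE]
  genes <- genes[order(genes$start), , drop = FALSE]
  gene_centers <- (genes$start + genes$end) %/% 2L
  gap_centers <- if (nrow(genes) > 1L) {
    (genes$end[-nrow(genes)] + genes$start[-1L]) %/% 2L
  } else integer()
  out <- data.frame(start = integer(), end = integer())
  for (i in seq_len(n)) {
    centers <- if (i %% 2L == 1L || length(gap_centers) == 0L) {
      gene_centers
    } else gap_centers
    ok <- FALSE
    for (try in seq_len(10000L)) {
      ctr <- centers[sample.int(length(centers), 1L)]
      s <- ctr - len %/% 2L
      e <- s + len - 1L
      if (s < 1L || e > L) next
      # pad the collision check: hotspots closer than ~2 scan windows are
      # not resolvable as distinct loci, so keep them well separated
      taken <- rbind(out, avoid)
      if (nrow(taken) == 0L ||
          all(overlap_length(s - 750L, e + 750L, taken$start,
                             taken$end) == 0L)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place ", n, " hotspots of ", len,
                  " bp in a ", L, " bp genome")
    out <- rbind(out, data.frame(start = s, end = e))
  }
  out
}

# Gene tiling: gene_count genes in equal slots, each occupying the middle
# ~60% of its slot; every fifth gene gets an intron (middle third, with
# the flanking thirds as exons).
tile_genes <- function(L, gene_count) {
  slot <- L %/% gene_count
  rows <- list()
  for (i in seq_len(gene_count)) {
    g_start <- (i - 1L) * slot + max(1L, slot %/% 5L)
    g_end <- min(L, (i - 1L) * slot + (4L * slot) %/% 5L)
    if (g_end <= g_start) next
    nm <- sprintf("g%02d", i)
    rows[[length(rows) + 1L]] <-
      data.frame(name = nm, kind = "gene", start = g_start, end = g_end)
    if (i %% 5L == 0L) {
      glen <- g_end - g_start + 1L
      i_start <- g_start + glen %/% 3L
      i_end <- g_start + (2L * glen) %/% 3L
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm, kind = c("exon", "intron", "exon"),
        start = c(g_start, i_start, i_end + 1L),
        end = c(i_start - 1L, i_end, g_end))
    }
  }
  tab <- do.call(rbind, rows)
  feature_table(tab$name, tab$kind, tab$start, tab$end)
}

#' Simulate one genus of congeneric genomes
#'
#' Draws a uniform-random ancestral sequence, evolves each taxon
#' independently under Jukes-Cantor with branch length
#' `background_branch_length` outside hotspots and `f` times that inside,
#' then overlays single-taxon deletion events (geometric lengths,
#' re-drawn on collision so the true alignment stays well defined),
#' taxon-variable (AT)n microsatellite tracts, and small inversions
#' applied to one random taxon.
#'
#' @param cfg A [sim_config].
#' @param genus_label Label for the emitted alignment (default
#'   `"SimGenus"`).
#' @return List with elements `alignment` (a [genus_alignment]),
#'   `features` (a [feature_table]) and `truth` (list of class
#'   `sim_truth`: `hotspots` with realized substitution counts,
#'   `indels`, `inversions`, `microsats`, `background_subs`).
#' @export
simulate_genus <- function(cfg, genus_label = "SimGenus") {
  stopifnot(inherits(cfg, "sim_config"))
  L <- cfg$genome_length
  n <- cfg$n_taxa

  # --- layout (shareable across genera via layout_seed) ---
  set.seed(cfg$layout_seed)
  features <- tile_genes(L, cfg$gene_count)
  hot <- place_hotspots(cfg$hotspot_count, cfg$hotspot_length, L, features)
  ms_unit <- 16L  # room for up to (AT)8
  ms <- place_intervals(cfg$microsat_count, ms_unit, L, avoid = hot)
  inv <- place_intervals(cfg$inversion_count, cfg$inversion_length, L,
                         avoid = rbind(hot, ms))

  # --- evolution (per-genus seed) ---
  set.seed(cfg$seed)
  if (cfg$private_hotspot_count > 0L) {
    priv <- place_hotspots(cfg$private_hotspot_count, cfg$hotspot_length,
                           L, features,
                           avoid = rbind(hot, ms[, c("start", "end")],
                                         inv[, c("start", "end")]))
    hot$type <- rep("shared", nrow(hot))
    priv$type <- "private"
    hot <- rbind(hot, priv)
  } else if (nrow(hot) > 0L) {
    hot$type <- "shared"
  } else {
    hot$type <- character()
  }

  anc <- sample(DNA_BASES, L, replace = TRUE)
  p_site <- rep(expected_pairwise_divergence(cfg$background_branch_length), L)
  p_hot <- expected_pairwise_divergence(
    cfg$hotspot_rate_multiplier * cfg$background_branch_length)
  for (h in seq_len(nrow(hot))) p_site[hot$start[h]:hot$end[h]] <- p_hot

  seq_mat <- matrix(rep(anc, each = n), nrow = n)
  mut_mat <- matrix(FALSE, nrow = n, ncol = L)
  for (i in seq_len(n)) {
    mut <- stats::runif(L) < p_site
    if (any(mut)) {
      shift <- sample.int(3L, sum(mut), replace = TRUE)
      idx <- (match(anc[mut], DNA_BASES) - 1L + shift) %% 4L + 1L
      seq_mat[i, mut] <- DNA_BASES[idx]
    }
    mut_mat[i, ] <- mut
  }

  # inversions: reverse-complement one random taxon over each interval
  inv_rows <- list()
  for (h in seq_len(nrow(inv))) {
    taxon <- sample.int(n, 1L)
    s <- inv$start[h]; e <- inv$end[h]
    seq_mat[taxon, s:e] <- revcomp_chars(seq_mat[taxon, s:e])
    inv_rows[[h]] <- data.frame(taxon = taxon, start = s, end = e)
  }
  inversions <- if (length(inv_rows)) do.call(rbind, inv_rows) else
    data.frame(taxon = integer(), start = integer(), end = integer())

  # single-taxon deletion events; non-overlapping within a taxon and kept
  # out of microsatellite/inversion tracts
  indel_rows <- list()
  # indels never overlap each other (across taxa) nor the microsatellite
  # and inversion tracts: keeps the true alignment well defined and rules
  # out gap-only columns
  taken <- rbind(ms[, c("start", "end")], inv[, c("start", "end")])
  for (i in seq_len(n)) {
    n_ev <- stats::rpois(1L, cfg$indel_rate * L)
    for (ev in seq_len(n_ev)) {
      len <- stats::rgeom(1L, 1 / cfg$indel_length_mean) + 1L
      placed <- FALSE
      for (try in seq_len(1000L)) {
        s <- sample.int(L - len + 1L, 1L)
        e <- s + len - 1L
        if (all(overlap_length(s, e, taken$start, taken$end) == 0L)) {
          placed <- TRUE; break
        }
      }
      if (!placed) next
      seq_mat[i, s:e] <- "-"
      taken <- rbind(taken, data.frame(start = s, end = e))
      indel_rows[[length(indel_rows) + 1L]] <-
        data.frame(taxon = i, start = s, end = e, length = len)
    }
  }
  indels <- if (length(indel_rows)) do.call(rbind, indel_rows) else
    data.frame(taxon = integer(), start = integer(), end = integer(),
               length = integer())

  # (AT)n tracts with taxon-specific repeat numbers; the longest allele
  # fills its region, shorter alleles are gap-padded, so the tract length
  # in ancestral coordinates is fixed by the realized maximum
  ms_rows <- list()
  for (h in seq_len(nrow(ms))) {
    reps <- 4L + sample.int(4L, n, replace = TRUE)   # 5..8 (AT) units
    width <- 2L * max(reps)
    s <- ms$start[h]; e <- s + width - 1L
    for (i in seq_len(n)) {
      tract <- c(rep(c("A", "T"), reps[i]),
                 rep("-", width - 2L * reps[i]))
      seq_mat[i, s:e] <- tract
    }
    ms_rows[[h]] <- data.frame(start = s, end = e,
                               repeats = paste(reps, collapse = "/"))
  }
  microsats <- if (length(ms_rows)) do.call(rbind, ms_rows) else
    data.frame(start = integer(), end = integer(), repeats = character())

  # realized substitution counts per hotspot (and background total)
  if (nrow(hot) > 0L) {
    hot$n_subs <- vapply(seq_len(nrow(hot)), function(h) {
      sum(mut_mat[, hot$start[h]:hot$end[h]])
    }, 0L)
  } else {
    hot$n_subs <- integer()
  }
  in_hot <- rep(FALSE, L)
  for (h in seq_len(nrow(hot))) in_hot[hot$start[h]:hot$end[h]] <- TRUE
  background_subs <- sum(mut_mat[, !in_hot])

  seqs <- apply(seq_mat, 1L, paste, collapse = "")
  names(seqs) <- paste0(genus_label, "_sp", seq_len(n))
  aln <- genus_alignment(seqs, genus_label)
  if (aln$dropped_columns > 0L) {
    stop("internal error: simulated alignment contained gap-only columns")
  }
  # The planted inversions are left in the emitted alignment (they are
  # divergence events, not yet "separated"); the truth carries the
  # matching declaration in ungapped sample coordinates, ready for
  # apply_inversions() - the analyst's separation step.
  decl_rows <- lapply(seq_len(nrow(inversions)), function(h) {
    i <- inversions$taxon[h]
    cum <- cumsum(seq_mat[i, ] != "-")
    data.frame(sample_id = aln$taxa[i],
               start = cum[inversions$start[h]],
               end = cum[inversions$end[h]],
               note = "planted")
  })
  declarations <- if (length(decl_rows)) do.call(rbind, decl_rows) else
    data.frame(sample_id = character(), start = integer(),
               end = integer(), note = character())

  truth <- structure(list(hotspots = hot, indels = indels,
                          inversions = inversions,
                          inversion_declarations = declarations,
                          microsats = microsats,
                          background_subs = background_subs),
                     class = "sim_truth")
  list(alignment = aln, features = features, truth = truth)
}

#' Write simulator outputs to a directory
#'
#' Emits the alignment (FASTA), annotation (GFF3), truth table (TSV) and
#' the resolved configuration (YAML, including the seed) so a run can be
#' reproduced from its own output.
#'
#' @param sim Result of [simulate_genus].
#' @param cfg The [sim_config] used.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genus_alignment(sim$alignment, file.path(dir, "alignment.fa"))
  write_features(sim$features, file.path(dir, "features.gff3"),
                 seqid = sim$alignment$taxa[sim$alignment$reference])
  tr <- sim$truth
  utils::write.table(tr$hotspots, file.path(dir, "truth_hotspots.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tr$indels, file.path(dir, "truth_indels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # declaration file consumable by read_inversions()
  utils::write.table(tr$inversion_declarations,
                     file.path(dir, "inversions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
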