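# End-to-end orchestration: (simulate |) scan -> hotspots -> cross-genus
# intersection -> primers, as one configured, logged, reproducible run.
# Every default equals the field-standard value where one exists (600 bp
# windows, 50 bp step, mean + 2 stdev threshold, >= 3 genera retention);
# the rest are documented gap-filling choices.

#' Build a run configuration
#'
#' @param window,step Scan window length and step in bp.
#' @param k Hotspot threshold multiplier.
#' @param min_genera Cross-genus retention threshold m.
#' @param policy Site-deletion policy.
#' @param max_gap Hotspot merge gap in bp (defaults to `step`).
#' @param flank_span Primer flank width in bp.
#' @param primer Primer constraints, a [primer_constraints] list.
#' @param simulate Either `NULL` or a list: `n_genera` plus any
#'   [sim_config] fields; genus g gets seed `seed + g` and all genera
#'   share `layout_seed = seed`, so their loci carry comparable names.
#' @param genera Either `NULL` or a list of per-genus input manifests,
#'   each a list with `label`, `fasta`, `gff` and optionally `inversions`
#'   (TSV path) and `reference_id`.
#' @param seed Integer master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(window = 600L, step = 50L, k = 2, min_genera = 3L,
                       policy = "complete", max_gap = NULL,
                       flank_span = 400L, primer = primer_constraints(),
                       simulate = list(n_genera = 3L), genera = NULL,
                       seed = 1L) {
  stopifnot(window >= 1L, step >= 1L, step <= window, k >= 0,
            min_genera >= 1L)
  structure(list(window = as.integer(window), step = as.integer(step),
                 k = k, min_genera = as.integer(min_genera),
                 policy = policy, max_gap = as.integer(max_gap %||% step),
                 flank_span = as.integer(flank_span), primer = primer,
                 simulate = simulate, genera = genera,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [run_config].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$primer)) raw$primer <- do.call(primer_constraints,
                                                  raw$primer)
  do.call(run_config, raw)
}

load_or_simulate_genera <- function(config) {
  if (!is.null(config$genera)) {
    out <- lapply(config$genera, function(g) {
      aln <- read_genus_alignment(g$fasta, g$label,
                                  reference_id = g$reference_id)
      if (!is.null(g$inversions)) {
        aln <- apply_inversions(aln, read_inversions(g$inversions))
      }
      list(alignment = aln, features = read_features(g$gff), truth = NULL)
    })
    names(out) <- vapply(config$genera, `[[`, "", "label")
    return(out)
  }
  sim <- config$simulate %||% list()
  n_genera <- sim$n_genera %||% 3L
  sim$n_genera <- NULL
  out <- lapply(seq_len(n_genera), function(g) {
    cfg_args <- sim
    cfg_args$seed <- config$seed + g
    cfg_args$layout_seed <- cfg_args$layout_seed %||% config$seed
    cfg <- do.call(sim_config, cfg_args)
    sim <- simulate_genus(cfg, genus_label = sprintf("Genus%s", LETTERS[g]))
    # separate the declared inversions before any statistics
    sim$alignment <- apply_inversions(sim$alignment,
                                      sim$truth$inversion_declarations)
    sim
  })
  names(out) <- sprintf("Genus%s", LETTERS[seq_len(n_genera)])
  out
}

#' Run the full marker-discovery pipeline
#'
#' For each genus (simulated from the config, or loaded from the input
#' manifest): sliding-window scan, hotspot selection and naming, and a
#' per-genus report. The per-genus loci are then intersected by name,
#' filtered to those shared by at least `min_genera` genera, ranked, and
#' primer pairs are designed for each retained locus in each genus where
#' it occurs. All outputs are plain text (FASTA/GFF3/TSV/BED/JSON) under
#' `out_dir`; rerunning with an identical config reproduces identical
#' bytes.
#'
#' @param config A [run_config].
#' @param out_dir Output directory (created; must be empty or absent).
#' @return Invisibly, a list with `genera` (per-genus alignment, profile,
#'   loci), `shared` (ranked retained table), `breakdown`, `primers` and
#'   `out_dir`.
#' @export
run_discovery <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genera <- load_or_simulate_genera(config)
  counts <- list()

  per_genus <- lapply(names(genera), function(gname) {
    g <- genera[[gname]]
    gdir <- file.path(out_dir, paste0("genus_", gname))
    dir.create(gdir, showWarnings = FALSE)
    write_genus_alignment(g$alignment, file.path(gdir, "alignment.fa"))
    write_features(g$features, file.path(gdir, "features.gff3"),
                   seqid = g$alignment$taxa[g$alignment$reference])
    profile <- scan_windows(g$alignment, window = config$window,
                            step = config$step, policy = config$policy)
    write_scan_profile(profile, file.path(gdir, "profile.tsv"))
    loci <- find_hotspots(profile, g$alignment, g$features, k = config$k,
                          max_gap = config$max_gap)
    write_hotspots(loci, tsv_path = file.path(gdir, "loci.tsv"),
                   bed_path = file.path(gdir, "loci.bed"))
    list(name = gname, alignment = g$alignment, features = g$features,
         profile = profile, loci = loci, truth = g$truth, dir = gdir)
  })
  names(per_genus) <- names(genera)
  counts$windows <- vapply(per_genus, function(g) nrow(g$profile$windows),
                           0L)
  counts$loci <- vapply(per_genus, function(g) nrow(g$loci), 0L)

  shared <- intersect_loci(lapply(per_genus, `[[`, "loci"))
  retained <- rank_loci(retain_shared(shared, m = config$min_genera))
  write_shared_loci(retained, file.path(out_dir, "shared_loci.tsv"),
                    file.path(out_dir, "breakdown.json"))
  counts$shared_loci <- nrow(shared)
  counts$retained_loci <- nrow(retained)

  primer_rows <- list()
  for (g in per_genus) {
    keep <- g$loci[g$loci$name %in% retained$name, , drop = FALSE]
    for (i in seq_len(nrow(keep))) {
      des <- design_primers(g$alignment, keep$start[i], keep$end[i],
                            flank_span = config$flank_span,
                            constraints = config$primer)
      if (nrow(des$pairs) > 0L) {
        top <- des$pairs[1L, ]
        primer_rows[[length(primer_rows) + 1L]] <- data.frame(
          genus = g$name, locus = keep$name[i],
          fwd_seq = tolower(top$fwd_seq), rev_seq = tolower(top$rev_seq),
          fwd_tm = round(top$fwd_tm, 2), rev_tm = round(top$rev_tm, 2),
          product_length = top$product_length)
      }
    }
  }
  primers <- if (length(primer_rows)) do.call(rbind, primer_rows) else
    data.frame(genus = character(), locus = character(),
               fwd_seq = character(), rev_seq = character(),
               fwd_tm = numeric(), rev_tm = numeric(),
               product_length = integer())
  utils::write.table(primers, file.path(out_dir, "primers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts$primer_pairs <- nrow(primers)

  manifest <- list(
    package = "cphotspot",
    version = as.character(utils::packageVersion("cphotspot")),
    seed = config$seed,
    config = serialize_config(config),
    breakdown = as.list(attr(retained, "breakdown")),
    counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(genera = per_genus, shared = retained,
                 breakdown = attr(retained, "breakdown"),
                 primers = primers, out_dir = out_dir))
}

serialize_config <- function(config) {
  out <- unclass(config)
  out$primer <- unclass(out$primer)
  out
}
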