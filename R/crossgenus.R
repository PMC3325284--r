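# Cross-genus comparison: hotspot loci are matched between genera by their
# annotation-derived NAME (plastome coordinates are not comparable across
# genera; names, with anticodon suffixes where needed, are). Loci found in
# fewer than `min_genera` genera are dropped, and the survivors are ranked
# by breadth first, then diversity.

#' Intersect per-genus hotspot loci into a shared-locus table
#'
#' @param loci_list List of `hotspot_loci` data frames (one per genus, see
#'   [find_hotspots]); each must carry a `genus` column. Duplicate locus
#'   names within one genus are disambiguated with "-a"/"-b" suffixes
#'   (with a warning) before matching.
#' @return A data frame of class `shared_locus_table`: one row per locus
#'   name, one `pi.<genus>` column per genus (`NA` when absent), plus
#'   `genus_count` and `mean_pi` (mean over the genera where present).
#' @export
intersect_loci <- function(loci_list) {
  if (length(loci_list) < 2L) stop("need loci from at least 2 genera")
  genera <- vapply(loci_list, function(x) {
    if (nrow(x) > 0L) x$genus[1L] else NA_character_
  }, "")
  # Empty tables still need a genus label for their column.
  if (anyNA(genera)) {
    nm <- names(loci_list)
    genera[is.na(genera)] <- if (!is.null(nm)) nm[is.na(genera)] else
      paste0("genus", which(is.na(genera)))
  }
  if (anyDuplicated(genera)) stop("duplicate genus labels")
  loci_list <- lapply(loci_list, function(x) {
    if (nrow(x) > 0L && anyDuplicated(x$name)) {
      warning("duplicate locus names within genus '", x$genus[1L],
              "'; adding -a/-b suffixes")
      x$name <- suffix_duplicates(x$name, x$start)
    }
    x
  })
  all_names <- sort(unique(unlist(lapply(loci_list, function(x) x$name))))
  tab <- data.frame(name = all_names, stringsAsFactors = FALSE)
  for (g in seq_along(loci_list)) {
    pi_col <- rep(NA_real_, length(all_names))
    x <- loci_list[[g]]
    if (nrow(x) > 0L) pi_col[match(x$name, all_names)] <- x$pi
    tab[[paste0("pi.", genera[g])]] <- pi_col
  }
  pim <- as.matrix(tab[, -1L, drop = FALSE])
  tab$genus_count <- as.integer(rowSums(!is.na(pim)))
  tab$mean_pi <- rowMeans(pim, na.rm = TRUE)
  tab$mean_pi[tab$genus_count == 0L] <- NA_real_
  attr(tab, "genera") <- unname(genera)
  class(tab) <- c("shared_locus_table", "data.frame")
  tab
}

#' Retain loci shared by at least m genera
#'
#' Besides the filtered table, the cumulative breakdown - how many loci
#' are present in at least 1, 2, ..., max genera - is attached as
#' attribute `"breakdown"`, making the progressive narrowing of the
#' candidate list visible in any run.
#'
#' @param table A `shared_locus_table`.
#' @param m Minimum number of genera (default 3).
#' @return The retained rows (class preserved) with attributes
#'   `"breakdown"` (named integer vector over thresholds `1..max`) and
#'   `"min_genera"`.
#' @export
retain_shared <- function(table, m = 3L) {
  stopifnot(inherits(table, "shared_locus_table"))
  if (!is_count(m) || m < 1L) stop("min_genera m must be a positive integer")
  n_gen <- length(attr(table, "genera"))
  breakdown <- vapply(seq_len(max(1L, n_gen)), function(th) {
    sum(table$genus_count >= th)
  }, 0L)
  names(breakdown) <- paste0(">=", seq_along(breakdown))
  out <- table[table$genus_count >= m, , drop = FALSE]
  attr(out, "genera") <- attr(table, "genera")
  attr(out, "breakdown") <- breakdown
  attr(out, "min_genera") <- as.integer(m)
  class(out) <- class(table)
  out
}

#' Rank shared loci by breadth, then diversity
#'
#' Primary key: `genus_count` descending (a locus variable in many genera
#' is a broader marker candidate than a locally extreme one); secondary
#' key: `mean_pi` descending; ties broken lexicographically by name, so
#' the ordering is stable and deterministic.
#'
#' @param table A `shared_locus_table` (typically after [retain_shared]).
#' @return The table reordered.
#' @export
rank_loci <- function(table) {
  stopifnot(inherits(table, "shared_locus_table"))
  mp <- table$mean_pi
  mp[is.na(mp)] <- -Inf
  out <- table[order(-table$genus_count, -mp, table$name), , drop = FALSE]
  for (a in c("genera", "breakdown", "min_genera")) {
    attr(out, a) <- attr(table, a)
  }
  class(out) <- class(table)
  out
}

#' Write a shared-locus table
#'
#' @param table A `shared_locus_table`.
#' @param tsv_path Path for the loci x genera TSV matrix.
#' @param json_path Optional path for a JSON summary holding the genera
#'   and the cumulative breakdown.
#' @return Invisibly, the written paths.
#' @export
write_shared_loci <- function(table, tsv_path, json_path = NULL) {
  utils::write.table(as.data.frame(table), tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(genera = attr(table, "genera"),
           min_genera = attr(table, "min_genera"),
           breakdown = as.list(attr(table, "breakdown")),
           n_retained = nrow(table)),
      json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(c(tsv_path, json_path))
}
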