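# Genus alignments: the scan substrate. One object holds the aligned
# congeneric sequences of a single genus plus the index of the reference
# sequence that carries the annotation coordinate system.

#' Construct a genus alignment
#'
#' Builds the container used by every downstream stage from a set of equal
#' length aligned sequences. Columns consisting solely of gap characters
#' carry no information and distort window coordinates, so they are removed
#' here (the number removed is reported with a message and stored in the
#' object).
#'
#' @param sequences Named character vector of aligned sequences (uppercase
#'   or lowercase DNA with `-` for gaps; IUPAC ambiguity codes are retained
#'   and treated as missing data by the statistics).
#' @param genus_label Free-text genus label.
#' @param reference_id Name of the sequence carrying the annotation
#'   coordinate system. Defaults to the first sequence.
#' @return An object of class `genus_alignment`: a list with elements
#'   `genus`, `taxa`, `seq` (character matrix, taxa in rows, one column per
#'   alignment position), `reference` (row index), `inversions` (data frame
#'   of re-oriented segments, alignment coordinates) and `dropped_columns`.
#' @examples
#' aln <- genus_alignment(c(a = "ACGT-A", b = "ACGTTA"), "Toy")
#' @export
genus_alignment <- function(sequences, genus_label,
                            reference_id = names(sequences)[1L]) {
  if (length(sequences) < 2L) {
    stop("a genus alignment needs at least 2 sequences, got ",
         length(sequences))
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("sequences must carry unique names")
  }
  lens <- nchar(sequences)
  if (any(lens != lens[1L])) {
    bad <- names(sequences)[which(lens != lens[1L])[1L]]
    stop("aligned sequences must have identical length; record '", bad,
         "' has length ", nchar(sequences[[bad]]), " but '",
         names(sequences)[1L], "' has length ", lens[1L])
  }
  if (lens[1L] < 1L) stop("alignment length must be >= 1")
  ref <- match(reference_id, names(sequences))
  if (is.na(ref)) {
    stop("reference_id '", reference_id, "' does not match any record")
  }
  mat <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
  rownames(mat) <- names(sequences)
  gap_only <- colSums(mat == "-") == nrow(mat)
  dropped <- sum(gap_only)
  if (dropped > 0L) {
    mat <- mat[, !gap_only, drop = FALSE]
    message("dropped ", dropped, " gap-only column",
            if (dropped > 1L) "s", " from alignment '", genus_label, "'")
  }
  if (ncol(mat) < 1L) stop("alignment has no non-gap columns")
  structure(
    list(genus = genus_label, taxa = names(sequences), seq = mat,
         reference = ref,
         inversions = data.frame(sample_id = character(), start = integer(),
                                 end = integer()),
         dropped_columns = dropped),
    class = "genus_alignment")
}

#' @export
print.genus_alignment <- function(x, ...) {
  cat("genus_alignment '", x$genus, "': ", length(x$taxa), " sequences x ",
      ncol(x$seq), " columns (reference: ", x$taxa[x$reference], ")\n",
      sep = "")
  if (nrow(x$inversions) > 0L) {
    cat("  ", nrow(x$inversions), "inversion segment(s) re-oriented\n")
  }
  invisible(x)
}

#' Number of alignment columns
#' @param aln A `genus_alignment`.
#' @return Integer alignment length.
#' @export
alignment_length <- function(aln) ncol(aln$seq)

#' Read an aligned FASTA file as a genus alignment
#'
#' @param path Path to an aligned FASTA file (all records the same length).
#' @param genus_label Genus label to attach.
#' @param reference_id Record id carrying the annotations; defaults to the
#'   first record. Ids are the first whitespace-delimited token of each
#'   FASTA header.
#' @return A [genus_alignment]. Gap-only columns are dropped at load.
#' @export
read_genus_alignment <- function(path, genus_label, reference_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) < 2L) {
    stop("alignment '", path, "' has fewer than 2 records")
  }
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  genus_alignment(seqs, genus_label,
                  reference_id = reference_id %||% names(seqs)[1L])
}

#' Write a genus alignment as aligned FASTA
#' @param aln A `genus_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genus_alignment <- function(aln, path) {
  seqs <- aln_strings(aln)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

# Collapse the character matrix back to named strings.
aln_strings <- function(aln) {
  out <- apply(aln$seq, 1L, paste, collapse = "")
  names(out) <- aln$taxa
  out
}

# Ungapped sequence of row i as a single string.
ungapped_string <- function(aln, i) {
  chars <- aln$seq[i, ]
  paste(chars[chars != "-"], collapse = "")
}

# Map an alignment-coordinate interval [start, end] to ungapped coordinates
# of sequence row i. Returns c(NA, NA) when the interval covers only gap
# positions of that row.
map_to_ungapped <- function(aln, start, end, i = aln$reference) {
  chars <- aln$seq[i, ]
  cum <- cumsum(chars != "-")
  sel <- start:end
  hit <- sel[chars[sel] != "-"]
  if (length(hit) == 0L) return(c(NA_integer_, NA_integer_))
  c(cum[hit[1L]], cum[hit[length(hit)]])
}

#' Map an alignment interval to ungapped reference coordinates
#'
#' Projects a 1-based inclusive interval on alignment columns onto the
#' ungapped coordinate system of the reference sequence (the one carrying
#' the annotations). Returns `c(NA, NA)` when the interval covers only
#' gap positions of the reference row.
#'
#' @param aln A [genus_alignment].
#' @param start,end Alignment coordinates.
#' @return Integer vector `c(ref_start, ref_end)`.
#' @export
alignment_to_reference <- function(aln, start, end) {
  map_to_ungapped(aln, start, end)
}

# Alignment columns holding ungapped positions pos (vector) of row i.
map_from_ungapped <- function(aln, pos, i = aln$reference) {
  chars <- aln$seq[i, ]
  which(chars != "-")[pos]
}

#' Re-orient declared inversion segments
#'
#' Small inversions in rapidly evolving regions exaggerate sequence
#' differences if scanned as-is, so declared segments are replaced by their
#' reverse complement before any statistics are computed. Gap columns
#' inside a segment keep their positions; only residue characters are
#' reverse-complemented in place among the residue positions, so applying
#' the same declaration twice restores the original residues.
#'
#' @param aln A [genus_alignment].
#' @param inversions Data frame with columns `sample_id`, `start`, `end`;
#'   coordinates are 1-based inclusive on that sample's ungapped sequence
#'   (see [read_inversions]).
#' @return A new `genus_alignment` whose `inversions` element records the
#'   applied segments in alignment coordinates; the count of applied
#'   inversions is `nrow(result$inversions)` and is also attached as
#'   attribute `"applied"`.
#' @export
apply_inversions <- function(aln, inversions) {
  stopifnot(inherits(aln, "genus_alignment"))
  if (is.null(inversions) || nrow(inversions) == 0L) {
    attr(aln, "applied") <- 0L
    return(aln)
  }
  stopifnot(all(c("sample_id", "start", "end") %in% names(inversions)))
  rec <- aln$inversions
  for (r in seq_len(nrow(inversions))) {
    sid <- inversions$sample_id[r]
    i <- match(sid, aln$taxa)
    if (is.na(i)) stop("inversion sample '", sid, "' not in alignment")
    s <- inversions$start[r]; e <- inversions$end[r]
    if (s > e) stop("inversion interval has start > end")
    chars <- aln$seq[i, ]
    res_cols <- which(chars != "-")
    if (s < 1L || e > length(res_cols)) {
      stop("inversion [", s, ",", e, "] out of range for sample '", sid,
           "' (ungapped length ", length(res_cols), ")")
    }
    cols <- res_cols[s:e]
    aln$seq[i, cols] <- revcomp_chars(chars[cols])
    rec <- rbind(rec, data.frame(sample_id = sid, start = cols[1L],
                                 end = cols[length(cols)]))
  }
  aln$inversions <- rec
  attr(aln, "applied") <- nrow(inversions)
  aln
}

#' Read inversion declarations
#'
#' Inversions are user-declared (they were separated by inspection in the
#' workflows this package supports), as a 4-column tab-separated file:
#' `sample_id`, `start`, `end`, `note`. Coordinates are 1-based inclusive
#' on the sample's ungapped sequence.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `sample_id`, `start`, `end`, `note`.
#' @export
read_inversions <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("sample_id", "start", "end", "note"),
                           colClasses = c("character", "integer", "integer",
                                          "character"),
                           quote = "", comment.char = "#", fill = TRUE)
  bad <- tab$start > tab$end
  if (any(bad)) stop("inversion rows with start > end: ", sum(bad))
  # Non-overlap within one sample.
  for (sid in unique(tab$sample_id)) {
    sub <- tab[tab$sample_id == sid, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] <= sub$end[-nrow(sub)])) {
      stop("overlapping inversion intervals for sample '", sid, "'")
    }
  }
  tab
}
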