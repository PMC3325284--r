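# Reference annotations: genes, exons and introns on the ungapped reference
# sequence. Hotspot loci are classified and named from these features
# (coding region, "<gene> intron", or "<left>-<right>" intergenic spacer).

#' Construct a feature table
#'
#' @param name Character vector of feature names (gene names; exon/intron
#'   rows carry the name of their host gene).
#' @param kind One of `"gene"`, `"exon"`, `"intron"` per row.
#' @param start,end 1-based inclusive coordinates on the ungapped reference
#'   sequence.
#' @param strand `"+"` or `"-"` per row.
#' @param anticodon Optional 3-letter RNA anticodon (e.g. `"UGA"`) used to
#'   disambiguate paralogous tRNA genes such as trnS^UGA^ vs trnS^GCU^;
#'   `NA` when absent.
#' @return A data frame of class `feature_table`.
#' @export
feature_table <- function(name, kind, start, end, strand = "+",
                          anticodon = NA_character_) {
  ft <- data.frame(name = as.character(name), kind = as.character(kind),
                   start = as.integer(start), end = as.integer(end),
                   strand = rep_len(as.character(strand), length(name)),
                   anticodon = rep_len(as.character(anticodon), length(name)),
                   stringsAsFactors = FALSE)
  validate_feature_table(ft)
  class(ft) <- c("feature_table", "data.frame")
  ft
}

validate_feature_table <- function(ft) {
  if (!all(ft$kind %in% c("gene", "exon", "intron"))) {
    stop("feature kind must be gene, exon or intron")
  }
  bad <- ft$end < ft$start
  if (any(bad)) {
    stop("feature '", ft$name[which(bad)[1L]], "' has end < start")
  }
  ac <- ft$anticodon[!is.na(ft$anticodon)]
  if (length(ac) && !all(grepl("^[ACGU]{3}$", ac))) {
    stop("anticodons must be 3-letter RNA strings")
  }
  # Same-name same-kind intervals must not overlap (e.g. the exons of one
  # gene are disjoint).
  key <- paste(ft$name, ft$kind)
  for (k in unique(key[duplicated(key)])) {
    sub <- ft[key == k, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (any(sub$start[-1L] <= sub$end[-nrow(sub)])) {
      stop("overlapping ", sub$kind[1L], " intervals for '", sub$name[1L], "'")
    }
  }
  invisible(ft)
}

#' Read gene/exon/intron annotations from GFF3
#'
#' Features of type `gene`, `exon` and `intron` are extracted; any other
#' types are ignored (their count is reported with a message). The feature
#' name is taken from the `Name`, `gene` or `ID` attribute, in that order;
#' an `anticodon` attribute, when present, is attached for tRNA
#' disambiguation.
#'
#' @param path Path to a GFF3 file (1-based inclusive coordinates).
#' @return A [feature_table].
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gff <- ape::read.gff(path, GFF3 = TRUE)
  keep <- gff$type %in% c("gene", "exon", "intron")
  n_ignored <- sum(!keep)
  if (n_ignored > 0L) {
    message("ignored ", n_ignored, " feature(s) of other types in ", path)
  }
  gff <- gff[keep, , drop = FALSE]
  if (nrow(gff) == 0L) {
    return(feature_table(character(), character(), integer(), integer()))
  }
  attr_field <- function(attrs, key) {
    pat <- paste0("(?:^|;)\\s*", key, "=([^;]+)")
    hit <- regexpr(pat, attrs, perl = TRUE)
    res <- rep(NA_character_, length(attrs))
    ok <- hit > 0L
    res[ok] <- sub(pat, "\\1", regmatches(attrs, hit), perl = TRUE)
    res
  }
  attrs <- as.character(gff$attributes)
  nm <- attr_field(attrs, "Name")
  nm2 <- attr_field(attrs, "gene")
  nm3 <- attr_field(attrs, "ID")
  name <- ifelse(!is.na(nm), nm, ifelse(!is.na(nm2), nm2, nm3))
  if (anyNA(name)) stop("GFF3 feature without Name/gene/ID attribute")
  anticodon <- attr_field(attrs, "anticodon")
  feature_table(name = name, kind = as.character(gff$type),
                start = gff$start, end = gff$end,
                strand = as.character(gff$strand), anticodon = anticodon)
}

#' Write a feature table as GFF3
#' @param features A [feature_table].
#' @param path Output path.
#' @param seqid Sequence id for column 1.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, seqid = "ref") {
  attrs <- paste0("ID=", features$name, ".", features$kind, ".",
                  seq_len(nrow(features)), ";Name=", features$name)
  has_ac <- !is.na(features$anticodon)
  attrs[has_ac] <- paste0(attrs[has_ac], ";anticodon=",
                          features$anticodon[has_ac])
  lines <- paste(seqid, "cphotspot", features$kind, features$start,
                 features$end, ".", features$strand, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

# Display name of a gene: base name, with ^anticodon^ appended when the
# base name is ambiguous within the table (paralogous tRNAs).
gene_display_names <- function(features) {
  genes <- features[features$kind == "gene", , drop = FALSE]
  nm <- genes$name
  dup <- nm %in% nm[duplicated(nm)]
  out <- nm
  use <- dup & !is.na(genes$anticodon)
  out[use] <- paste0(nm[use], "^", genes$anticodon[use], "^")
  stats::setNames(out, paste0(nm, "@", genes$start))
}
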