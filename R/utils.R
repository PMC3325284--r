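# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC ambiguity codes (and N); treated as missing data downstream.
AMBIGUITY_CODES <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reverse complement of a DNA string
#'
#' @param x A single character string over the DNA alphabet (IUPAC codes
#'   allowed).
#' @return The reverse complement, as a character string.
#' @examples
#' revcomp("AACG")  # "CGTT"
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Reverse complement on a character vector of single bases; gaps are the
# caller's responsibility (used on gap-free selections only).
revcomp_chars <- function(chars) {
  rev(chartr("ACGTacgt", "TGCAtgca", chars))
}

# Length of the overlap of 1-based inclusive intervals [s1,e1] and [s2,e2].
overlap_length <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

# Sum over a 1-based inclusive range of a cumulative-sum vector that has a
# leading zero (cs[k+1] = sum of first k elements).
range_sum <- function(cs0, start, end) {
  cs0[end + 1L] - cs0[start]
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x)
}
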