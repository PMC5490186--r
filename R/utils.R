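# small shared helpers: sequence manipulation, phred decoding, junction keys

#' Reverse-complement nucleotide strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, any case).
#' @return Character vector of reverse complements, uppercase.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

# decode a phred+33 quality string into integer scores
phred_ints <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

# canonical junction key: chrom:intron_start-intron_end (0-based half-open)
jkey <- function(chrom, start, end) sprintf("%s:%d-%d", chrom, start, end)

# parse a CIGAR string into a list with integer lengths and character ops
cigar_ops <- function(cigar) {
  m <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")
  lapply(m, function(x) list(len = as.integer(x[, 2]), op = x[, 3]))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
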