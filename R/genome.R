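#' Load a reference genome from FASTA
#'
#' Reads a (multi-)FASTA file into an in-memory genome index. Sequences are
#' uppercased and any IUPAC ambiguity code other than A/C/G/T is stored as N.
#' Names are truncated at the first whitespace, the usual FASTA convention.
#'
#' @param path Path to a FASTA file.
#' @return A `svase_genome` object: a named character vector of chromosome
#'   sequences with a `lengths` accessor via [genome_lengths()].
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("duplicate sequence names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[^ACGT]", "N", seqs)
  names(seqs) <- nm
  structure(seqs, class = "svase_genome")
}

# build a genome object directly from named character sequences (simulator,
# tests); applies the same normalisation as load_genome()
as_genome <- function(seqs) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  seqs <- gsub("[^ACGT]", "N", toupper(unlist(seqs)))
  structure(seqs, class = "svase_genome")
}

#' Chromosome lengths of a genome index
#' @param genome A `svase_genome`.
#' @return Named integer vector of lengths in bp.
#' @export
genome_lengths <- function(genome) {
  stats::setNames(nchar(unclass(genome)), names(genome))
}

#' Extract a genome interval (0-based, half-open)
#'
#' @param genome A `svase_genome`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval; must lie within the contig.
#' @return Sequence string of length `end - start`.
#' @export
genome_seq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- nchar(genome[[chrom]])
  if (start < 0 || end > len || start > end) {
    stop(sprintf("interval [%d,%d) out of bounds for %s (length %d)",
                 start, end, chrom, len))
  }
  substr(genome[[chrom]], start + 1L, end)
}

# single reference base at a 0-based position
genome_base <- function(genome, chrom, pos) genome_seq(genome, chrom, pos, pos + 1L)

#' Write a genome index to FASTA
#' @param genome A `svase_genome`.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(unclass(genome), names(genome))), path)
  invisible(path)
}

#' @export
print.svase_genome <- function(x, ...) {
  cat("<svase_genome> ", length(x), " contig(s), ",
      format(sum(genome_lengths(x)), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}
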