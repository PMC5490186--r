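#' Read a SAM or BAM alignment file into a tibble
#'
#' SAM input is first converted to BAM with [Rsamtools::asBam()]; records
#' therefore surface in coordinate order regardless of input order (all
#' downstream logic is set-based and outputs are sorted, so ordering is
#' immaterial). One row per alignment record, with the SAM FLAG decoded into
#' logical columns and the mismatch (NM) tag carried along when present.
#'
#' Positions are converted to the package-wide 0-based half-open convention:
#' `pos` is the 0-based leftmost aligned reference base and `end` is
#' one-past the last aligned base (soft clips excluded, N gaps included).
#'
#' @param path SAM (`.sam`) or BAM file.
#' @param genome Optional `svase_genome`; if supplied, every mapped record's
#'   reference name must exist in it (error names the offender).
#' @return Tibble with columns `read_id, flag, chrom, pos, end, mapq, cigar,
#'   seq, qual, nm` plus decoded flag logicals (`paired, proper_pair,
#'   unmapped, reverse, secondary, qcfail, duplicate, supplementary`).
#' @export
read_alignments <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- suppressWarnings(
      Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE))
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = "NM")
  b <- Rsamtools::scanBam(bam, param = param)[[1]]
  nm <- b$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(b$qname))
  reads <- tibble::tibble(
    read_id = b$qname,
    flag    = b$flag,
    chrom   = as.character(b$rname),
    pos     = b$pos - 1L,
    mapq    = b$mapq,
    cigar   = b$cigar,
    seq     = as.character(b$seq),
    qual    = as.character(b$qual),
    nm      = as.integer(nm)
  )
  reads <- decode_flags(reads)
  reads$end <- reads$pos + ref_width(reads$cigar, reads$unmapped)
  if (!is.null(genome)) {
    bad <- setdiff(unique(reads$chrom[!reads$unmapped]), names(genome))
    if (length(bad)) {
      stop("alignment references absent from genome: ", paste(bad, collapse = ", "))
    }
  }
  reads
}

decode_flags <- function(reads) {
  f <- reads$flag
  dplyr::mutate(reads,
    paired        = bitwAnd(f, 1L) > 0L,
    proper_pair   = bitwAnd(f, 2L) > 0L,
    unmapped      = bitwAnd(f, 4L) > 0L,
    reverse       = bitwAnd(f, 16L) > 0L,
    secondary     = bitwAnd(f, 256L) > 0L,
    qcfail        = bitwAnd(f, 512L) > 0L,
    duplicate     = bitwAnd(f, 1024L) > 0L,
    supplementary = bitwAnd(f, 2048L) > 0L)
}

# reference-space width of a CIGAR (M/=/X/D/N consume reference)
ref_width <- function(cigar, unmapped = NULL) {
  w <- rep(NA_integer_, length(cigar))
  ok <- !is.na(cigar) & cigar != "*"
  if (!is.null(unmapped)) ok <- ok & !unmapped
  if (any(ok)) {
    w[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[ok])
  }
  w
}

#' Base calls covering one reference position
#'
#' Walks each covering read's CIGAR to find the query base aligned to a
#' reference position. Reads whose alignment spans the position only through
#' an N (intron) or D gap contribute no base. Bases with Phred quality below
#' `min_base_qual` are quality-masked and excluded — the same mask used in
#' pileup construction, so association counts and pileup counts agree.
#'
#' @param reads Alignment tibble (QC-passed).
#' @param chrom,pos Reference position, 0-based.
#' @param min_base_qual Mask threshold (Phred), default 30.
#' @return Tibble `read_id, base` with one row per unmasked covering base.
#' @export
bases_at <- function(reads, chrom, pos, min_base_qual = 30) {
  cand <- reads[!reads$unmapped & reads$chrom == chrom &
                  reads$pos <= pos & reads$end > pos, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(tibble::tibble(read_id = character(0), base = character(0)))
  }
  ops <- cigar_ops(cand$cigar)
  out_id <- character(0); out_base <- character(0)
  for (i in seq_len(nrow(cand))) {
    qi <- query_index_at(ops[[i]], cand$pos[i], pos)
    if (is.na(qi)) next
    q <- as.integer(charToRaw(substr(cand$qual[i], qi, qi))) - 33L
    if (q < min_base_qual) next
    base <- substr(cand$seq[i], qi, qi)
    if (base == "N") next
    out_id <- c(out_id, cand$read_id[i])
    out_base <- c(out_base, base)
  }
  tibble::tibble(read_id = out_id, base = out_base)
}

# 1-based query index aligned to reference position `pos`, or NA when the
# position falls in an N/D gap or outside the alignment
query_index_at <- function(op, read_pos, pos) {
  rpos <- read_pos; qpos <- 0L
  for (j in seq_along(op$op)) {
    o <- op$op[j]; l <- op$len[j]
    if (o %in% c("M", "=", "X")) {
      if (pos >= rpos && pos < rpos + l) return(qpos + (pos - rpos) + 1L)
      rpos <- rpos + l; qpos <- qpos + l
    } else if (o %in% c("N", "D")) {
      if (pos >= rpos && pos < rpos + l) return(NA_integer_)
      rpos <- rpos + l
    } else if (o %in% c("I", "S")) {
      qpos <- qpos + l
    }
  }
  NA_integer_
}
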