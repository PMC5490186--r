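#' Read-level quality-control parameters
#'
#' Stringent rule-dependent read filters applied before any junction or
#' variant logic. Defaults follow the method's conventions: reads shorter
#' than 30 bp, with mean base quality below Q30, unpaired mates of
#' paired-end libraries, PCR duplicates, QC-fail records, secondary or
#' supplementary (multi-mapping) alignments, indel-containing alignments and
#' reads with more than `max_mismatches` mismatches are rejected.
#'
#' Base quality plays a dual role: the whole-read mean gates the read here,
#' and individual bases below `min_base_qual` are additionally masked during
#' pileup and association counting (the read still supports its junction).
#'
#' @param min_base_qual Phred threshold for both the mean-quality gate and
#'   the per-base mask (default 30).
#' @param min_read_len Minimum read length in bp (default 30).
#' @param max_mismatches Maximum mismatches per read; a cap, not a ban,
#'   since variant-carrying reads necessarily mismatch (default 3).
#' @param allow_indels Keep reads whose alignments contain I/D operations
#'   (default `FALSE`).
#' @param require_proper_pair Reject paired-end reads lacking the
#'   proper-pair flag (default `TRUE`).
#' @param drop_duplicates,drop_qcfail,drop_secondary Reject flagged records
#'   (defaults `TRUE`).
#' @param min_mapq Reject primary alignments with MAPQ below this multi-mapper
#'   sentinel (default 1).
#' @return A `svase_qc_params` list.
#' @export
qc_params <- function(min_base_qual = 30, min_read_len = 30, max_mismatches = 3,
                      allow_indels = FALSE, require_proper_pair = TRUE,
                      drop_duplicates = TRUE, drop_qcfail = TRUE,
                      drop_secondary = TRUE, min_mapq = 1) {
  p <- list(min_base_qual = min_base_qual, min_read_len = min_read_len,
            max_mismatches = max_mismatches, allow_indels = allow_indels,
            require_proper_pair = require_proper_pair,
            drop_duplicates = drop_duplicates, drop_qcfail = drop_qcfail,
            drop_secondary = drop_secondary, min_mapq = min_mapq)
  stopifnot(min_base_qual >= 0, min_read_len >= 0, max_mismatches >= 0,
            min_mapq >= 0)
  structure(p, class = "svase_qc_params")
}

# rejection reasons in their fixed, exclusive evaluation order
qc_reasons <- c("unmapped", "multimap", "duplicate", "qcfail", "unpaired",
                "indel", "mismatch", "length", "basequal")

#' Assess one alignment record against the QC rules
#'
#' Reject reasons are exclusive and checked in a fixed order
#' (unmapped, multi-mapping, duplicate, qc-fail, unpaired, indel,
#' mismatch excess, length, mean base quality) so tallies are deterministic.
#'
#' @param read One-row alignment tibble.
#' @param params [qc_params()].
#' @param genome Optional genome, used to recompute mismatches when the NM
#'   tag is absent.
#' @return List with `pass` (logical) and `reason` (`NA` when passing).
#' @export
assess_read <- function(read, params = qc_params(), genome = NULL) {
  stopifnot(nrow(read) == 1L)
  r <- qc_reason_vec(read, params, genome)
  list(pass = is.na(r), reason = r)
}

# vectorised verdicts: NA = pass, else the first failing reason code
qc_reason_vec <- function(reads, params, genome = NULL) {
  n <- nrow(reads)
  reason <- rep(NA_character_, n)
  hit <- function(cond, code) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- code
  }
  hit(reads$unmapped, "unmapped")
  multi <- reads$mapq < params$min_mapq
  if (params$drop_secondary) multi <- multi | reads$secondary | reads$supplementary
  hit(multi, "multimap")
  hit(params$drop_duplicates & reads$duplicate, "duplicate")
  hit(params$drop_qcfail & reads$qcfail, "qcfail")
  hit(params$require_proper_pair & reads$paired & !reads$proper_pair, "unpaired")
  hit(!params$allow_indels & grepl("[ID]", reads$cigar), "indel")
  nm <- reads$nm
  if (any(is.na(nm) & is.na(reason)) && !is.null(genome)) {
    idx <- which(is.na(nm) & is.na(reason))
    nm[idx] <- vapply(idx, function(i) count_mismatches(reads[i, ], genome), integer(1))
  }
  hit(nm > params$max_mismatches, "mismatch")
  hit(nchar(reads$seq) < params$min_read_len, "length")
  meanq <- vapply(phred_ints(reads$qual), mean, numeric(1))
  hit(meanq < params$min_base_qual, "basequal")
  reason
}

# mismatches of a single read against the genome across its M blocks
count_mismatches <- function(read, genome) {
  op <- cigar_ops(read$cigar)[[1]]
  rpos <- read$pos; qpos <- 0L; mm <- 0L
  for (j in seq_along(op$op)) {
    o <- op$op[j]; l <- op$len[j]
    if (o %in% c("M", "=", "X")) {
      ref <- genome_seq(genome, read$chrom, rpos, rpos + l)
      qry <- substr(read$seq, qpos + 1L, qpos + l)
      mm <- mm + sum(charToRaw(ref) != charToRaw(qry))
      rpos <- rpos + l; qpos <- qpos + l
    } else if (o %in% c("N", "D")) {
      rpos <- rpos + l
    } else if (o %in% c("I", "S")) {
      qpos <- qpos + l
    }
  }
  as.integer(mm)
}

#' Filter an alignment table, tallying rejections by reason
#'
#' @param reads Alignment tibble from [read_alignments()].
#' @param params [qc_params()].
#' @param genome Optional genome for NM recomputation.
#' @return List: `reads` (passing rows, unchanged) and `tally`, a tibble of
#'   `reason`/`n` covering every rejection reason (zeros included) in the
#'   fixed evaluation order.
#' @export
filter_alignments <- function(reads, params = qc_params(), genome = NULL) {
  verdicts <- if (nrow(reads)) qc_reason_vec(reads, params, genome) else character(0)
  counts <- vapply(qc_reasons, function(rs) sum(verdicts == rs, na.rm = TRUE),
                   integer(1))
  tally <- tibble::tibble(reason = qc_reasons, n = unname(counts))
  reason <- verdicts
  list(reads = reads[is.na(reason), , drop = FALSE], tally = tally)
}
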