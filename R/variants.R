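#' Variant-calling parameters
#'
#' @param min_depth Minimum unmasked read depth at a site (default 3).
#' @param min_alt_reads Minimum ALT-supporting reads (default 3).
#' @param min_alt_fraction Minimum ALT proportion (default 0.1).
#' @param alpha_variant Significance threshold for the variant Fisher gate
#'   (default 0.05).
#' @param error_rate Per-base sequencing error probability used to build the
#'   expected-error row of the variant significance table (default 0.001,
#'   the Q30 error probability).
#' @return A `svase_variant_params` list.
#' @export
variant_params <- function(min_depth = 3, min_alt_reads = 3,
                           min_alt_fraction = 0.1, alpha_variant = 0.05,
                           error_rate = 0.001) {
  stopifnot(min_depth > 0, min_alt_reads > 0,
            min_alt_fraction > 0, min_alt_fraction < 1,
            alpha_variant > 0, alpha_variant < 1,
            error_rate > 0, error_rate < 1)
  structure(list(min_depth = min_depth, min_alt_reads = min_alt_reads,
                 min_alt_fraction = min_alt_fraction,
                 alpha_variant = alpha_variant, error_rate = error_rate),
            class = "svase_variant_params")
}

#' Build per-side pileups over junction anchor blocks
#'
#' Each junction is decomposed into two independent parts: the left (5'ss on
#' the plus strand) and right (3'ss) exonic anchors. For every supporting
#' read, only bases aligned within the anchor block adjacent to that
#' junction's intron are counted; bases below `min_base_qual` and N calls
#' are quality-masked. Left-side positions are always `< intron_start`,
#' right-side positions `>= intron_end`.
#'
#' @param junctions Junction tibble (surviving all junction filters).
#' @param obs Observation tibble from [junction_observations()] (anchor
#'   geometry is reused, no CIGAR re-walk).
#' @param reads QC-passed alignment tibble (for sequences and qualities).
#' @param min_base_qual Per-base mask threshold (default 30).
#' @return Long pileup tibble: `junction_id, side, chrom, pos, base, n`.
#' @export
side_pileups <- function(junctions, obs, reads, min_base_qual = 30) {
  empty <- tibble::tibble(junction_id = character(0), side = character(0),
                          chrom = character(0), pos = integer(0),
                          base = character(0), n = integer(0))
  if (nrow(junctions) == 0L || nrow(obs) == 0L) return(empty)
  obs$junction_id <- jkey(obs$chrom, obs$intron_start, obs$intron_end)
  obs <- obs[obs$junction_id %in% junctions$junction_id, , drop = FALSE]
  if (nrow(obs) == 0L) return(empty)
  # a read may report the same intron once per N op; count each read once
  obs <- dplyr::distinct(obs, .data$junction_id, .data$read_id, .keep_all = TRUE)
  ridx <- match(obs$read_id, reads$read_id)
  seqs <- reads$seq[ridx]
  qints <- phred_ints(reads$qual[ridx])

  blocks <- dplyr::bind_rows(
    tibble::tibble(junction_id = obs$junction_id, side = "left",
                   chrom = obs$chrom, ref_start = obs$left_ref_start,
                   qstart = obs$left_qstart, len = obs$left_anchor,
                   seq = seqs, qi = qints),
    tibble::tibble(junction_id = obs$junction_id, side = "right",
                   chrom = obs$chrom, ref_start = obs$intron_end,
                   qstart = obs$right_qstart, len = obs$right_anchor,
                   seq = seqs, qi = qints))

  idx <- sequence(blocks$len) # 1..len within each block
  row <- rep(seq_len(nrow(blocks)), blocks$len)
  pos <- blocks$ref_start[row] + idx - 1L
  qpos <- blocks$qstart[row] + idx # 1-based query index
  base <- substring(blocks$seq[row], qpos, qpos)
  qual <- unlist(purrr::pmap(list(blocks$qi, blocks$qstart, blocks$len),
                             function(qi, qs, l) qi[qs + seq_len(l)]))
  keep <- qual >= min_base_qual & base != "N"
  tibble::tibble(junction_id = blocks$junction_id[row][keep],
                 side = blocks$side[row][keep],
                 chrom = blocks$chrom[row][keep],
                 pos = pos[keep], base = base[keep]) |>
    dplyr::count(.data$junction_id, .data$side, .data$chrom, .data$pos,
                 .data$base, name = "n")
}

#' Variant significance against the sequencing-error expectation
#'
#' One-sided (greater) Fisher exact p for
#' `[[alt_count, depth - alt_count], [e, depth - e]]` where
#' `e = round(error_rate * depth)` is the number of ALT observations
#' expected from sequencing error alone.
#'
#' @param alt_count,depth Observed ALT count and unmasked depth (vectors).
#' @param params [variant_params()].
#' @return Vector of p-values.
#' @export
variant_significance <- function(alt_count, depth, params = variant_params()) {
  e <- round(params$error_rate * depth)
  fisher_exact_p_vec(alt_count, depth - alt_count, e, depth - e, "greater")
}

#' Call variant candidates from side pileups
#'
#' For every pileup column and every non-reference base, a candidate is
#' formed and kept iff depth, ALT read count and ALT fraction meet their
#' thresholds and the variant significance gate passes
#' (`p <= alpha_variant`). One column may yield several candidates with
#' different ALT bases, each tested on its own counts.
#'
#' @param pileups Tibble from [side_pileups()].
#' @param genome `svase_genome` supplying the reference base.
#' @param params [variant_params()].
#' @return Candidate tibble: `junction_id, side, chrom, pos, ref, alt,
#'   depth, alt_count, alt_fraction, p_variant`.
#' @export
call_candidates <- function(pileups, genome, params = variant_params()) {
  empty <- tibble::tibble(junction_id = character(0), side = character(0),
                          chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          depth = integer(0), alt_count = integer(0),
                          alt_fraction = numeric(0), p_variant = numeric(0))
  if (nrow(pileups) == 0L) return(empty)
  cols <- pileups |>
    dplyr::group_by(.data$junction_id, .data$side, .data$chrom, .data$pos) |>
    dplyr::mutate(depth = sum(.data$n)) |>
    dplyr::ungroup()
  # reference base per unique (chrom, pos), vectorised per chromosome
  sites <- dplyr::distinct(cols, .data$chrom, .data$pos)
  sites$ref <- NA_character_
  for (ch in unique(sites$chrom)) {
    idx <- sites$chrom == ch
    sites$ref[idx] <- substring(genome[[ch]], sites$pos[idx] + 1L,
                                sites$pos[idx] + 1L)
  }
  cols <- dplyr::left_join(cols, sites, by = c("chrom", "pos"))
  cand <- cols |>
    dplyr::filter(.data$base != .data$ref, .data$ref %in% c("A", "C", "G", "T")) |>
    dplyr::rename(alt = "base", alt_count = "n") |>
    dplyr::mutate(alt_fraction = .data$alt_count / .data$depth) |>
    dplyr::filter(.data$depth >= params$min_depth,
                  .data$alt_count >= params$min_alt_reads,
                  .data$alt_fraction >= params$min_alt_fraction)
  cand$p_variant <- variant_significance(cand$alt_count, cand$depth, params)
  cand <- cand[p_within_alpha(cand$p_variant, params$alpha_variant), ,
               drop = FALSE]
  dplyr::select(cand, "junction_id", "side", "chrom", "pos", "ref", "alt",
                "depth", "alt_count", "alt_fraction", "p_variant") |>
    dplyr::arrange(.data$chrom, .data$pos, .data$junction_id, .data$alt)
}
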