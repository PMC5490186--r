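#' Junction-stage parameters
#'
#' @param min_anchor Minimum aligned anchor, in bp, required on *both* sides
#'   of a junction for a split read to count as support (default 8).
#' @param min_junction_depth Minimum distinct supporting reads (default 3).
#' @param background_rate Background expression proportion tested against in
#'   the Fisher filter over related junctions (default 0.01).
#' @param alpha_junction Significance threshold for the background test
#'   (default 0.05).
#' @param max_shift Maximum boundary offset, in bp, scanned for junction-shift
#'   (alignment-ambiguity) events (default 10).
#' @param keep_known Keep junctions matching the annotation (`TRUE`) or
#'   restrict downstream analysis to novel junctions (`FALSE`).
#' @return A `svase_junction_params` list.
#' @export
junction_params <- function(min_anchor = 8, min_junction_depth = 3,
                            background_rate = 0.01, alpha_junction = 0.05,
                            max_shift = 10, keep_known = TRUE) {
  stopifnot(min_anchor >= 1, min_junction_depth >= 1,
            background_rate > 0, background_rate < 1,
            alpha_junction > 0, alpha_junction < 1, max_shift >= 0)
  structure(list(min_anchor = min_anchor,
                 min_junction_depth = min_junction_depth,
                 background_rate = background_rate,
                 alpha_junction = alpha_junction,
                 max_shift = max_shift, keep_known = keep_known),
            class = "svase_junction_params")
}

#' Extract junction observations from split reads
#'
#' One observation per CIGAR `N` operation. The left/right anchors are the
#' matched blocks immediately flanking that specific gap; for multi-intron
#' reads the inter-intron block is the shared anchor of both neighbours.
#' Observations with either anchor shorter than `min_anchor` are dropped.
#' Alongside the intron interval, the reference start and query offset of
#' each anchor block are recorded so pileups can be built later without
#' re-walking CIGARs.
#'
#' @param reads QC-passed alignment tibble.
#' @param min_anchor Minimum anchor length in bp (default 8).
#' @return Tibble: `read_id, chrom, intron_start, intron_end, left_anchor,
#'   right_anchor, left_ref_start, left_qstart, right_qstart` (0-based;
#'   `*_qstart` are 0-based offsets into the read sequence).
#' @export
junction_observations <- function(reads, min_anchor = 8) {
  empty <- tibble::tibble(
    read_id = character(0), chrom = character(0),
    intron_start = integer(0), intron_end = integer(0),
    left_anchor = integer(0), right_anchor = integer(0),
    left_ref_start = integer(0), left_qstart = integer(0),
    right_qstart = integer(0))
  split <- reads[!reads$unmapped & grepl("N", reads$cigar, fixed = TRUE), ,
                 drop = FALSE]
  if (nrow(split) == 0L) return(empty)

  # fast path: the canonical single-intron shape <a>M<i>N<b>M (soft clips allowed)
  simple <- stringr::str_match(split$cigar,
    "^(?:(\\d+)S)?(\\d+)M(\\d+)N(\\d+)M(?:(\\d+)S)?$")
  is_simple <- !is.na(simple[, 1])
  res <- list()
  if (any(is_simple)) {
    s <- split[is_simple, ]
    la <- as.integer(simple[is_simple, 3])
    il <- as.integer(simple[is_simple, 4])
    ra <- as.integer(simple[is_simple, 5])
    clip <- as.integer(simple[is_simple, 2]); clip[is.na(clip)] <- 0L
    res[[1]] <- tibble::tibble(
      read_id = s$read_id, chrom = s$chrom,
      intron_start = s$pos + la, intron_end = s$pos + la + il,
      left_anchor = la, right_anchor = ra,
      left_ref_start = s$pos, left_qstart = clip,
      right_qstart = clip + la)
  }
  if (any(!is_simple)) {
    gen <- split[!is_simple, ]
    ops <- cigar_ops(gen$cigar)
    res[[2]] <- purrr::map_dfr(seq_len(nrow(gen)), function(i) {
      obs_from_cigar(ops[[i]], gen$read_id[i], gen$chrom[i], gen$pos[i])
    })
  }
  out <- dplyr::bind_rows(res)
  out[out$left_anchor >= min_anchor & out$right_anchor >= min_anchor, ,
      drop = FALSE]
}

# general CIGAR walk for one read; errors on a gap with no flanking match
obs_from_cigar <- function(op, read_id, chrom, pos) {
  rpos <- pos; qpos <- 0L
  blk <- NULL          # last aligned block: ref_start, qstart, len
  pending <- list()    # introns awaiting their right anchor
  done <- list()
  for (j in seq_along(op$op)) {
    o <- op$op[j]; l <- op$len[j]
    if (o %in% c("M", "=", "X")) {
      newblk <- list(ref_start = rpos, qstart = qpos, len = l)
      # merge runs split only in op encoding (e.g. 5=1X4=)
      if (!is.null(blk) && blk$ref_start + blk$len == rpos &&
          blk$qstart + blk$len == qpos) {
        newblk <- list(ref_start = blk$ref_start, qstart = blk$qstart,
                       len = blk$len + l)
      }
      blk <- newblk
      for (p in pending) {
        done[[length(done) + 1L]] <- tibble::tibble(
          read_id = read_id, chrom = chrom,
          intron_start = p$start, intron_end = p$end,
          left_anchor = p$left$len, right_anchor = blk$len,
          left_ref_start = p$left$ref_start, left_qstart = p$left$qstart,
          right_qstart = blk$qstart)
      }
      pending <- list()
      rpos <- rpos + l; qpos <- qpos + l
    } else if (o == "N") {
      if (is.null(blk) || blk$ref_start + blk$len != rpos) {
        stop("malformed alignment for read ", read_id,
             ": intron gap without a flanking aligned block")
      }
      pending[[length(pending) + 1L]] <- list(start = rpos, end = rpos + l,
                                              left = blk)
      rpos <- rpos + l
      blk <- NULL
    } else if (o == "D") {
      rpos <- rpos + l; blk <- NULL
    } else if (o == "I") {
      qpos <- qpos + l; blk <- NULL
    } else if (o == "S") {
      qpos <- qpos + l
    }
  }
  if (length(pending)) {
    stop("malformed alignment for read ", read_id, ": CIGAR ends in an intron gap")
  }
  dplyr::bind_rows(done)
}

#' Aggregate junction observations into a junction table
#'
#' Depth counts *distinct* supporting reads (a read observed twice for the
#' same intron counts once); junctions below `min_junction_depth` are
#' discarded.
#'
#' @param obs Tibble from [junction_observations()].
#' @param params [junction_params()].
#' @return Junction tibble: `junction_id, chrom, intron_start, intron_end,
#'   depth, read_ids` (list-column), sorted by coordinate.
#' @export
aggregate_junctions <- function(obs, params = junction_params()) {
  tab <- obs |>
    dplyr::group_by(.data$chrom, .data$intron_start, .data$intron_end) |>
    dplyr::summarise(depth = dplyr::n_distinct(.data$read_id),
                     read_ids = list(sort(unique(.data$read_id))),
                     .groups = "drop") |>
    dplyr::filter(.data$depth >= params$min_junction_depth) |>
    dplyr::arrange(.data$chrom, .data$intron_start, .data$intron_end)
  tab$junction_id <- jkey(tab$chrom, tab$intron_start, tab$intron_end)
  dplyr::relocate(tab, "junction_id")
}

#' Related splicing events of each junction
#'
#' Related events share the same intron start (5'ss) or the same intron end
#' (3'ss) on the same chromosome. The combined (union) set drives the
#' junction-level background test; side-specific sets (sharing the opposite
#' boundary of the side under analysis) drive variant consistency and
#' association work.
#'
#' @param junctions Junction tibble.
#' @return The junction tibble with list-columns `related_start`
#'   (junction_ids sharing intron_start), `related_end` (sharing
#'   intron_end); a junction is never in its own related sets.
#' @export
related_junctions <- function(junctions) {
  key_s <- paste(junctions$chrom, junctions$intron_start)
  key_e <- paste(junctions$chrom, junctions$intron_end)
  by_s <- split(junctions$junction_id, key_s)
  by_e <- split(junctions$junction_id, key_e)
  junctions$related_start <- purrr::map2(key_s, junctions$junction_id,
                                         function(k, id) setdiff(by_s[[k]], id))
  junctions$related_end <- purrr::map2(key_e, junctions$junction_id,
                                       function(k, id) setdiff(by_e[[k]], id))
  junctions
}

#' Background-expression Fisher filter
#'
#' Tests each junction's read share against a background proportion within
#' the combined pool of the junction and its related events. With
#' `N = depth + sum(related depths)` and `b = ceiling(background_rate * N)`,
#' the one-sided (greater) Fisher exact p of `[[depth, N-depth], [b, N-b]]`
#' must be at or below `alpha_junction`. A junction with no related events
#' faces no competition and is kept with `background_p = 0`.
#'
#' @param junctions Junction tibble (with related sets; computed if absent).
#' @param params [junction_params()].
#' @return Junction tibble with `background_p`, filtered to significant rows.
#' @export
filter_background <- function(junctions, params = junction_params()) {
  if (nrow(junctions) == 0L) {
    junctions$background_p <- numeric(0)
    return(junctions)
  }
  if (is.null(junctions$related_start)) junctions <- related_junctions(junctions)
  depth_of <- stats::setNames(junctions$depth, junctions$junction_id)
  rel_total <- vapply(seq_len(nrow(junctions)), function(i) {
    ids <- union(junctions$related_start[[i]], junctions$related_end[[i]])
    sum(depth_of[ids])
  }, numeric(1))
  p <- numeric(nrow(junctions))
  for (i in seq_len(nrow(junctions))) {
    if (rel_total[i] == 0) { p[i] <- 0; next }
    d <- junctions$depth[i]
    N <- d + rel_total[i]
    b <- ceiling(params$background_rate * N)
    p[i] <- fisher_exact_p(d, N - d, b, N - b, "greater")
  }
  junctions$background_p <- p
  junctions[p_within_alpha(p, params$alpha_junction), , drop = FALSE]
}

#' Classify junctions against an annotation
#'
#' Exact intron-interval matches are `known`, everything else `novel`. With
#' `keep_known = FALSE` the table is restricted to novel junctions
#' (novel-only mode).
#'
#' @param junctions Junction tibble.
#' @param known Known-junction tibble (`chrom, intron_start, intron_end`), or
#'   `NULL`/empty for no annotation (everything is `novel`).
#' @param keep_known Retain known junctions (default `TRUE`).
#' @return Junction tibble with a `status` column.
#' @export
classify_vs_known <- function(junctions, known = NULL, keep_known = TRUE) {
  if (is.null(known) || nrow(known) == 0L) {
    junctions$status <- rep("novel", nrow(junctions))
  } else {
    kk <- jkey(known$chrom, known$intron_start, known$intron_end)
    junctions$status <- ifelse(junctions$junction_id %in% kk, "known", "novel")
  }
  if (!keep_known) junctions <- junctions[junctions$status == "novel", , drop = FALSE]
  junctions
}

#' Detect junction-shift (alignment-ambiguity) events
#'
#' A novel junction is a shift of a known intron when a known intron of
#' identical length sits at a small boundary offset *and* the genome sequence
#' makes the two alignments indistinguishable: introns `[s, e)` and
#' `[s+k, e+k)` yield the same spliced sequence iff
#' `genome[s, s+k) == genome[e, e+k)` (for `k > 0`; symmetric for `k < 0`).
#' The smallest `|offset|` wins, ties broken toward the positive offset.
#'
#' @param junctions Junction tibble with `status`.
#' @param known Known-junction tibble.
#' @param genome `svase_genome`.
#' @param max_shift Maximum |offset| scanned (default 10).
#' @return Junction tibble with `shift_of` (known junction key or `NA`) and
#'   `shift_offset` (novel minus known boundary, or `NA`); shifted rows get
#'   `status = "shift"`.
#' @export
detect_shift <- function(junctions, known, genome, max_shift = 10) {
  junctions$shift_of <- rep(NA_character_, nrow(junctions))
  junctions$shift_offset <- rep(NA_integer_, nrow(junctions))
  if (is.null(known) || nrow(known) == 0L || nrow(junctions) == 0L ||
      max_shift < 1) {
    return(junctions)
  }
  offsets <- as.vector(rbind(seq_len(max_shift), -seq_len(max_shift)))
  kk <- jkey(known$chrom, known$intron_start, known$intron_end)
  known_set <- stats::setNames(seq_along(kk), kk)
  for (i in which(junctions$status == "novel")) {
    s <- junctions$intron_start[i]; e <- junctions$intron_end[i]
    chrom <- junctions$chrom[i]
    clen <- genome_lengths(genome)[[chrom]]
    for (k in offsets) {
      ks <- s - k; ke <- e - k # candidate known intron: novel = known + k
      key <- jkey(chrom, ks, ke)
      if (is.na(known_set[key])) next
      lo_s <- min(s, ks); lo_e <- min(e, ke)
      if (lo_s < 0 || max(e, ke) > clen) next
      if (genome_seq(genome, chrom, lo_s, lo_s + abs(k)) ==
          genome_seq(genome, chrom, lo_e, lo_e + abs(k))) {
        junctions$shift_of[i] <- key
        junctions$shift_offset[i] <- k
        junctions$status[i] <- "shift"
        break
      }
    }
  }
  junctions
}
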