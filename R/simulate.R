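#' Configuration for the synthetic spliced-read generator
#'
#' Defaults describe the reference validation conditions used throughout
#' the package's tests: one 1 Mb chromosome carrying 200 GT-AG junctions at
#' uniform read depth 30 with 12-38 bp anchors, 50 junction-private planted
#' variants at ALT fraction 0.9, Q30-equivalent base error rate 0.001, and
#' five non-split (decoy) reads per junction side providing the association
#' contrast.
#'
#' @param seed RNG seed; the same seed reproduces byte-identical output.
#' @param n_chroms,chrom_len Genome shape.
#' @param n_junctions Planted junctions (split across chromosomes).
#' @param intron_len Length-2 range of intron lengths (bp).
#' @param depth Split-read depth per junction.
#' @param anchor_len Length-2 range of anchor lengths (bp); right anchors
#'   are stretched so every read is at least 30 bp.
#' @param n_variants Planted variants (at most one per junction).
#' @param alt_fraction Fraction of covering reads carrying the ALT allele.
#' @param placement `"junction-private"` (ALT restricted to target-junction
#'   reads), `"shared-with-related"` (shared across junctions sharing the
#'   acceptor; forces `frac_related > 0`), or `"genome-wide"` (uniform ALT
#'   across all covering reads, junction-supporting or not).
#' @param error_rate Per-base substitution error probability.
#' @param frac_related Fraction of junctions given a sibling junction
#'   sharing their intron end (a competing donor).
#' @param decoys_per_side Non-split reads covering each junction flank.
#' @param decoy_len Decoy read length (bp).
#' @param minus_strand_frac Fraction of junctions written with the
#'   minus-strand canonical motif (CT..AC) instead of GT..AG.
#' @param paired Emit reads flagged as proper pairs (flags only; mates are
#'   independent molecules here).
#' @param n_duplicates,n_secondary,n_qcfail,n_lowqual,n_short Counts of
#'   QC-noise records to inject (rejected upstream by design).
#' @return A `svase_sim_config` list.
#' @export
sim_config <- function(seed = 1, n_chroms = 1, chrom_len = 1e6,
                       n_junctions = 200, intron_len = c(200, 2000),
                       depth = 30, anchor_len = c(12, 38),
                       n_variants = 50, alt_fraction = 0.9,
                       placement = c("junction-private", "shared-with-related",
                                     "genome-wide"),
                       error_rate = 0.001, frac_related = 0,
                       decoys_per_side = 5, decoy_len = 50,
                       minus_strand_frac = 0, paired = FALSE,
                       n_duplicates = 0, n_secondary = 0, n_qcfail = 0,
                       n_lowqual = 0, n_short = 0) {
  placement <- match.arg(placement)
  stopifnot(alt_fraction >= 0, alt_fraction <= 1,
            error_rate >= 0, error_rate < 1,
            frac_related >= 0, frac_related <= 1,
            minus_strand_frac >= 0, minus_strand_frac <= 1,
            n_variants <= n_junctions,
            anchor_len[1] >= 1, intron_len[1] >= 10)
  if (placement == "shared-with-related" && frac_related == 0) frac_related <- 1
  structure(as.list(environment()), class = "svase_sim_config")
}

#' Simulate a spliced RNA-seq dataset with truth tables
#'
#' Generates a uniform-random genome with canonical splice motifs written at
#' planted introns, junction-spanning reads with configurable anchors,
#' planted variant alleles, decoy (non-split) coverage, base-call errors and
#' optional QC-noise records. Reads are emitted pre-aligned: the generator
#' writes truthful alignments directly, so the caller is tested, not an
#' aligner. Deterministic for a fixed config.
#'
#' @param config [sim_config()].
#' @param dir Optional output directory; when given, writes `genome.fa`,
#'   `reads.sam`, `truth_junctions.tsv`, `truth_variants.tsv`.
#' @return List: `genome` (`svase_genome`), `reads` (alignment tibble in
#'   [read_alignments()] layout), `truth_junctions`, `truth_variants`,
#'   `config`, and `paths` when `dir` was given.
#' @export
simulate_splice_reads <- function(config = sim_config(), dir = NULL) {
  set.seed(config$seed)
  chrom_names <- sprintf("chr%d", seq_len(config$n_chroms))
  seqs <- vapply(chrom_names, function(x) {
    paste(sample(c("A", "C", "G", "T"), config$chrom_len, replace = TRUE),
          collapse = "")
  }, character(1))

  jt <- place_junctions(config, chrom_names)
  for (i in seq_len(nrow(jt))) { # write splice motifs into the genome
    ch <- jt$chrom[i]
    motif <- if (jt$strand[i] == "+") c("GT", "AG") else c("CT", "AC")
    substr(seqs[[ch]], jt$intron_start[i] + 1L, jt$intron_start[i] + 2L) <- motif[1]
    substr(seqs[[ch]], jt$intron_end[i] - 1L, jt$intron_end[i]) <- motif[2]
  }

  rd <- build_reads(config, jt, seqs)
  reads <- rd$reads
  truth_v <- plant_variants(config, jt, reads, seqs)
  reads <- truth_v$reads
  truth_variants <- truth_v$truth
  reads <- inject_errors(reads, config$error_rate)
  reads$nm <- mismatch_vs_template(reads$seq, rd$template)
  reads <- inject_noise(config, reads, jt, seqs)

  aln <- as_alignment_tibble(reads, config)
  genome <- as_genome(seqs)
  jt$junction_id <- jkey(jt$chrom, jt$intron_start, jt$intron_end)
  out <- list(genome = genome, reads = aln,
              truth_junctions = jt, truth_variants = truth_variants,
              config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(genome = file.path(dir, "genome.fa"),
                  sam = file.path(dir, "reads.sam"),
                  truth_junctions = file.path(dir, "truth_junctions.tsv"),
                  truth_variants = file.path(dir, "truth_variants.tsv"))
    write_genome(genome, paths$genome)
    write_sam(aln, genome, paths$sam)
    readr::write_tsv(jt, paths$truth_junctions)
    readr::write_tsv(truth_variants, paths$truth_variants)
    out$paths <- paths
  }
  out
}

# lay out non-overlapping introns with 80 bp exonic flanks; siblings share
# the intron end (competing donor) with a start shifted 20-60 bp right
place_junctions <- function(config, chrom_names) {
  per_chrom <- table(factor(rep_len(chrom_names, config$n_junctions),
                            levels = chrom_names))
  rows <- list()
  for (ch in chrom_names) {
    cursor <- 150L
    for (j in seq_len(per_chrom[[ch]])) {
      ilen <- sample(config$intron_len[1]:config$intron_len[2], 1L)
      s <- cursor + 80L
      e <- s + ilen
      if (e + 280L > config$chrom_len) {
        stop("infeasible simulation config: chromosome too short for ",
             config$n_junctions, " junctions")
      }
      strand <- if (stats::runif(1) < config$minus_strand_frac) "-" else "+"
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = ch, intron_start = s, intron_end = e, strand = strand,
        depth = config$depth, is_sibling = FALSE)
      if (stats::runif(1) < config$frac_related) {
        s2 <- s + sample(20:60, 1L)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          chrom = ch, intron_start = s2, intron_end = e, strand = strand,
          depth = config$depth, is_sibling = TRUE)
      }
      cursor <- e + 80L + sample(100:300, 1L)
    }
  }
  dplyr::bind_rows(rows)
}

build_reads <- function(config, jt, seqs) {
  amin <- config$anchor_len[1]; amax <- config$anchor_len[2]
  lst <- list(); tmpl <- list()
  counter <- 0L
  for (i in seq_len(nrow(jt))) {
    ch <- jt$chrom[i]; s <- jt$intron_start[i]; e <- jt$intron_end[i]
    d <- jt$depth[i]
    la <- sample(amin:amax, d, replace = TRUE)
    ra <- pmax(sample(amin:amax, d, replace = TRUE), 30L - la)
    seq <- paste0(substring(seqs[[ch]], s - la + 1L, s),
                  substring(seqs[[ch]], e + 1L, e + ra))
    lst[[length(lst) + 1L]] <- tibble::tibble(
      read_id = sprintf("r%07d", counter + seq_len(d)),
      type = "junction", j_idx = i, chrom = ch,
      pos = s - la, la = la, ra = ra,
      cigar = sprintf("%dM%dN%dM", la, e - s, ra),
      seq = seq, flag = 0L)
    counter <- counter + d
    nd <- config$decoys_per_side
    if (nd > 0) {
      offL <- sample(10:42, nd, replace = TRUE)
      offR <- sample(8:40, nd, replace = TRUE)
      dpos <- c(s - offL, e - offR)
      dseq <- substring(seqs[[ch]], dpos + 1L, dpos + config$decoy_len)
      lst[[length(lst) + 1L]] <- tibble::tibble(
        read_id = sprintf("r%07d", counter + seq_len(2L * nd)),
        type = "decoy", j_idx = i, chrom = ch,
        pos = dpos, la = config$decoy_len, ra = 0L,
        cigar = sprintf("%dM", config$decoy_len),
        seq = dseq, flag = 0L)
      counter <- counter + 2L * nd
    }
  }
  reads <- dplyr::bind_rows(lst)
  list(reads = reads, template = reads$seq)
}

# positions covered by a read's aligned blocks
sim_read_covers <- function(reads, jt, pos) {
  jm <- reads$j_idx
  s <- jt$intron_start[jm]; e <- jt$intron_end[jm]
  ifelse(reads$type == "junction",
         (pos >= reads$pos & pos < s) | (pos >= e & pos < e + reads$ra),
         pos >= reads$pos & pos < reads$pos + reads$la)
}

# apply an ALT base at reference position `pos` within each selected read
sim_apply_alt <- function(reads, jt, sel, pos, alt) {
  for (k in sel) {
    if (reads$type[k] == "junction") {
      s <- jt$intron_start[reads$j_idx[k]]; e <- jt$intron_end[reads$j_idx[k]]
      idx <- if (pos < s) pos - reads$pos[k] + 1L else reads$la[k] + (pos - e) + 1L
    } else {
      idx <- pos - reads$pos[k] + 1L
    }
    substr(reads$seq[k], idx, idx) <- alt
  }
  reads
}

plant_variants <- function(config, jt, reads, seqs) {
  truth <- tibble::tibble(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), junction_id = character(0), side = character(0),
    placement = character(0), alt_fraction = numeric(0),
    n_alt_target = integer(0), depth_target = integer(0),
    expected = logical(0))
  if (config$n_variants == 0L) return(list(reads = reads, truth = truth))
  primaries <- which(!jt$is_sibling)
  targets <- sort(sample(primaries, config$n_variants))
  rows <- list()
  for (t in targets) {
    ch <- jt$chrom[t]; s <- jt$intron_start[t]; e <- jt$intron_end[t]
    side <- if (config$placement == "shared-with-related") "right" else
      sample(c("left", "right"), 1L)
    offset <- sample(1:8, 1L)
    pos <- if (side == "left") s - offset else e + offset - 1L
    ref <- substr(seqs[[ch]], pos + 1L, pos + 1L)
    alt <- if (ref == "A") "G" else sample(setdiff(c("A", "C", "G", "T"), ref), 1L)

    cover <- which(reads$chrom == ch & sim_read_covers(reads, jt, pos))
    target_reads <- cover[reads$type[cover] == "junction" &
                            reads$j_idx[cover] == t]
    strata <- switch(config$placement,
      "junction-private" = list(target_reads),
      "shared-with-related" = {
        keep <- cover[reads$type[cover] == "junction"]
        split(keep, reads$j_idx[keep])
      },
      "genome-wide" = split(cover, paste(reads$type[cover], reads$j_idx[cover])))
    n_alt_target <- 0L
    for (g in strata) {
      n_alt <- round(config$alt_fraction * length(g))
      sel <- sort(g)[seq_len(n_alt)]
      reads <- sim_apply_alt(reads, jt, sel, pos, alt)
      if (length(g) && any(g %in% target_reads)) {
        n_alt_target <- n_alt_target + sum(sel %in% target_reads)
      }
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      chrom = ch, pos = pos, ref = ref, alt = alt,
      junction_id = jkey(ch, s, e), side = side,
      placement = config$placement, alt_fraction = config$alt_fraction,
      n_alt_target = n_alt_target, depth_target = length(target_reads),
      expected = expected_svase(config, n_alt_target, length(target_reads)))
  }
  list(reads = reads, truth = dplyr::bind_rows(rows))
}

# expected-detection arithmetic under the default thresholds, derived only
# from the configuration (audited independently in the test suite)
expected_svase <- function(config, n_alt, depth) {
  if (depth < 3L || n_alt < 3L || n_alt / depth < 0.1) return(FALSE)
  e0 <- round(config$error_rate * depth)
  if (fisher_exact_p(n_alt, depth - n_alt, e0, depth - e0, "greater") > 0.05) {
    return(FALSE)
  }
  if (config$placement == "junction-private") {
    n_dec <- config$decoys_per_side
    if (n_dec == 0L) return(TRUE) # no contrast: kept by convention
    p <- fisher_exact_p(n_alt, depth - n_alt, 0L, n_dec, "greater")
    return(p <= 0.05)
  }
  if (config$placement == "genome-wide") return(FALSE)
  # shared-with-related: sibling reads carry the same ALT fraction, so the
  # association contrast is expected to vanish
  sib_alt <- round(config$alt_fraction * config$depth)
  p <- fisher_exact_p(n_alt, depth - n_alt,
                      sib_alt, config$depth - sib_alt + config$decoys_per_side,
                      "greater")
  p <= 0.05
}

inject_errors <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  nb <- nchar(reads$seq)
  nerr <- stats::rbinom(nrow(reads), nb, error_rate)
  for (k in which(nerr > 0)) {
    at <- sample(nb[k], nerr[k])
    for (a in at) {
      old <- substr(reads$seq[k], a, a)
      substr(reads$seq[k], a, a) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    }
  }
  reads
}

mismatch_vs_template <- function(seq, template) {
  mapply(function(a, b) sum(charToRaw(a) != charToRaw(b)), seq, template,
         USE.NAMES = FALSE)
}

inject_noise <- function(config, reads, jt, seqs) {
  take <- function(n) reads[rep_len(which(reads$type == "junction"), n), , drop = FALSE]
  extra <- list()
  relabel <- function(df, tag, flag_add) {
    if (nrow(df) == 0L) return(NULL)
    df$read_id <- paste0(df$read_id, "_", tag)
    df$flag <- df$flag + flag_add
    df
  }
  extra$dup <- relabel(take(config$n_duplicates), "dup", 1024L)
  extra$sec <- relabel(take(config$n_secondary), "sec", 256L)
  extra$qcf <- relabel(take(config$n_qcfail), "qcf", 512L)
  lowq <- take(config$n_lowqual)
  if (nrow(lowq)) {
    lowq <- relabel(lowq, "lowq", 0L)
    lowq$lowqual <- TRUE
  }
  extra$lowq <- lowq
  if (config$n_short > 0) {
    ch <- jt$chrom[1]
    pos <- jt$intron_start[1] - 100L + seq_len(config$n_short)
    extra$short <- tibble::tibble(
      read_id = sprintf("short%04d", seq_len(config$n_short)),
      type = "decoy", j_idx = 1L, chrom = ch, pos = pos,
      la = 20L, ra = 0L, cigar = "20M",
      seq = substring(seqs[[ch]], pos + 1L, pos + 20L), flag = 0L)
  }
  reads$lowqual <- FALSE
  extra <- purrr::compact(extra)
  if (length(extra)) {
    extra <- dplyr::bind_rows(extra)
    if (!"lowqual" %in% names(extra)) extra$lowqual <- FALSE
    extra$lowqual[is.na(extra$lowqual)] <- FALSE
    reads <- dplyr::bind_rows(reads, extra)
  }
  reads
}

as_alignment_tibble <- function(reads, config) {
  qual <- ifelse(reads$lowqual %||% FALSE,
                 strrep("#", nchar(reads$seq)),
                 strrep("I", nchar(reads$seq)))
  flag <- reads$flag
  if (config$paired) flag <- flag + 1L + 2L + ifelse(seq_along(flag) %% 2 == 0, 128L, 64L)
  aln <- tibble::tibble(
    read_id = reads$read_id, flag = flag, chrom = reads$chrom,
    pos = reads$pos, mapq = 60L, cigar = reads$cigar,
    seq = reads$seq, qual = qual, nm = as.integer(reads$nm %||% 0L))
  aln$nm[is.na(aln$nm)] <- 0L
  aln <- decode_flags(aln)
  aln$end <- aln$pos + ref_width(aln$cigar)
  dplyr::arrange(aln, .data$chrom, .data$pos, .data$read_id)
}

#' Write an alignment tibble as SAM
#'
#' Coordinate-sorted SAM 1.6 with `@SQ` lines from the genome and the NM
#' tag when present.
#' @param reads Alignment tibble.
#' @param genome `svase_genome`.
#' @param path Output path.
#' @export
write_sam <- function(reads, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), genome_lengths(genome)))
  reads <- dplyr::arrange(reads, .data$chrom, .data$pos, .data$read_id)
  nm <- if (!is.null(reads$nm)) sprintf("\tNM:i:%d", reads$nm) else ""
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
                  reads$read_id, reads$flag, reads$chrom, reads$pos + 1L,
                  reads$mapq, reads$cigar, reads$seq, reads$qual, nm)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Mirror a dataset to the opposite strand
#'
#' Reverse-complements every chromosome and transforms the alignments
#' accordingly (positions flipped, CIGARs reversed, sequences
#' reverse-complemented, qualities reversed). Running the caller on the
#' mirrored dataset must yield the same associations with flipped strands
#' and identical p-values — the strand-involution property.
#'
#' @param reads Alignment tibble.
#' @param genome `svase_genome`.
#' @return List `genome`, `reads`.
#' @export
mirror_alignments <- function(reads, genome) {
  lens <- genome_lengths(genome)
  g2 <- as_genome(stats::setNames(revcomp(unclass(genome)), names(genome)))
  ops <- cigar_ops(reads$cigar)
  rev_cigar <- vapply(ops, function(o) {
    paste0(rev(o$len), rev(o$op), collapse = "")
  }, character(1))
  rev_qual <- vapply(strsplit(reads$qual, NULL), function(q) {
    paste(rev(q), collapse = "")
  }, character(1))
  out <- reads
  out$pos <- lens[reads$chrom] - reads$end
  out$end <- lens[reads$chrom] - reads$pos
  out$cigar <- rev_cigar
  out$seq <- revcomp(reads$seq)
  out$qual <- rev_qual
  out$flag <- bitwXor(reads$flag, 16L)
  out <- decode_flags(out)
  list(genome = g2, reads = dplyr::arrange(out, .data$chrom, .data$pos,
                                           .data$read_id))
}

#' Compare called records against a simulation truth table
#'
#' Match is exact on (chrom, pos, ref, alt, junction key). Precision is
#' matched/emitted (NA when nothing was emitted), recall is
#' matched/expected. When a second run is supplied, per-run replicate
#' consistency (shared records / run total) is also reported.
#'
#' @param records Record tibble from a run.
#' @param truth `truth_variants` tibble from [simulate_splice_reads()].
#' @param records_b Optional record tibble from a replicate run.
#' @return One-row tibble of metrics.
#' @export
evaluate_calls <- function(records, truth, records_b = NULL) {
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, x$junction_id)
  emitted <- key(records)
  expected <- key(truth[truth$expected, , drop = FALSE])
  matched <- intersect(emitted, expected)
  out <- tibble::tibble(
    n_emitted = length(emitted),
    n_expected = length(expected),
    n_matched = length(matched),
    precision = if (length(emitted)) length(matched) / length(emitted) else NA_real_,
    recall = if (length(expected)) length(matched) / length(expected) else NA_real_)
  if (!is.null(records_b)) {
    eb <- key(records_b)
    common <- intersect(emitted, eb)
    out$consistency_a <- if (length(emitted)) length(common) / length(emitted) else NA_real_
    out$consistency_b <- if (length(eb)) length(common) / length(eb) else NA_real_
  }
  out
}
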