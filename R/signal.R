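# Splice-signal scoring.
#
# Window conventions are fixed: the donor model sees a 9-mer (3 exonic +
# 6 intronic bases around the 5'ss) and the acceptor model a 23-mer
# (20 intronic + 3 exonic around the 3'ss), always on the transcribed
# (sense) strand. The scorer is a first-order position weight matrix in
# log2 odds against a uniform background; any scorer honouring these window
# conventions can be slotted in via the `svase_signal_model` contract.

DONOR_LEN <- 9L
ACCEPTOR_LEN <- 23L
BASES <- c("A", "C", "G", "T")

#' Classify the splice-signal dinucleotides and infer strand
#'
#' Reads the first and last two intronic bases of each junction and maps
#' them to a motif class: `GT..AG` is the canonical plus-strand signal
#' (class `GT-AG`, strand `+`), its reverse complement `CT..AC` the
#' canonical minus-strand signal (class `CT-AC`, strand `-`); the minor
#' classes `GC-AG` and `AT-AC` (and their reverse complements, mapped to
#' strand `-`) are recognised likewise. Anything else is `other` with
#' undetermined strand (`.`).
#'
#' @param junctions Junction tibble.
#' @param genome `svase_genome`.
#' @return Junction tibble with `motif_class` and `strand` columns.
#' @export
splice_motif <- function(junctions, genome) {
  n <- nrow(junctions)
  cls <- rep("other", n); strand <- rep(".", n)
  for (i in seq_len(n)) {
    s <- junctions$intron_start[i]; e <- junctions$intron_end[i]
    if (e - s < 4L) next
    d <- genome_seq(genome, junctions$chrom[i], s, s + 2L)
    a <- genome_seq(genome, junctions$chrom[i], e - 2L, e)
    key <- paste0(d, a)
    hit <- switch(key,
      GTAG = c("GT-AG", "+"), CTAC = c("CT-AC", "-"),
      GCAG = c("GC-AG", "+"), CTGC = c("GC-AG", "-"),
      ATAC = c("AT-AC", "+"), GTAT = c("AT-AC", "-"),
      NULL)
    if (!is.null(hit)) { cls[i] <- hit[1]; strand[i] <- hit[2] }
  }
  junctions$motif_class <- cls
  junctions$strand <- strand
  junctions
}

#' Extract donor and acceptor windows for a junction
#'
#' Returns the sense-strand donor 9-mer and acceptor 23-mer. On the minus
#' strand the donor window comes from the intron *end* side of the genome
#' and both windows are reverse-complemented, so the model always sees
#' sense-strand sequence.
#'
#' @param chrom Chromosome name.
#' @param intron_start,intron_end Intron interval, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @param genome `svase_genome`.
#' @return List `donor`, `acceptor` (strings), plus `donor_range` and
#'   `acceptor_range` — the genome (plus-strand) 0-based half-open intervals
#'   each window was read from.
#' @export
extract_site_windows <- function(chrom, intron_start, intron_end, strand, genome) {
  s <- intron_start; e <- intron_end
  if (strand == "+") {
    dr <- c(s - 3L, s + 6L); ar <- c(e - 20L, e + 3L)
  } else if (strand == "-") {
    dr <- c(e - 6L, e + 3L); ar <- c(s - 3L, s + 20L)
  } else {
    stop("strand must be '+' or '-'")
  }
  clen <- genome_lengths(genome)[[chrom]]
  if (dr[1] < 0 || ar[1] < 0 || dr[2] > clen || ar[2] > clen) {
    stop("splice-signal window out of contig bounds for ",
         jkey(chrom, s, e))
  }
  donor <- genome_seq(genome, chrom, dr[1], dr[2])
  acceptor <- genome_seq(genome, chrom, ar[1], ar[2])
  if (strand == "-") {
    donor <- revcomp(donor)
    acceptor <- revcomp(acceptor)
  }
  list(donor = donor, acceptor = acceptor,
       donor_range = dr, acceptor_range = ar)
}

#' Train a position-weight splice-signal model
#'
#' Per-position base frequencies over the donor and acceptor windows of the
#' training junctions (those with a determinable strand, i.e. a canonical
#' or minor motif class), with an additive pseudocount, converted to log2
#' odds against the uniform 0.25 background.
#'
#' @param known Junction tibble (`chrom, intron_start, intron_end`), e.g.
#'   from [load_known_junctions()] or a called junction table.
#' @param genome `svase_genome`.
#' @param pseudocount Additive pseudocount per base (default 0.25).
#' @return A `svase_signal_model`: list with `donor` (9 x 4) and `acceptor`
#'   (23 x 4) log2-odds matrices, `pseudocount`, `n_train`.
#' @export
train_signal_model <- function(known, genome, pseudocount = 0.25) {
  if (is.null(known) || nrow(known) == 0L) stop("empty training set")
  known <- splice_motif(known, genome)
  known <- known[known$strand %in% c("+", "-"), , drop = FALSE]
  if (nrow(known) == 0L) stop("no training junction has a determinable strand")
  dseqs <- character(nrow(known)); aseqs <- character(nrow(known))
  ok <- logical(nrow(known))
  for (i in seq_len(nrow(known))) {
    w <- tryCatch(extract_site_windows(known$chrom[i], known$intron_start[i],
                                       known$intron_end[i], known$strand[i],
                                       genome),
                  error = function(e) NULL)
    if (is.null(w)) next
    dseqs[i] <- w$donor; aseqs[i] <- w$acceptor; ok[i] <- TRUE
  }
  if (!any(ok)) stop("no training junction has in-bounds signal windows")
  model <- list(donor = pwm_from_seqs(dseqs[ok], DONOR_LEN, pseudocount),
                acceptor = pwm_from_seqs(aseqs[ok], ACCEPTOR_LEN, pseudocount),
                pseudocount = pseudocount, n_train = sum(ok))
  structure(model, class = "svase_signal_model")
}

pwm_from_seqs <- function(seqs, width, pseudocount) {
  mat <- matrix(pseudocount, nrow = width, ncol = 4,
                dimnames = list(NULL, BASES))
  for (s in seqs) {
    b <- strsplit(s, NULL)[[1]]
    for (i in seq_len(width)) {
      if (b[i] %in% BASES) mat[i, b[i]] <- mat[i, b[i]] + 1
    }
  }
  probs <- mat / rowSums(mat)
  log2(probs / 0.25)
}

#' Uniform (zero-information) signal model
#'
#' Scores every sequence 0 bits; the fallback when no junctions with
#' canonical motifs are available for training.
#' @return A `svase_signal_model`.
#' @export
uniform_signal_model <- function() {
  structure(list(donor = matrix(0, DONOR_LEN, 4, dimnames = list(NULL, BASES)),
                 acceptor = matrix(0, ACCEPTOR_LEN, 4,
                                   dimnames = list(NULL, BASES)),
                 pseudocount = NA_real_, n_train = 0L),
            class = "svase_signal_model")
}

#' Score a sequence under a position-weight model
#'
#' Additive log2-odds: the score is the sum of per-position entries, so a
#' single substitution changes the score by exactly the per-position
#' difference. Positions with N score 0.
#'
#' @param model `svase_signal_model`.
#' @param seq Sequence string (length 9 for `site = "donor"`, 23 for
#'   `"acceptor"`).
#' @param site `"donor"` or `"acceptor"`.
#' @return Score in bits.
#' @export
score_sequence <- function(model, seq, site = c("donor", "acceptor")) {
  site <- match.arg(site)
  mat <- model[[site]]
  b <- strsplit(seq, NULL)[[1]]
  if (length(b) != nrow(mat)) {
    stop(site, " window must have length ", nrow(mat))
  }
  sum(vapply(seq_along(b), function(i) {
    if (b[i] %in% BASES) mat[i, b[i]] else 0
  }, numeric(1)))
}

#' Annotate records with splice-signal scores, reference vs variant
#'
#' Scores each record's junction donor and acceptor windows on the
#' reference sequence; when the variant position falls inside a window, the
#' window is re-scored with the ALT base substituted (strand-aware:
#' substitution happens in genome coordinates before any reverse
#' complementing), otherwise the alt score equals the ref score. Junctions
#' with an undetermined strand (`other` motif) are scored on both
#' orientations, the better-scoring one is reported and flagged
#' low-confidence.
#'
#' @param records Record tibble (needs `chrom, pos, ref, alt, intron_start,
#'   intron_end`).
#' @param junctions Junction tibble with `motif_class`/`strand` (computed
#'   here if absent).
#' @param model `svase_signal_model`.
#' @param genome `svase_genome`.
#' @return Records with `motif_class, strand, strand_confident, donor_ref,
#'   donor_alt, acceptor_ref, acceptor_alt` columns.
#' @export
score_signal <- function(records, junctions, model, genome) {
  if (is.null(junctions$strand)) junctions <- splice_motif(junctions, genome)
  j <- match(records$junction_id, junctions$junction_id)
  n <- nrow(records)
  records$motif_class <- junctions$motif_class[j]
  records$strand <- junctions$strand[j]
  records$strand_confident <- records$strand %in% c("+", "-")
  for (col in c("donor_ref", "donor_alt", "acceptor_ref", "acceptor_alt")) {
    records[[col]] <- rep(NA_real_, n)
  }
  for (i in seq_len(n)) {
    strands <- if (records$strand_confident[i]) records$strand[i] else c("+", "-")
    best <- NULL
    for (st in strands) {
      sc <- tryCatch(
        score_one_signal(records[i, ], model, genome, st),
        error = function(e) NULL)
      if (is.null(sc)) next
      if (is.null(best) || sc$total_ref > best$total_ref) {
        best <- sc
        best$strand <- st
      }
    }
    if (is.null(best)) next
    records$donor_ref[i] <- best$donor_ref
    records$donor_alt[i] <- best$donor_alt
    records$acceptor_ref[i] <- best$acceptor_ref
    records$acceptor_alt[i] <- best$acceptor_alt
    if (!records$strand_confident[i]) records$strand[i] <- best$strand
  }
  records
}

score_one_signal <- function(rec, model, genome, strand) {
  w <- extract_site_windows(rec$chrom, rec$intron_start, rec$intron_end,
                            strand, genome)
  res <- list(donor_ref = score_sequence(model, w$donor, "donor"),
              acceptor_ref = score_sequence(model, w$acceptor, "acceptor"))
  res$donor_alt <- res$donor_ref
  res$acceptor_alt <- res$acceptor_ref
  for (site in c("donor", "acceptor")) {
    rng <- w[[paste0(site, "_range")]]
    if (rec$pos >= rng[1] && rec$pos < rng[2]) {
      gwin <- genome_seq(genome, rec$chrom, rng[1], rng[2])
      off <- rec$pos - rng[1] + 1L
      substr(gwin, off, off) <- rec$alt
      if (strand == "-") gwin <- revcomp(gwin)
      res[[paste0(site, "_alt")]] <- score_sequence(model, gwin, site)
    }
  }
  res$total_ref <- res$donor_ref + res$acceptor_ref
  res
}

#' Persist / restore a signal model as plain text
#'
#' Layout: a header line `# svase signal model pseudocount=<p> n_train=<n>`,
#' then one line per matrix row as `<site> <index> <A> <C> <G> <T>`.
#' @param model `svase_signal_model`.
#' @param path File path.
#' @export
write_signal_model <- function(model, path) {
  lines <- sprintf("# svase signal model pseudocount=%s n_train=%d",
                   format(model$pseudocount), model$n_train)
  for (site in c("donor", "acceptor")) {
    m <- model[[site]]
    lines <- c(lines, sprintf("%s\t%d\t%.10g\t%.10g\t%.10g\t%.10g",
                              site, seq_len(nrow(m)),
                              m[, 1], m[, 2], m[, 3], m[, 4]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_signal_model
#' @export
read_signal_model <- function(path) {
  lines <- readLines(path)
  hdr <- stringr::str_match(lines[1],
    "pseudocount=([^ ]+) n_train=(\\d+)")
  body <- utils::read.table(text = lines[-1], sep = "\t",
                            col.names = c("site", "idx", BASES))
  mk <- function(site, width) {
    m <- as.matrix(body[body$site == site, BASES])
    dimnames(m) <- list(NULL, BASES)
    stopifnot(nrow(m) == width)
    m
  }
  structure(list(donor = mk("donor", DONOR_LEN),
                 acceptor = mk("acceptor", ACCEPTOR_LEN),
                 pseudocount = suppressWarnings(as.numeric(hdr[2])),
                 n_train = as.integer(hdr[3])),
            class = "svase_signal_model")
}
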