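# Independent oracle for Fisher's exact test: exhaustive enumeration over
# all 2x2 tables with the observed margins, using only lchoose() arithmetic.
# Deliberately shares no code with fisher_exact_p().
enum_fisher <- function(a, b, c, d, alternative = "greater") {
  m <- a + b; n <- c + d; K <- a + c
  ks <- max(0, K - n):min(K, m)
  logp <- lchoose(m, ks) + lchoose(n, K - ks) - lchoose(m + n, K)
  probs <- exp(logp)
  obs <- probs[ks == a]
  switch(alternative,
         greater = sum(probs[ks >= a]),
         less = sum(probs[ks <= a]),
         two.sided = sum(probs[probs <= obs * (1 + 1e-07)]))
}

# minimal hand-built alignment row in read_alignments() layout
make_read <- function(read_id = "r1", chrom = "chr1", pos = 0L, cigar = "50M",
                      seq = NULL, qual = NULL, flag = 0L, mapq = 60L,
                      nm = 0L) {
  qlen <- sum(as.integer(
    stringr::str_match_all(cigar, "(\\d+)([MIS=X])")[[1]][, 2]))
  if (is.null(seq)) seq <- strrep("A", qlen)
  if (is.null(qual)) qual <- strrep("I", qlen)
  r <- tibble::tibble(read_id = read_id, flag = flag, chrom = chrom,
                      pos = as.integer(pos), mapq = mapq, cigar = cigar,
                      seq = seq, qual = qual, nm = as.integer(nm))
  r <- svase:::decode_flags(r)
  r$end <- r$pos + svase:::ref_width(r$cigar)
  r
}

make_reads <- function(...) dplyr::bind_rows(...)

# uniform-random genome with fixed seed, as a svase_genome
make_genome <- function(len = 1000, seed = 42, name = "chr1") {
  withr::with_seed(seed, {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
  })
  svase:::as_genome(stats::setNames(s, name))
}

# reads supporting one junction: `depth` split reads with fixed anchors,
# all sequences copied from the genome (so zero mismatches)
junction_reads <- function(genome, chrom = "chr1", s, e, depth = 5,
                           la = 15L, ra = 15L, prefix = "jr") {
  gseq <- unclass(genome)[[chrom]]
  seq <- paste0(substr(gseq, s - la + 1L, s), substr(gseq, e + 1L, e + ra))
  make_reads(!!!lapply(seq_len(depth), function(i) {
    make_read(sprintf("%s%03d", prefix, i), chrom, s - la,
              sprintf("%dM%dN%dM", la, e - s, ra), seq = seq)
  }))
}

# substitute the base a read carries at reference position `pos` (the read
# must align that position through an M block)
with_alt <- function(reads, rows, pos, alt) {
  ops <- svase:::cigar_ops(reads$cigar)
  for (k in rows) {
    qi <- svase:::query_index_at(ops[[k]], reads$pos[k], pos)
    stopifnot(!is.na(qi))
    substr(reads$seq[k], qi, qi) <- alt
    reads$nm[k] <- reads$nm[k] + 1L
  }
  reads
}
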