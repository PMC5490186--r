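test_that("load_genome reads, uppercases and validates FASTA", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 description text", "acgt", ">chr2", "NNAA"), fa)
  g <- load_genome(fa)
  expect_equal(unclass(g)[["chr1"]], "ACGT")
  expect_equal(genome_lengths(g), c(chr1 = 4L, chr2 = 4L))
  expect_equal(genome_seq(g, "chr2", 0, 2), "NN")
  expect_error(genome_seq(g, "chr1", 2, 5), "out of bounds")

  writeLines(c(">dup", "AAAA", ">dup", "CCCC"), fa)
  expect_error(load_genome(fa), "duplicate")
  writeLines(character(0), fa)
  expect_error(load_genome(fa))
  expect_error(load_genome(file.path(tempdir(), "nope.fa")), "not found")
})

test_that("SAM and BAM encodings of the same records load identically", {
  g <- make_genome(500)
  reads <- make_reads(
    make_read("a", pos = 10L, cigar = "20M100N30M",
              seq = strrep("C", 50), nm = 2L),
    make_read("b", pos = 40L, cigar = "50M", flag = 16L))
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(reads, g, sam)

  from_sam <- read_alignments(sam, g)
  expect_equal(nrow(from_sam), 2L)
  a <- from_sam[from_sam$read_id == "a", ]
  expect_equal(a$pos, 10L)            # POS converted back to 0-based
  expect_equal(a$cigar, "20M100N30M") # three CIGAR segments survive
  expect_equal(a$nm, 2L)
  expect_equal(a$end, 10L + 150L)
  expect_true(from_sam$reverse[from_sam$read_id == "b"])

  bam <- Rsamtools::asBam(sam, withr::local_tempfile(),
                          indexDestination = FALSE)
  from_bam <- read_alignments(bam, g)
  cols <- c("read_id", "flag", "chrom", "pos", "cigar", "seq", "qual", "nm")
  expect_equal(dplyr::arrange(from_sam[cols], read_id),
               dplyr::arrange(from_bam[cols], read_id))
})

test_that("alignments referencing a contig absent from the genome error", {
  g <- make_genome(500)
  reads <- make_read("a", chrom = "chrX", pos = 10L, cigar = "30M")
  sam <- withr::local_tempfile(fileext = ".sam")
  # hand-written header so the SAM itself declares chrX
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chrX\tLN:500",
               sprintf("a\t0\tchrX\t11\t60\t30M\t*\t0\t0\t%s\t%s",
                       strrep("A", 30), strrep("I", 30))), sam)
  expect_error(read_alignments(sam, g), "chrX")
})

test_that("introns derive correctly from GTF exon structure", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  attr1 <- 'gene_id "g1"; transcript_id "t1";'
  writeLines(c(
    paste("chr1", "src", "exon", 1, 100, ".", "+", ".", attr1, sep = "\t"),
    paste("chr1", "src", "exon", 201, 300, ".", "+", ".", attr1, sep = "\t"),
    # single-exon transcript contributes no intron
    paste("chr1", "src", "exon", 400, 500, ".", "+", ".",
          'gene_id "g2"; transcript_id "t2";', sep = "\t")), gtf)
  kj <- load_known_junctions(gtf)
  expect_equal(nrow(kj), 1L)
  expect_equal(kj$intron_start, 100L)  # 1-based exon end 100 -> 0-based start
  expect_equal(kj$intron_end, 200L)    # next exon start 201 -> exclusive end
  expect_equal(kj$strand, "+")
})

test_that("introns derive from BED12 blocks and plain BED intervals", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste("chr1", 0, 300, "tx1", 0, "+", 0, 300, "0", 2,
                   "100,100", "0,200", sep = "\t"), bed)
  kj <- load_known_junctions(bed)
  expect_equal(kj$intron_start, 100L)
  expect_equal(kj$intron_end, 200L)

  writeLines(paste("chr1", 119, 219, "intron1", 5, "+", sep = "\t"), bed)
  kj2 <- load_known_junctions(bed)
  expect_equal(kj2$intron_start, 119L)
  expect_equal(kj2$intron_end, 219L)
})

test_that("known sites load 0-based from VCF with multi-allelic expansion and SNV-only filter", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t101\t.\tA\tG\t.\t.\t.",
               "chr1\t150\t.\tA\tG,T\t.\t.\t.",
               "chr1\t200\t.\tA\tAT\t.\t.\t."), vcf)
  sites <- suppressMessages(load_known_sites(vcf, label = "RNA editing"))
  expect_equal(nrow(sites), 3L)                    # indel skipped
  expect_equal(attr(sites, "n_skipped"), 1L)
  expect_equal(sites$pos[sites$alt == "G" & sites$pos == 100], 100L)
  expect_setequal(sites$alt[sites$pos == 149], c("G", "T"))
  expect_equal(attr(sites, "label"), "RNA editing")

  # tabular re-export loads to an identical index
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sprintf("%s\t%d\t%s\t%s", sites$chrom, sites$pos + 1L,
                     sites$ref, sites$alt), tsv)
  sites2 <- load_known_sites(tsv)
  for (col in c("chrom", "pos", "ref", "alt")) {
    expect_equal(sites[[col]], sites2[[col]])
  }
})

test_that("records VCF round-trips with 1-based POS and genome-checked REF", {
  g <- make_genome(400)
  rec <- tibble::tibble(
    chrom = "chr1", pos = 100L,
    ref = genome_seq(g, "chr1", 100, 101),
    alt = setdiff(c("A", "C", "G", "T"), genome_seq(g, "chr1", 100, 101))[1],
    junction_id = "chr1:119-219", side = "left", depth = 10L, alt_count = 5L,
    alt_fraction = 0.5, p_variant = 0.01, intron_start = 119L,
    intron_end = 219L, background_p = 0, p_association = 0.002,
    no_contrast = FALSE, used_universe = "target-only", status = "novel",
    shift_of = NA_character_, shift_offset = NA_integer_,
    motif_class = "GT-AG", strand = "+", source_type = "novel")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(rec, g, vcf)
  lines <- readLines(vcf)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(as.integer(strsplit(body, "\t")[[1]][2]), 101L) # POS shift
  # every INFO key used is defined in the header
  used <- unique(sub("=.*$", "", strsplit(strsplit(body, "\t")[[1]][8], ";")[[1]]))
  defined <- stringr::str_match(lines[grepl("^##INFO", lines)],
                                "ID=([A-Z]+)")[, 2]
  expect_true(all(used %in% defined))

  back <- read_svase_vcf(vcf)
  expect_equal(back$pos, rec$pos)
  expect_equal(back$ref, rec$ref)
  expect_equal(back$junction_id, rec$junction_id)
  expect_equal(back$p_association, rec$p_association, tolerance = 1e-6)

  # empty record set still produces a parseable header-only VCF
  write_vcf(rec[0, ], g, vcf)
  expect_equal(nrow(read_svase_vcf(vcf)), 0L)

  # REF disagreeing with the genome is an error
  bad <- rec; bad$ref <- setdiff(c("A", "C", "G", "T"),
                                 c(rec$ref, rec$alt))[1]
  expect_error(write_vcf(bad, g, vcf), "disagrees with genome")
})

test_that("junction BED round-trips the coordinate convention losslessly", {
  jt <- tibble::tibble(junction_id = c("chr1:119-219", "chr1:400-600"),
                       chrom = "chr1", intron_start = c(119L, 400L),
                       intron_end = c(219L, 600L), depth = c(12L, 3L),
                       strand = c("+", "-"))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_junction_bed(jt, bed)
  back <- read_junction_bed(bed)
  expect_equal(back[, names(jt)], jt)
})

test_that("flank FASTA carries ref and alt windows with edge truncation", {
  g <- make_genome(10000)
  ref100 <- genome_seq(g, "chr1", 100, 101)
  alt100 <- setdiff(c("A", "C", "G", "T"), ref100)[1]
  ref3 <- genome_seq(g, "chr1", 3, 4)
  rec <- tibble::tibble(chrom = "chr1", pos = c(100L, 3L),
                        ref = c(ref100, ref3),
                        alt = c(alt100, setdiff(c("A", "C", "G", "T"), ref3)[1]))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_flank_fasta(rec, g, 50, fa)
  out <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(out), 4L)
  expect_equal(unname(Biostrings::width(out)[1:2]), c(101L, 101L))
  # centre base differs between the two versions and alt centre equals ALT
  expect_equal(substr(as.character(out[[1]]), 51, 51), ref100)
  expect_equal(substr(as.character(out[[2]]), 51, 51), alt100)
  # window at pos 3 is left-truncated to the contig start
  expect_equal(unname(Biostrings::width(out)[3]), 3L + 51L)
  expect_equal(as.character(out[[3]]), genome_seq(g, "chr1", 0, 54))
})
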