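# External-format boundary. Internal coordinates are 0-based half-open
# everywhere; conversion to/from the 1-based conventions of GTF/GFF/VCF and
# the 0-based convention of BED happens only in this file.

#' Load known splicing events (introns) from GTF, GFF or BED
#'
#' For GTF/GFF, introns are derived from consecutive exons of each
#' transcript (grouped by `transcript_attr`, falling back to `Parent` for
#' GFF3; exons are sorted within transcript, so unsorted input is fine).
#' For BED, BED12 block structure yields the inter-block introns; simple
#' BED intervals are taken to be intron intervals directly. Duplicates are
#' collapsed.
#'
#' @param path Annotation file.
#' @param format `"gtf"`, `"gff"`, `"bed"`, or `"auto"` (by extension).
#' @param transcript_attr GTF/GFF attribute that groups exons into
#'   transcripts (default `"transcript_id"`; other dialects may need an
#'   override).
#' @return Tibble `chrom, intron_start, intron_end, strand` (0-based
#'   half-open introns).
#' @export
load_known_junctions <- function(path, format = c("auto", "gtf", "gff", "bed"),
                                 transcript_attr = "transcript_id") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gtf = "gtf", gff = "gff", gff3 = "gff", bed = "bed",
                     stop("cannot guess annotation format from extension: ", ext))
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    return(introns_from_bed(gr))
  }
  gr <- rtracklayer::import(path, format = format)
  introns_from_exons(gr, transcript_attr)
}

introns_from_bed <- function(gr) {
  out <- list()
  blocks <- if ("blocks" %in% names(S4Vectors::mcols(gr))) {
    S4Vectors::mcols(gr)$blocks
  } else NULL
  for (i in seq_along(gr)) {
    chrom <- as.character(GenomicRanges::seqnames(gr)[i])
    strand <- as.character(GenomicRanges::strand(gr)[i])
    if (strand == "*") strand <- "."
    off <- GenomicRanges::start(gr)[i] - 1L # chromStart, 0-based
    bl <- if (!is.null(blocks)) blocks[[i]] else NULL
    if (!is.null(bl) && length(bl) >= 2L) {
      for (b in seq_len(length(bl) - 1L)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          chrom = chrom,
          intron_start = off + S4Vectors::end(bl)[b],
          intron_end = off + S4Vectors::start(bl)[b + 1L] - 1L,
          strand = strand)
      }
    } else if (is.null(bl) || length(bl) <= 1L) {
      if (!is.null(bl) && length(bl) == 1L) next # single-block record: no intron
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = chrom, intron_start = off,
        intron_end = GenomicRanges::end(gr)[i], strand = strand)
    }
  }
  dplyr::distinct(dplyr::bind_rows(
    c(out, list(empty_junction_tbl()))))
}

introns_from_exons <- function(gr, transcript_attr) {
  mc <- S4Vectors::mcols(gr)
  ex <- gr[!is.na(mc$type) & tolower(as.character(mc$type)) == "exon"]
  if (length(ex) == 0L) return(empty_junction_tbl())
  mc <- S4Vectors::mcols(ex)
  tx <- if (transcript_attr %in% names(mc)) {
    mc[[transcript_attr]]
  } else if ("Parent" %in% names(mc)) {
    vapply(as.list(mc$Parent), function(p) paste(p, collapse = ","), character(1))
  } else {
    stop("no '", transcript_attr, "' or 'Parent' attribute groups exons")
  }
  tb <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex), end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)), tx = as.character(tx))
  tb$strand[tb$strand == "*"] <- "."
  tb |>
    dplyr::arrange(.data$tx, .data$start) |>
    dplyr::group_by(.data$tx) |>
    dplyr::reframe(chrom = .data$chrom[-dplyr::n()],
                   intron_start = .data$end[-dplyr::n()],        # 1-based end == 0-based intron start
                   intron_end = .data$start[-1] - 1L,            # next exon start-1 == 0-based exclusive end
                   strand = .data$strand[-dplyr::n()]) |>
    dplyr::select("chrom", "intron_start", "intron_end", "strand") |>
    dplyr::distinct() |>
    dplyr::arrange(.data$chrom, .data$intron_start, .data$intron_end)
}

empty_junction_tbl <- function() {
  tibble::tibble(chrom = character(0), intron_start = integer(0),
                 intron_end = integer(0), strand = character(0))
}

#' Load known variant sites (VCF or tabular)
#'
#' Accepts a VCF (positions 1-based; multi-allelic rows expanded to one
#' (ref, alt) pair each) or a tab-separated table with columns
#' chrom/pos/ref/alt or chrom/pos/alleles (`REF>ALT` or `REF/ALT`), also
#' 1-based. Non-SNV rows are skipped; the skip count is reported via a
#' message and the `n_skipped` attribute.
#'
#' @param path Site list file.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by extension).
#' @param label Free-text source label (e.g. `"DNA mutation"`,
#'   `"RNA editing"`), stored as the `label` attribute.
#' @return Tibble `chrom, pos, ref, alt` with 0-based positions.
#' @export
load_known_sites <- function(path, format = c("auto", "vcf", "tsv"),
                             label = "") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    fix <- vcfR::read.vcfR(path, verbose = FALSE)@fix
    raw <- tibble::tibble(chrom = fix[, "CHROM"],
                          pos1 = suppressWarnings(as.integer(fix[, "POS"])),
                          ref = fix[, "REF"], alt = fix[, "ALT"])
  } else {
    raw <- utils::read.table(path, sep = "\t", header = FALSE,
                             comment.char = "#", colClasses = "character")
    if (ncol(raw) == 3L) {
      al <- stringr::str_split_fixed(raw[[3]], "[>/|]", 2)
      raw <- tibble::tibble(chrom = raw[[1]],
                            pos1 = suppressWarnings(as.integer(raw[[2]])),
                            ref = al[, 1], alt = al[, 2])
    } else if (ncol(raw) >= 4L) {
      raw <- tibble::tibble(chrom = raw[[1]],
                            pos1 = suppressWarnings(as.integer(raw[[2]])),
                            ref = raw[[3]], alt = raw[[4]])
    } else {
      stop("site table needs 3 or 4 columns (chrom, pos, [ref, alt | alleles])")
    }
  }
  n_in <- nrow(raw)
  raw <- tidyr::separate_rows(raw, "alt", sep = ",")
  raw$ref <- toupper(raw$ref); raw$alt <- toupper(raw$alt)
  ok <- !is.na(raw$pos1) & raw$ref %in% c("A", "C", "G", "T") &
    raw$alt %in% c("A", "C", "G", "T") & raw$ref != raw$alt
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    message("load_known_sites: skipped ", n_skipped,
            " non-SNV or malformed entries")
  }
  out <- tibble::tibble(chrom = raw$chrom[ok], pos = raw$pos1[ok] - 1L,
                        ref = raw$ref[ok], alt = raw$alt[ok]) |>
    dplyr::distinct()
  attr(out, "label") <- label
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_input") <- n_in
  out
}

# INFO keys written to the VCF, with their header definitions
vcf_info_defs <- c(
  JID = '##INFO=<ID=JID,Number=1,Type=String,Description="Junction key chrom:intron_start-intron_end (0-based half-open)">',
  JSTART = '##INFO=<ID=JSTART,Number=1,Type=Integer,Description="Intron start (0-based)">',
  JEND = '##INFO=<ID=JEND,Number=1,Type=Integer,Description="Intron end (0-based, exclusive)">',
  SIDE = '##INFO=<ID=SIDE,Number=1,Type=String,Description="Junction part carrying the variant (left=5p splice site side, right=3p side)">',
  DP = '##INFO=<ID=DP,Number=1,Type=Integer,Description="Unmasked read depth at site within the junction part">',
  ALTC = '##INFO=<ID=ALTC,Number=1,Type=Integer,Description="ALT supporting reads">',
  AF = '##INFO=<ID=AF,Number=1,Type=Float,Description="ALT fraction">',
  PVAR = '##INFO=<ID=PVAR,Number=1,Type=Float,Description="Variant significance p (Fisher exact vs error expectation)">',
  PJUN = '##INFO=<ID=PJUN,Number=1,Type=Float,Description="Junction background-expression p (0 = no competing junction)">',
  PASSOC = '##INFO=<ID=PASSOC,Number=1,Type=Float,Description="Variant-junction association p (0 = junction-private, no contrast)">',
  NOC = '##INFO=<ID=NOC,Number=0,Type=Flag,Description="No-contrast: all covering reads support the junction">',
  UNIV = '##INFO=<ID=UNIV,Number=1,Type=String,Description="Association read universe (target-only or related-total)">',
  JSTATUS = '##INFO=<ID=JSTATUS,Number=1,Type=String,Description="Junction status: known, novel or shift">',
  SHIFTOF = '##INFO=<ID=SHIFTOF,Number=1,Type=String,Description="Known junction this novel junction is a shift of">',
  SHIFT = '##INFO=<ID=SHIFT,Number=1,Type=Integer,Description="Shift offset in bp (novel minus known)">',
  SIG = '##INFO=<ID=SIG,Number=1,Type=String,Description="Splice motif class (GT-AG, CT-AC, GC-AG, AT-AC, other)">',
  STRAND = '##INFO=<ID=STRAND,Number=1,Type=String,Description="Inferred transcribed strand">',
  SRC = '##INFO=<ID=SRC,Number=1,Type=String,Description="Source type from known-site lists">')

#' Write validated records as VCF 4.2
#'
#' POS is 1-based; every record's REF is checked against the genome and a
#' disagreement is an error. INFO carries the junction key and coordinates,
#' junction side, depth/ALT counts and fraction, the three p-values, motif
#' class, strand, shift and source-type annotation; every key is defined in
#' the header.
#'
#' @param records Record tibble.
#' @param genome `svase_genome`.
#' @param path Output path.
#' @export
write_vcf <- function(records, genome, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=svase",
           sprintf("##contig=<ID=%s,length=%d>", names(genome),
                   genome_lengths(genome)),
           unname(vcf_info_defs),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO"), collapse = "\t"))
  lines <- hdr
  if (nrow(records)) {
    gref <- vapply(seq_len(nrow(records)), function(i) {
      genome_base(genome, records$chrom[i], records$pos[i])
    }, character(1))
    bad <- which(gref != records$ref)
    if (length(bad)) {
      stop("REF allele disagrees with genome at ",
           paste(jkey(records$chrom[bad], records$pos[bad],
                      records$pos[bad] + 1L), collapse = ", "))
    }
    fmt_p <- function(p) sub("e([+-])0(\\d)$", "e\\1\\2", sprintf("%.6g", p))
    info <- vapply(seq_len(nrow(records)), function(i) {
      r <- records[i, ]
      parts <- c(
        sprintf("JID=%s", r$junction_id),
        sprintf("JSTART=%d", r$intron_start),
        sprintf("JEND=%d", r$intron_end),
        sprintf("SIDE=%s", r$side),
        sprintf("DP=%d", r$depth),
        sprintf("ALTC=%d", r$alt_count),
        sprintf("AF=%s", fmt_p(r$alt_fraction)),
        sprintf("PVAR=%s", fmt_p(r$p_variant)),
        sprintf("PJUN=%s", fmt_p(r$background_p)),
        sprintf("PASSOC=%s", fmt_p(r$p_association)),
        if (isTRUE(r$no_contrast)) "NOC",
        sprintf("UNIV=%s", r$used_universe),
        sprintf("JSTATUS=%s", r$status),
        if (!is.na(r$shift_of %||% NA)) sprintf("SHIFTOF=%s", r$shift_of),
        if (!is.na(r$shift_offset %||% NA)) sprintf("SHIFT=%d", r$shift_offset),
        sprintf("SIG=%s", r$motif_class %||% "other"),
        sprintf("STRAND=%s", r$strand %||% "."),
        sprintf("SRC=%s", r$source_type %||% "novel"))
      paste(parts[!vapply(parts, is.null, logical(1))], collapse = ";")
    }, character(1))
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                              records$chrom, records$pos + 1L,
                              records$ref, records$alt, info))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Re-load a records VCF written by [write_vcf()]
#'
#' @param path VCF file.
#' @return Tibble with the core record columns (0-based positions restored).
#' @export
read_svase_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    return(tibble::tibble(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          junction_id = character(0)))
  }
  getinfo <- function(key) {
    m <- stringr::str_match(fix[, "INFO"], paste0("(?:^|;)", key, "=([^;]+)"))
    m[, 2]
  }
  fix <- apply(fix, 2, unname)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  tibble::tibble(
    chrom = unname(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]) - 1L,
    ref = unname(fix[, "REF"]), alt = unname(fix[, "ALT"]),
    junction_id = getinfo("JID"),
    intron_start = as.integer(getinfo("JSTART")),
    intron_end = as.integer(getinfo("JEND")),
    side = getinfo("SIDE"),
    depth = as.integer(getinfo("DP")),
    alt_count = as.integer(getinfo("ALTC")),
    alt_fraction = as.numeric(getinfo("AF")),
    p_variant = as.numeric(getinfo("PVAR")),
    background_p = as.numeric(getinfo("PJUN")),
    p_association = as.numeric(getinfo("PASSOC")),
    status = getinfo("JSTATUS"),
    source_type = getinfo("SRC"))
}

#' Write/read the junction table as BED
#'
#' Intron intervals (BED's native 0-based half-open convention, so the
#' round trip is lossless), junction key as name, depth as score, inferred
#' strand when available.
#'
#' @param junctions Junction tibble.
#' @param path Output path.
#' @export
write_junction_bed <- function(junctions, path) {
  strand <- junctions$strand %||% rep(".", nrow(junctions))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   junctions$chrom, junctions$intron_start,
                   junctions$intron_end, junctions$junction_id,
                   junctions$depth, strand)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_junction_bed
#' @export
read_junction_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble::tibble(
    junction_id = S4Vectors::mcols(gr)$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    intron_start = GenomicRanges::start(gr) - 1L,
    intron_end = GenomicRanges::end(gr),
    depth = as.integer(S4Vectors::mcols(gr)$score),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))))
}

#' Write flanking sequences for each record as FASTA
#'
#' Two records per variant: the reference-allele and the alternative-allele
#' version of the window `[pos - flank_bp, pos + flank_bp]`, truncated at
#' contig edges. IDs encode chrom, 1-based position, REF, ALT and the
#' allele version, e.g. `chr1_101_G_A_ref`.
#'
#' @param records Record tibble.
#' @param genome `svase_genome`.
#' @param flank_bp Flank size in bp (default 50).
#' @param path Output path.
#' @export
write_flank_fasta <- function(records, genome, flank_bp = 50, path) {
  stopifnot(flank_bp >= 1)
  seqs <- character(0)
  lens <- genome_lengths(genome)
  for (i in seq_len(nrow(records))) {
    chrom <- records$chrom[i]; pos <- records$pos[i]
    lo <- max(0L, pos - as.integer(flank_bp))
    hi <- min(lens[[chrom]], pos + as.integer(flank_bp) + 1L)
    refseq <- genome_seq(genome, chrom, lo, hi)
    altseq <- refseq
    substr(altseq, pos - lo + 1L, pos - lo + 1L) <- records$alt[i]
    id <- sprintf("%s_%d_%s_%s", chrom, pos + 1L, records$ref[i], records$alt[i])
    seqs[paste0(id, "_ref")] <- refseq
    seqs[paste0(id, "_alt")] <- altseq
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write the main results table as TSV
#'
#' One row per validated record with all counts and p-values; list-columns
#' are dropped.
#' @param records Record tibble.
#' @param path Output path.
#' @export
write_results_tsv <- function(records, path) {
  flat <- records[, !vapply(records, is.list, logical(1)), drop = FALSE]
  readr::write_tsv(flat, path)
  invisible(path)
}
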