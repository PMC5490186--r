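test_that("CIGAR walk yields intron intervals with correct anchors", {
  r <- make_read("a", pos = 99L, cigar = "20M100N30M")
  obs <- junction_observations(r, min_anchor = 1)
  expect_equal(obs$intron_start, 119L)  # 20 aligned bases cover 99..118
  expect_equal(obs$intron_end, 219L)
  expect_equal(obs$left_anchor, 20L)
  expect_equal(obs$right_anchor, 30L)
  expect_equal(obs$left_ref_start, 99L)
  expect_equal(obs$left_qstart, 0L)
  expect_equal(obs$right_qstart, 20L)

  # anchor rule: both parts need min_anchor aligned bases
  expect_equal(nrow(junction_observations(r, min_anchor = 8)), 1L)
  r2 <- make_read("b", pos = 99L, cigar = "5M100N45M")
  expect_equal(nrow(junction_observations(r2, min_anchor = 8)), 0L)
})

test_that("multi-intron reads share the inter-intron block as anchor", {
  r <- make_read("m", pos = 0L, cigar = "15M50N10M60N20M")
  obs <- junction_observations(r, min_anchor = 1)
  expect_equal(nrow(obs), 2L)
  expect_equal(obs$intron_start, c(15L, 75L))
  expect_equal(obs$intron_end, c(65L, 135L))
  expect_equal(obs$right_anchor[1], 10L)  # middle block, right anchor of intron 1
  expect_equal(obs$left_anchor[2], 10L)   # same block, left anchor of intron 2
  expect_equal(obs$left_qstart[2], 15L)

  # soft clips shift query offsets but not reference geometry
  rs <- make_read("sc", pos = 99L, cigar = "5S20M100N30M")
  osc <- junction_observations(rs, min_anchor = 8)
  expect_equal(osc$intron_start, 119L)
  expect_equal(osc$left_qstart, 5L)
})

test_that("a CIGAR whose gap lacks a flanking aligned block is malformed", {
  bad <- make_read("bad", pos = 0L, cigar = "100N30M")
  expect_error(junction_observations(bad, 1), "malformed")
  bad2 <- make_read("bad2", pos = 0L, cigar = "30M100N")
  expect_error(junction_observations(bad2, 1), "malformed")
})

test_that("aggregation counts distinct reads and applies the depth filter", {
  g <- make_genome(1000)
  obs <- junction_observations(dplyr::bind_rows(
    junction_reads(g, s = 200, e = 400, depth = 5, prefix = "a"),
    junction_reads(g, s = 500, e = 700, depth = 2, prefix = "b")), 8)
  jt <- aggregate_junctions(obs, junction_params())
  expect_equal(nrow(jt), 1L)          # depth-2 junction discarded
  expect_equal(jt$depth, 5L)
  expect_equal(jt$junction_id, "chr1:200-400")

  # one read observing the same intron twice still counts once
  dup_obs <- dplyr::bind_rows(obs[obs$read_id == "a001", ],
                              obs[obs$read_id == "a001", ])
  jd <- aggregate_junctions(dup_obs, junction_params(min_junction_depth = 1))
  expect_equal(jd$depth, 1L)
})

test_that("related sets collect junctions sharing either boundary", {
  jt <- tibble::tibble(
    junction_id = c("chr1:100-300", "chr1:150-300", "chr1:200-300",
                    "chr1:100-500", "chr1:700-900"),
    chrom = "chr1",
    intron_start = c(100L, 150L, 200L, 100L, 700L),
    intron_end = c(300L, 300L, 300L, 500L, 900L),
    depth = 5L)
  jt <- related_junctions(jt)
  i <- match("chr1:100-300", jt$junction_id)
  # three junctions share the acceptor: the other two are end-related
  expect_setequal(jt$related_end[[i]], c("chr1:150-300", "chr1:200-300"))
  # one junction shares the donor
  expect_setequal(jt$related_start[[i]], "chr1:100-500")
  # the unique junction has empty related sets
  u <- match("chr1:700-900", jt$junction_id)
  expect_length(jt$related_start[[u]], 0)
  expect_length(jt$related_end[[u]], 0)
})

test_that("background test matches the enumeration oracle and keeps lone junctions at p = 0", {
  params <- junction_params()
  lone <- related_junctions(tibble::tibble(
    junction_id = "chr1:10-20", chrom = "chr1", intron_start = 10L,
    intron_end = 20L, depth = 3L))
  kept <- filter_background(lone, params)
  expect_equal(kept$background_p, 0)

  # two junctions sharing an acceptor: [[10, 0], [b, N-b]] construction
  pair <- related_junctions(tibble::tibble(
    junction_id = c("chr1:100-300", "chr1:150-300"), chrom = "chr1",
    intron_start = c(100L, 150L), intron_end = c(300L, 300L),
    depth = c(10L, 10L)))
  kept2 <- filter_background(pair, params)
  # N = 20, b = ceiling(0.01 * 20) = 1: oracle value for [[10,10],[1,19]]
  expect_equal(kept2$background_p[1], enum_fisher(10, 10, 1, 19, "greater"),
               tolerance = 1e-11)

  # a weakly supported junction against deep competition is filtered out
  weak <- related_junctions(tibble::tibble(
    junction_id = c("chr1:100-300", "chr1:150-300"), chrom = "chr1",
    intron_start = c(100L, 150L), intron_end = c(300L, 300L),
    depth = c(3L, 297L)))
  kept3 <- filter_background(weak, params)
  expect_false("chr1:100-300" %in% kept3$junction_id)
  # and the p it was tested at equals the oracle for [[3,297],[3,297]]
  expect_equal(enum_fisher(3, 297, 3, 297, "greater"),
               fisher_exact_p(3, 297, 3, 297, "greater"), tolerance = 1e-11)
})

test_that("background test equals exhaustive enumeration for all small pools", {
  params <- junction_params()
  for (d in 1:12) {
    for (rel in 1:12) {
      N <- d + rel
      b <- ceiling(params$background_rate * N)
      expect_equal(fisher_exact_p(d, N - d, b, N - b, "greater"),
                   enum_fisher(d, N - d, b, N - b, "greater"),
                   tolerance = 1e-11)
    }
  }
})

test_that("known/novel classification is exact-interval and honours keep_known", {
  jt <- tibble::tibble(junction_id = c("chr1:100-200", "chr1:101-200"),
                       chrom = "chr1", intron_start = c(100L, 101L),
                       intron_end = 200L, depth = 5L)
  known <- tibble::tibble(chrom = "chr1", intron_start = 100L,
                          intron_end = 200L, strand = "+")
  cl <- classify_vs_known(jt, known)
  expect_equal(cl$status, c("known", "novel"))   # off-by-one stays novel
  novel_only <- classify_vs_known(jt, known, keep_known = FALSE)
  expect_equal(novel_only$junction_id, "chr1:101-200")
  # no annotation: everything novel
  expect_equal(classify_vs_known(jt, NULL)$status, c("novel", "novel"))
})

test_that("shift detection requires an identical-length known intron and a boundary repeat", {
  base <- strrep("T", 300)
  mk <- function(s) svase:::as_genome(c(chr1 = s))
  seq <- base
  substr(seq, 101, 102) <- "AG"  # genome[100:102)
  substr(seq, 201, 202) <- "AG"  # genome[200:202): repeat present
  g <- mk(seq)
  jt <- tibble::tibble(junction_id = "chr1:102-202", chrom = "chr1",
                       intron_start = 102L, intron_end = 202L, depth = 5L,
                       status = "novel")
  known <- tibble::tibble(chrom = "chr1", intron_start = 100L,
                          intron_end = 200L, strand = "+")
  sh <- detect_shift(jt, known, g, 10)
  expect_equal(sh$status, "shift")
  expect_equal(sh$shift_of, "chr1:100-200")
  expect_equal(sh$shift_offset, 2L)

  # breaking the repeat removes the call
  seq2 <- base
  substr(seq2, 101, 102) <- "AG"
  substr(seq2, 201, 202) <- "TT"
  sh2 <- detect_shift(jt, known, mk(seq2), 10)
  expect_equal(sh2$status, "novel")
  expect_true(is.na(sh2$shift_of))

  # length mismatch: no candidate regardless of sequence
  known_len <- tibble::tibble(chrom = "chr1", intron_start = 100L,
                              intron_end = 210L, strand = "+")
  expect_equal(detect_shift(jt, known_len, g, 10)$status, "novel")

  # tie between +k and -k breaks toward the positive offset
  sym <- mk(strrep("A", 300))   # everything repeats everywhere
  jt_mid <- tibble::tibble(junction_id = "chr1:100-200", chrom = "chr1",
                           intron_start = 100L, intron_end = 200L,
                           depth = 5L, status = "novel")
  known_two <- tibble::tibble(chrom = "chr1",
                              intron_start = c(98L, 102L),
                              intron_end = c(198L, 202L), strand = "+")
  expect_equal(detect_shift(jt_mid, known_two, sym, 10)$shift_offset, 2L)
})

test_that("shift detection is invariant under a constant genomic translation", {
  set.seed(21)
  core <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  pad <- 17L
  run_at <- function(offset, seqstr) {
    substr(seqstr, 101 + offset, 102 + offset) <- "CA"
    substr(seqstr, 201 + offset, 202 + offset) <- "CA"
    g <- svase:::as_genome(c(chr1 = seqstr))
    jt <- tibble::tibble(junction_id = jkey("chr1", 102L + offset, 202L + offset),
                         chrom = "chr1", intron_start = 102L + offset,
                         intron_end = 202L + offset, depth = 5L,
                         status = "novel")
    known <- tibble::tibble(chrom = "chr1", intron_start = 100L + offset,
                            intron_end = 200L + offset, strand = "+")
    detect_shift(jt, known, g, 10)
  }
  a <- run_at(0L, paste0(core, strrep("G", pad)))
  b <- run_at(pad, paste0(strrep("G", pad), core))
  expect_equal(a$status, b$status)
  expect_equal(a$shift_offset, b$shift_offset)
})
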