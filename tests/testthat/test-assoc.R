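test_that("consistency verdicts follow the two-sided Fisher comparison", {
  p <- assoc_params()
  expect_true(consistency_check(c(3L, 3L), c(3L, 3L), p))    # modal table
  expect_false(consistency_check(c(10L, 0L), c(0L, 10L), p)) # p ~ 1.1e-5
  expect_equal(fisher_exact_p(10, 0, 0, 10, "two.sided"),
               2 * enum_fisher(10, 0, 0, 10, "greater"), tolerance = 1e-11)
  expect_true(consistency_check(c(5L, 0L), c(0L, 0L), p))    # no related coverage
})

test_that("association test enriches ALT in splicing-supporting reads", {
  a <- association_test(c(2L, 0L), c(0L, 5L))
  expect_equal(a$p, 1 / 21, tolerance = 1e-12)
  expect_false(a$no_contrast)

  same <- association_test(c(3L, 0L), c(3L, 0L))  # ALT everywhere
  expect_equal(same$p, 1, tolerance = 1e-12)

  private <- association_test(c(5L, 1L), c(0L, 0L))
  expect_equal(private$p, 0)
  expect_true(private$no_contrast)
})

build_assoc_fixture <- function(alt_in_decoys = FALSE, n_decoy = 6L,
                                depth = 8L, n_alt = 6L) {
  g <- make_genome(1200, seed = 13)
  jr <- junction_reads(g, s = 400, e = 700, depth = depth, prefix = "t")
  pos <- 395L
  ref <- genome_seq(g, "chr1", pos, pos + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  jr <- with_alt(jr, seq_len(n_alt), pos, alt)
  dseq <- genome_seq(g, "chr1", 360, 410)
  decoys <- make_reads(!!!lapply(seq_len(n_decoy), function(i) {
    make_read(sprintf("d%03d", i), pos = 360L, cigar = "50M", seq = dseq)
  }))
  if (alt_in_decoys) decoys <- with_alt(decoys, seq_len(n_alt), pos, alt)
  reads <- dplyr::bind_rows(jr, decoys)
  obs <- junction_observations(reads, 8)
  jt <- related_junctions(aggregate_junctions(obs, junction_params()))
  jt$background_p <- 0
  jt$status <- "novel"
  cand <- call_candidates(side_pileups(jt, obs, reads), g, variant_params())
  list(g = g, reads = reads, jt = jt, cand = cand, pos = pos, alt = alt)
}

test_that("junction-restricted ALT is associated; uniform ALT is rejected", {
  fx <- build_assoc_fixture(alt_in_decoys = FALSE)
  tested <- test_associations(fx$cand, fx$jt, fx$reads)
  expect_equal(nrow(tested), 1L)
  expect_true(tested$consistent)                  # no related junctions
  expect_equal(tested$used_universe, "target-only")
  # [[6, 2], [0, 6]] against REF-only decoys
  expect_equal(tested$p_association,
               enum_fisher(6, 2, 0, 6, "greater"), tolerance = 1e-11)
  rec <- assemble_records(tested, fx$jt)
  expect_equal(nrow(rec), 1L)

  # a genomic SNP expressed everywhere: same ALT fraction in decoys
  fx2 <- build_assoc_fixture(alt_in_decoys = TRUE)
  tested2 <- test_associations(fx2$cand, fx2$jt, fx2$reads)
  expect_gt(tested2$p_association, 0.05)
  expect_equal(nrow(assemble_records(tested2, fx2$jt)), 0L)
})

test_that("a junction-private variant with zero outside coverage is kept via no-contrast", {
  fx <- build_assoc_fixture(n_decoy = 0L)
  tested <- test_associations(fx$cand, fx$jt, fx$reads)
  expect_true(tested$no_contrast)
  expect_equal(tested$p_association, 0)
  expect_equal(nrow(assemble_records(tested, fx$jt)), 1L)
})

test_that("inconsistent ALT frequencies switch the universe to related-total", {
  g <- make_genome(2000, seed = 17)
  # two junctions sharing the acceptor; ALT only in the target's reads at a
  # position both cover
  jt_a <- junction_reads(g, s = 520, e = 900, depth = 10, la = 30L, prefix = "a")
  jt_b <- junction_reads(g, s = 540, e = 900, depth = 10, la = 35L, prefix = "b")
  pos <- 515L  # inside a's left anchor [490,520) and b's [505,540)
  ref <- genome_seq(g, "chr1", pos, pos + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  reads <- with_alt(dplyr::bind_rows(jt_a, jt_b), 1:10, pos, alt)
  obs <- junction_observations(reads, 8)
  jt <- related_junctions(aggregate_junctions(obs, junction_params()))
  jt$background_p <- 0.01
  jt$status <- "novel"
  cand <- call_candidates(side_pileups(jt, obs, reads), g, variant_params())
  cand <- cand[cand$junction_id == "chr1:520-900", ]
  tested <- test_associations(cand, jt, reads)
  # target 10/10 ALT vs related 0/10 ALT: clearly inconsistent
  expect_false(tested$consistent)
  expect_equal(tested$used_universe, "related-total")
  expect_equal(tested$alt_related, 0L)
  expect_equal(tested$ref_related, 10L)
  # with no non-junction coverage, pooled row2 is empty: no-contrast
  expect_true(tested$no_contrast)
})

test_that("record assembly sorts, joins junction state and applies optional BH", {
  jt <- tibble::tibble(junction_id = c("chr1:10-20", "chr1:30-40"),
                       chrom = "chr1", intron_start = c(10L, 30L),
                       intron_end = c(20L, 40L), depth = 5L,
                       background_p = 0, status = c("novel", "known"),
                       shift_of = NA_character_, shift_offset = NA_integer_)
  cand <- tibble::tibble(
    junction_id = c("chr1:30-40", "chr1:10-20", "chr1:10-20"),
    side = "left", chrom = "chr1", pos = c(25L, 5L, 6L),
    ref = "A", alt = "G", depth = 10L, alt_count = 5L, alt_fraction = 0.5,
    p_variant = 0.01, consistent = TRUE, used_universe = "target-only",
    p_association = c(0.5, 0.01, 0.04), no_contrast = FALSE)
  plain <- assemble_records(cand, jt, assoc_params())
  expect_equal(plain$pos, c(5L, 6L))                  # sorted, 0.5 cut
  expect_equal(plain$status, c("novel", "novel"))
  bh <- assemble_records(cand, jt, assoc_params(multiple_testing = "BH"))
  # BH on {0.01, 0.04, 0.5}: adjusted {0.03, 0.06, 0.5} -> only 0.01 survives
  expect_equal(bh$pos, 5L)
  expect_equal(bh$p_assoc_adj, 0.03, tolerance = 1e-12)

  # empty candidate set assembles to an empty record set
  expect_equal(nrow(assemble_records(cand[0, ], jt, assoc_params())), 0L)
})

test_that("the same site under two junctions yields two records with distinct keys", {
  cand <- tibble::tibble(
    junction_id = c("chr1:10-20", "chr1:30-40"), side = c("right", "left"),
    chrom = "chr1", pos = 25L, ref = "A", alt = "G", depth = 10L,
    alt_count = 5L, alt_fraction = 0.5, p_variant = 0.01, consistent = TRUE,
    used_universe = "target-only", p_association = 0.01, no_contrast = FALSE)
  jt <- tibble::tibble(junction_id = c("chr1:10-20", "chr1:30-40"),
                       chrom = "chr1", intron_start = c(10L, 30L),
                       intron_end = c(20L, 40L), depth = 5L,
                       background_p = 0, status = "novel",
                       shift_of = NA_character_, shift_offset = NA_integer_)
  rec <- assemble_records(cand, jt, assoc_params())
  expect_equal(nrow(rec), 2L)
  expect_setequal(rec$junction_id, c("chr1:10-20", "chr1:30-40"))
})
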