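#' Association-stage parameters
#'
#' @param alpha_assoc Significance threshold for the variant-junction
#'   association test (default 0.05).
#' @param alpha_consistency Threshold for the two-sided ALT-frequency
#'   consistency test between target and related junctions (default 0.05).
#' @param multiple_testing `"none"` (default; raw p-values are gated, the
#'   method's own convention) or `"BH"` for Benjamini-Hochberg across all
#'   candidates before the `alpha_assoc` cut.
#' @return A `svase_assoc_params` list.
#' @export
assoc_params <- function(alpha_assoc = 0.05, alpha_consistency = 0.05,
                         multiple_testing = c("none", "BH")) {
  multiple_testing <- match.arg(multiple_testing)
  stopifnot(alpha_assoc > 0, alpha_assoc < 1,
            alpha_consistency > 0, alpha_consistency < 1)
  structure(list(alpha_assoc = alpha_assoc,
                 alpha_consistency = alpha_consistency,
                 multiple_testing = multiple_testing),
            class = "svase_assoc_params")
}

#' ALT-frequency consistency between target and related junctions
#'
#' Compares the candidate's ALT frequency among target-junction reads with
#' its frequency among reads of the side-specific related junctions, via a
#' two-sided Fisher exact test on `[[alt_t, ref_t], [alt_r, ref_r]]`.
#' Frequencies are *consistent* when the test does not reject
#' (`p > alpha_consistency`) or when the related stratum has no coverage at
#' the site.
#'
#' @param target_counts,related_counts Length-2 integer vectors `(alt, ref)`.
#' @param params [assoc_params()].
#' @return `TRUE` when consistent.
#' @export
consistency_check <- function(target_counts, related_counts,
                              params = assoc_params()) {
  if (sum(related_counts) == 0L) return(TRUE)
  p <- fisher_exact_p(target_counts[1], target_counts[2],
                      related_counts[1], related_counts[2], "two.sided")
  p > params$alpha_consistency
}

#' Variant-junction association test
#'
#' Builds a 2x2 table over all quality-unmasked reads covering the candidate
#' position: row 1 are the splicing-supporting reads (the target junction
#' only when the ALT frequencies are consistent; target plus related
#' junctions otherwise), row 2 all remaining covering reads; columns are
#' ALT vs REF base calls. Returns the one-sided (greater) p for ALT
#' enrichment among splicing-supporting reads. When row 2 has no coverage
#' the variant is junction-private: p is 0 by convention with a no-contrast
#' flag.
#'
#' @param row1,row2 Length-2 integer vectors `(alt, ref)`.
#' @return List `p`, `no_contrast`.
#' @export
association_test <- function(row1, row2) {
  if (sum(row2) == 0L) return(list(p = 0, no_contrast = TRUE))
  list(p = fisher_exact_p(row1[1], row1[2], row2[1], row2[2], "greater"),
       no_contrast = FALSE)
}

# per-candidate consistency + association over the full tables.
# `reads` must be the QC-passed set (split and non-split), the read universe
# from which covering bases are drawn.
test_associations <- function(candidates, junctions, reads,
                              params = assoc_params(), min_base_qual = 30) {
  n <- nrow(candidates)
  out <- candidates
  out$alt_target <- out$ref_target <- out$alt_related <- out$ref_related <-
    rep(NA_integer_, n)
  out$consistent <- rep(NA, n)
  out$used_universe <- rep(NA_character_, n)
  out$p_association <- rep(NA_real_, n)
  out$no_contrast <- rep(NA, n)
  if (n == 0L) return(out)

  junctions <- if (is.null(junctions$related_start)) {
    related_junctions(junctions)
  } else junctions
  jidx <- match(candidates$junction_id, junctions$junction_id)
  ids_of <- stats::setNames(junctions$read_ids, junctions$junction_id)

  for (i in seq_len(n)) {
    j <- jidx[i]
    target_ids <- junctions$read_ids[[j]]
    related_keys <- if (candidates$side[i] == "left") {
      junctions$related_end[[j]]   # competing donors joined to one acceptor
    } else {
      junctions$related_start[[j]] # competing acceptors from one donor
    }
    related_ids <- setdiff(unique(unlist(ids_of[related_keys])), target_ids)

    cov <- bases_at(reads, candidates$chrom[i], candidates$pos[i], min_base_qual)
    cov <- cov[cov$base %in% c(candidates$alt[i], candidates$ref[i]), , drop = FALSE]
    is_alt <- cov$base == candidates$alt[i]
    in_t <- cov$read_id %in% target_ids
    in_r <- cov$read_id %in% related_ids
    tc <- c(sum(is_alt & in_t), sum(!is_alt & in_t))
    rc <- c(sum(is_alt & in_r), sum(!is_alt & in_r))
    cons <- consistency_check(tc, rc, params)
    in_row1 <- if (cons) in_t else (in_t | in_r)
    r1 <- c(sum(is_alt & in_row1), sum(!is_alt & in_row1))
    r2 <- c(sum(is_alt & !in_row1), sum(!is_alt & !in_row1))
    at <- association_test(r1, r2)

    out$alt_target[i] <- tc[1]; out$ref_target[i] <- tc[2]
    out$alt_related[i] <- rc[1]; out$ref_related[i] <- rc[2]
    out$consistent[i] <- cons
    out$used_universe[i] <- if (cons) "target-only" else "related-total"
    out$p_association[i] <- at$p
    out$no_contrast[i] <- at$no_contrast
  }
  out
}

#' Assemble final variant-junction association records
#'
#' Joins candidate test results with junction status, applies the optional
#' Benjamini-Hochberg correction, cuts at `alpha_assoc`, and sorts by
#' (chrom, pos, junction). Duplicate (site, junction) candidates arising
#' from both sides of two junctions sharing a boundary are each reported
#' under their own junction key.
#'
#' @param candidates Tested candidate tibble from the association stage.
#' @param junctions Junction tibble (status, background p, shift columns).
#' @param params [assoc_params()].
#' @return Record tibble (one row per validated association).
#' @export
assemble_records <- function(candidates, junctions, params = assoc_params()) {
  jcols <- dplyr::select(junctions, "junction_id", "intron_start",
                         "intron_end", "background_p",
                         dplyr::any_of(c("status", "shift_of", "shift_offset")))
  rec <- dplyr::left_join(candidates, jcols, by = "junction_id")
  if (!"status" %in% names(rec)) rec$status <- rep("novel", nrow(rec))
  rec$p_assoc_adj <- if (params$multiple_testing == "BH" && nrow(rec)) {
    bh_adjust(rec$p_association)
  } else {
    rec$p_association
  }
  rec <- rec[!is.na(rec$p_assoc_adj) &
               p_within_alpha(rec$p_assoc_adj, params$alpha_assoc), ,
             drop = FALSE]
  dplyr::arrange(rec, .data$chrom, .data$pos, .data$junction_id, .data$alt)
}
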