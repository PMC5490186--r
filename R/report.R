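#' Assign the source type of each variant from known-site lists
#'
#' Exact (pos, ref, alt) matches in the DNA-mutation index and/or the
#' RNA-editing index give `DNA-mutation-known` / `RNA-editing-known`
#' (both, comma-joined, when present in both); a position-only match (the
#' weaker label, since public dumps vary in allele orientation) gives
#' `position-known`; otherwise `novel`.
#'
#' @param records Record tibble.
#' @param dna_sites,editing_sites Site tibbles from [load_known_sites()]
#'   (may be `NULL` or empty).
#' @return Records with a `source_type` column.
#' @export
annotate_source <- function(records, dna_sites = NULL, editing_sites = NULL) {
  n <- nrow(records)
  rkey <- paste(records$chrom, records$pos, records$ref, records$alt)
  pkey <- paste(records$chrom, records$pos)
  keys <- function(sites) {
    if (is.null(sites) || nrow(sites) == 0L) {
      list(exact = character(0), pos = character(0))
    } else {
      list(exact = paste(sites$chrom, sites$pos, sites$ref, sites$alt),
           pos = paste(sites$chrom, sites$pos))
    }
  }
  dk <- keys(dna_sites); ek <- keys(editing_sites)
  src <- character(n)
  for (i in seq_len(n)) {
    labels <- c(if (rkey[i] %in% dk$exact) "DNA-mutation-known",
                if (rkey[i] %in% ek$exact) "RNA-editing-known")
    if (length(labels) == 0L &&
        (pkey[i] %in% dk$pos || pkey[i] %in% ek$pos)) {
      labels <- "position-known"
    }
    src[i] <- if (length(labels)) paste(labels, collapse = ",") else "novel"
  }
  records$source_type <- src
  records
}

#' Classify a substitution
#'
#' Collapses the 12 directed single-base substitutions into 6
#' strand-symmetric pairs. Transitions are purine-purine or
#' pyrimidine-pyrimidine changes; the editing-pair flag marks A>G/T>C, the
#' signature of A-to-I RNA editing.
#'
#' @param ref,alt Single-base character vectors (`ref != alt`).
#' @return Tibble `pair, is_transition, is_editing_pair`.
#' @export
substitution_class <- function(ref, alt) {
  valid <- c("A", "C", "G", "T")
  if (any(!ref %in% valid) || any(!alt %in% valid) || any(ref == alt)) {
    stop("ref and alt must be distinct single bases in A/C/G/T")
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  canonical <- c("A>G", "G>A", "A>C", "A>T", "C>G", "C>A")
  directed <- paste0(ref, ">", alt)
  flipped <- paste0(comp[ref], ">", comp[alt])
  use_flip <- !(directed %in% canonical)
  canon <- ifelse(use_flip, flipped, directed)
  pair <- paste0(canon, "/", ifelse(use_flip, directed, flipped))
  purine <- c("A", "G")
  is_transition <- (ref %in% purine) == (alt %in% purine)
  tibble::tibble(pair = pair, is_transition = is_transition,
                 is_editing_pair = canon == "A>G")
}

#' Distances from each variant to its junction breakpoint and exon ends
#'
#' `dist_breakpoint` is the distance to the intron boundary of the
#' variant's own side (left side to `intron_start`, right side to
#' `intron_end`), with the base adjacent to the boundary at distance 1.
#' `dist_exon5` / `dist_exon3` are measured to the genome-left and
#' genome-right ends of the anchor-covered exon segment (the only exon
#' boundary the tool knows without annotation), same adjacency convention.
#'
#' @param records Record tibble.
#' @param obs Observation tibble (anchor extents per junction).
#' @return Records with `dist_breakpoint, dist_exon5, dist_exon3`.
#' @export
breakpoint_distances <- function(records, obs) {
  n <- nrow(records)
  records$dist_breakpoint <- rep(NA_integer_, n)
  records$dist_exon5 <- rep(NA_integer_, n)
  records$dist_exon3 <- rep(NA_integer_, n)
  if (n == 0L) return(records)
  obs$junction_id <- jkey(obs$chrom, obs$intron_start, obs$intron_end)
  seg <- obs |>
    dplyr::group_by(.data$junction_id) |>
    dplyr::summarise(
      left_lo = min(.data$left_ref_start),
      right_hi = max(.data$intron_end + .data$right_anchor),
      .groups = "drop")
  m <- match(records$junction_id, seg$junction_id)
  for (i in seq_len(n)) {
    pos <- records$pos[i]
    if (records$side[i] == "left") {
      # exon segment [left_lo, intron_start)
      records$dist_breakpoint[i] <- records$intron_start[i] - pos
      records$dist_exon5[i] <- pos - seg$left_lo[m[i]] + 1L
      records$dist_exon3[i] <- records$intron_start[i] - pos
    } else {
      # exon segment [intron_end, right_hi)
      records$dist_breakpoint[i] <- pos - records$intron_end[i] + 1L
      records$dist_exon5[i] <- pos - records$intron_end[i] + 1L
      records$dist_exon3[i] <- seg$right_hi[m[i]] - pos
    }
  }
  records
}

#' Descriptive summary tables of a run
#'
#' Machine-readable versions of the standard characteristics plots:
#' junction depth distribution, junction counts and depth distribution per
#' splice-motif class, reference-vs-alternative signal scores, variant
#' distance histograms (to the breakpoint and to the exon segment ends),
#' substitution-type counts and the transition fraction. Each table is
#' produced for all junctions and for novel-only junctions.
#'
#' @param records Record tibble (signal/annotation columns present).
#' @param junctions Junction tibble (`motif_class` present).
#' @return A `svase_summary`: named list of tibbles, plus
#'   `transition_fraction` per universe.
#' @export
summarize_svase <- function(records, junctions) {
  universes <- list(
    all = list(rec = records, jun = junctions),
    novel = list(rec = records[records$status %in% c("novel", "shift"), ,
                               drop = FALSE],
                 jun = junctions[junctions$status %in% c("novel", "shift"), ,
                                 drop = FALSE]))
  tabs <- purrr::imap(universes, function(u, name) {
    rec <- u$rec; jun <- u$jun
    sub <- if (nrow(rec)) {
      dplyr::bind_cols(rec["junction_id"],
                       substitution_class(rec$ref, rec$alt))
    } else {
      tibble::tibble(junction_id = character(0), pair = character(0),
                     is_transition = logical(0), is_editing_pair = logical(0))
    }
    list(
      junction_depth = dplyr::count(jun, .data$depth, name = "n_junctions"),
      motif_class = dplyr::count(jun, .data$motif_class, name = "n_junctions"),
      depth_by_motif = dplyr::select(jun, "motif_class", "depth"),
      signal_scores = if (nrow(rec)) {
        dplyr::select(rec, "chrom", "pos", "ref", "alt", "junction_id",
                      dplyr::any_of(c("donor_ref", "donor_alt",
                                      "acceptor_ref", "acceptor_alt")))
      } else tibble::tibble(),
      dist_exon5 = dplyr::count(rec, .data$dist_exon5, name = "n_variants"),
      dist_exon3 = dplyr::count(rec, .data$dist_exon3, name = "n_variants"),
      dist_breakpoint_by_type = if (nrow(rec)) {
        tibble::tibble(pair = sub$pair, dist_breakpoint = rec$dist_breakpoint)
      } else tibble::tibble(pair = character(0), dist_breakpoint = integer(0)),
      substitution_types = dplyr::count(sub, .data$pair, name = "n_variants"),
      transition_fraction = tibble::tibble(
        n_records = nrow(rec),
        transition_fraction = if (nrow(rec)) mean(sub$is_transition) else NA_real_,
        editing_pair_fraction = if (nrow(rec)) mean(sub$is_editing_pair) else NA_real_)
    )
  })
  structure(tabs, class = "svase_summary")
}

#' Write every summary table as TSV
#'
#' Files are named `<universe>_<table>.tsv` (universe `all` or `novel`).
#' @param summary A `svase_summary`.
#' @param dir Output directory (created if needed).
#' @export
write_summary_tsv <- function(summary, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (uni in names(summary)) {
    for (tab in names(summary[[uni]])) {
      readr::write_tsv(summary[[uni]][[tab]],
                       file.path(dir, paste0(uni, "_", tab, ".tsv")))
    }
  }
  invisible(dir)
}

#' Plot summary characteristics
#'
#' @param object A `svase_summary`.
#' @param which One of `"substitutions"`, `"junction_depth"`,
#'   `"motif_class"`, `"dist_breakpoint"`, `"signal_scores"`.
#' @param universe `"all"` or `"novel"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot svase_summary
#' @export
autoplot.svase_summary <- function(object, which = "substitutions",
                                   universe = "all", ...) {
  u <- object[[universe]]
  switch(which,
    substitutions = ggplot2::ggplot(u$substitution_types,
        ggplot2::aes(x = .data$pair, y = .data$n_variants)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "substitution pair", y = "variants",
                    title = paste("Substitution spectrum,", universe, "junctions")),
    junction_depth = ggplot2::ggplot(u$junction_depth,
        ggplot2::aes(x = .data$depth, y = .data$n_junctions)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "supporting reads", y = "junctions"),
    motif_class = ggplot2::ggplot(u$motif_class,
        ggplot2::aes(x = .data$motif_class, y = .data$n_junctions)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "splice motif", y = "junctions"),
    dist_breakpoint = ggplot2::ggplot(u$dist_breakpoint_by_type,
        ggplot2::aes(x = .data$pair, y = .data$dist_breakpoint)) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(x = "substitution pair", y = "distance to breakpoint (bp)"),
    signal_scores = {
      sc <- tidyr::pivot_longer(u$signal_scores,
        dplyr::any_of(c("donor_ref", "donor_alt", "acceptor_ref", "acceptor_alt")),
        names_to = c("site", "allele"), names_sep = "_", values_to = "score")
      ggplot2::ggplot(sc, ggplot2::aes(x = .data$score, colour = .data$allele)) +
        ggplot2::geom_density() +
        ggplot2::facet_wrap(~site, scales = "free") +
        ggplot2::labs(x = "signal score (bits)")
    },
    stop("unknown plot: ", which))
}
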