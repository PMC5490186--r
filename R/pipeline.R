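#' Run the full association caller on in-memory objects
#'
#' Stage order is fixed: read QC, junction discovery (anchor and depth
#' filters), background-expression filter, known/novel classification and
#' shift detection, per-side de novo variant calling, variant significance,
#' ALT-frequency consistency, association testing, splice-signal scoring,
#' source-type annotation, distance annotation. Deterministic for fixed
#' inputs and parameters — no sampling anywhere in the path.
#'
#' @param reads Alignment tibble from [read_alignments()] or
#'   [simulate_splice_reads()].
#' @param genome A `svase_genome`.
#' @param known_junctions Optional known-intron tibble
#'   ([load_known_junctions()]).
#' @param dna_sites,editing_sites Optional known-site tibbles
#'   ([load_known_sites()]).
#' @param qc,junction,variant,assoc Parameter objects ([qc_params()],
#'   [junction_params()], [variant_params()], [assoc_params()]).
#' @param signal_model Optional `svase_signal_model`; by default one is
#'   trained on the known junctions when provided, else on the surviving
#'   junction table's canonical-motif junctions, falling back to the
#'   uniform model.
#' @return A `svase_result`: list with `records`, `junctions`, `obs`,
#'   `qc_tally`, `stage_counts`, `params`, `signal_model`.
#' @export
svase_call <- function(reads, genome, known_junctions = NULL,
                       dna_sites = NULL, editing_sites = NULL,
                       qc = qc_params(), junction = junction_params(),
                       variant = variant_params(), assoc = assoc_params(),
                       signal_model = NULL) {
  stage <- list(input_reads = nrow(reads))

  fa <- filter_alignments(reads, qc, genome)
  passed <- fa$reads
  stage$qc_pass <- nrow(passed)

  obs <- junction_observations(passed, junction$min_anchor)
  stage$observations <- nrow(obs)
  jt <- aggregate_junctions(obs, junction)
  stage$junctions_depth_ok <- nrow(jt)
  jt <- related_junctions(jt)
  jt <- filter_background(jt, junction)
  stage$junctions_background_ok <- nrow(jt)
  jt <- classify_vs_known(jt, known_junctions, junction$keep_known)
  jt <- detect_shift(jt, known_junctions, genome, junction$max_shift)
  jt <- splice_motif(jt, genome)
  stage$junctions_final <- nrow(jt)

  piles <- side_pileups(jt, obs, passed, qc$min_base_qual)
  cand <- call_candidates(piles, genome, variant)
  stage$candidates <- nrow(cand)
  cand <- test_associations(cand, jt, passed, assoc, qc$min_base_qual)
  records <- assemble_records(cand, jt, assoc)
  stage$records <- nrow(records)

  if (is.null(signal_model)) {
    train_set <- if (!is.null(known_junctions) && nrow(known_junctions)) {
      known_junctions
    } else {
      jt
    }
    signal_model <- tryCatch(train_signal_model(train_set, genome),
                             error = function(e) uniform_signal_model())
  }
  records <- score_signal(records, jt, signal_model, genome)
  records <- annotate_source(records, dna_sites, editing_sites)
  records <- breakpoint_distances(records, obs)

  res <- structure(list(records = records, junctions = jt, obs = obs,
                        qc_tally = fa$tally, stage_counts = stage,
                        params = list(qc = qc, junction = junction,
                                      variant = variant, assoc = assoc),
                        signal_model = signal_model),
                   class = "svase_result")
  viol <- audit_records(res)
  if (nrow(viol)) {
    stop("internal gate audit failed: ", nrow(viol), " violation(s); first: ",
         viol$check[1])
  }
  res
}

#' Post-run threshold-conformance audit
#'
#' Asserts that every emitted record simultaneously satisfies all count
#' gates (depth, ALT reads, ALT fraction) and all significance gates at
#' their configured thresholds, and that every record's junction survived
#' the depth and background filters. Run automatically at the end of
#' [svase_call()]; exposed for external auditing.
#'
#' @param result A `svase_result`.
#' @return Tibble of violations (`check`, `record`); empty when clean.
#' @export
audit_records <- function(result) {
  r <- result$records
  p <- result$params
  viol <- list()
  flag <- function(bad, check) {
    if (any(bad)) {
      viol[[length(viol) + 1L]] <<- tibble::tibble(
        check = check, record = paste(r$chrom[bad], r$pos[bad], r$alt[bad]))
    }
  }
  if (nrow(r)) {
    flag(r$depth < p$variant$min_depth, "depth below minimum")
    flag(r$alt_count < p$variant$min_alt_reads, "ALT reads below minimum")
    flag(r$alt_fraction < p$variant$min_alt_fraction, "ALT fraction below minimum")
    flag(!p_within_alpha(r$p_variant, p$variant$alpha_variant),
         "variant p above alpha")
    flag(!p_within_alpha(r$p_assoc_adj, p$assoc$alpha_assoc),
         "association p above alpha")
    flag(!p_within_alpha(r$background_p, p$junction$alpha_junction),
         "junction background p above alpha")
    jd <- result$junctions$depth[match(r$junction_id, result$junctions$junction_id)]
    flag(is.na(jd) | jd < p$junction$min_junction_depth,
         "junction depth below minimum")
  }
  j <- result$junctions
  if (nrow(j)) {
    o <- result$obs
    if (nrow(o)) {
      bad_anchor <- o$left_anchor < p$junction$min_anchor |
        o$right_anchor < p$junction$min_anchor
      if (any(bad_anchor)) {
        viol[[length(viol) + 1L]] <- tibble::tibble(
          check = "anchor below minimum",
          record = o$read_id[bad_anchor])
      }
    }
  }
  dplyr::bind_rows(c(viol, list(tibble::tibble(check = character(0),
                                               record = character(0)))))
}

#' Run the pipeline from files and write every output
#'
#' Thin orchestration over [svase_call()]: loads the genome, alignments and
#' optional annotations, runs the caller, and writes the results table,
#' VCF, junction BED and TSV, flanking FASTA, summary tables, QC tally and
#' a run log into `out_dir`. On error, partial outputs are removed.
#'
#' @param genome_path FASTA genome.
#' @param alignment_path SAM or BAM with split reads.
#' @param out_dir Output directory.
#' @param known_junctions_path,known_junctions_format Optional annotation.
#' @param dna_sites_path,editing_sites_path Optional known-site lists.
#' @param flank_bp Flank size for the FASTA export (default 50).
#' @param ... Passed to [svase_call()] (`qc`, `junction`, `variant`,
#'   `assoc`, `signal_model`).
#' @return The `svase_result`, invisibly.
#' @export
svase_run <- function(genome_path, alignment_path, out_dir,
                      known_junctions_path = NULL,
                      known_junctions_format = "auto",
                      dna_sites_path = NULL, editing_sites_path = NULL,
                      flank_bp = 50, ...) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wrote <- character(0)
  on_fail <- function(e) {
    unlink(wrote)
    stop("pipeline failed (outputs removed): ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    genome <- load_genome(genome_path)
    reads <- read_alignments(alignment_path, genome)
    known <- if (!is.null(known_junctions_path)) {
      load_known_junctions(known_junctions_path, known_junctions_format)
    }
    dna <- if (!is.null(dna_sites_path)) {
      load_known_sites(dna_sites_path, label = "DNA mutation")
    }
    edit <- if (!is.null(editing_sites_path)) {
      load_known_sites(editing_sites_path, label = "RNA editing")
    }
    res <- svase_call(reads, genome, known_junctions = known,
                      dna_sites = dna, editing_sites = edit, ...)
    out <- function(name) {
      p <- file.path(out_dir, name); wrote <<- c(wrote, p); p
    }
    write_results_tsv(res$records, out("results.tsv"))
    write_vcf(res$records, genome, out("svase.vcf"))
    write_junction_bed(res$junctions, out("junctions.bed"))
    readr::write_tsv(
      res$junctions[, !vapply(res$junctions, is.list, logical(1))],
      out("junctions.tsv"))
    write_flank_fasta(res$records, genome, flank_bp, out("flanks.fa"))
    readr::write_tsv(res$qc_tally, out("qc_tally.tsv"))
    write_summary_tsv(summarize_svase(res$records, res$junctions),
                      out("summary"))
    write_signal_model(res$signal_model, out("signal_model.txt"))
    log_lines <- c(sprintf("stage\t%s\tcount\t%d", names(res$stage_counts),
                           unlist(res$stage_counts)),
                   sprintf("qc_reject\t%s\tcount\t%d", res$qc_tally$reason,
                           res$qc_tally$n))
    writeLines(log_lines, out("run_log.tsv"))
    invisible(res)
  }, error = on_fail)
}

#' Validate a run configuration list
#'
#' Checks a flat configuration (input paths plus any of the four parameter
#' groups' fields) and returns the problems found; an empty character
#' vector means the configuration is valid.
#'
#' @param config Named list, e.g. parsed from a YAML config file. Fields:
#'   `genome_path`, `alignment_path`, `out_dir` (required) and any field of
#'   [qc_params()], [junction_params()], [variant_params()],
#'   [assoc_params()].
#' @return Character vector of problem messages.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  need <- function(field) {
    if (is.null(config[[field]])) {
      problems <<- c(problems, paste0("missing required field: ", field))
    }
  }
  need("genome_path"); need("alignment_path"); need("out_dir")
  for (f in c("genome_path", "alignment_path")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      problems <- c(problems, paste0(f, " does not exist: ", config[[f]]))
    }
  }
  groups <- list(qc = qc_params, junction = junction_params,
                 variant = variant_params, assoc = assoc_params)
  for (g in names(groups)) {
    fn <- groups[[g]]
    args <- intersect(names(config), names(formals(fn)))
    if (length(args)) {
      err <- tryCatch({ do.call(fn, config[args]); NULL },
                      error = function(e) conditionMessage(e))
      if (!is.null(err)) {
        problems <- c(problems,
                      paste0("invalid ", g, " parameter (",
                             paste(args, collapse = ", "), "): ", err))
      }
    }
  }
  problems
}

#' Build the parameter groups from a flat configuration list
#' @param config Named list as in [validate_config()].
#' @return List `qc`, `junction`, `variant`, `assoc`.
#' @export
params_from_config <- function(config) {
  groups <- list(qc = qc_params, junction = junction_params,
                 variant = variant_params, assoc = assoc_params)
  lapply(groups, function(fn) {
    do.call(fn, config[intersect(names(config), names(formals(fn)))])
  })
}

# ---- result methods --------------------------------------------------------

#' @export
print.svase_result <- function(x, ...) {
  cat("<svase_result>\n")
  cat("  reads in/passing QC: ", x$stage_counts$input_reads, " / ",
      x$stage_counts$qc_pass, "\n", sep = "")
  cat("  junctions surviving filters: ", nrow(x$junctions), "\n", sep = "")
  cat("  validated variant-junction associations: ", nrow(x$records), "\n",
      sep = "")
  invisible(x)
}

#' Tidy the validated records of a run
#' @param x A `svase_result`.
#' @param ... Unused.
#' @return The record tibble, one row per validated association.
#' @method tidy svase_result
#' @export
tidy.svase_result <- function(x, ...) x$records

#' One-row summary of a run
#' @param x A `svase_result`.
#' @param ... Unused.
#' @return Tibble with read, junction and record counts and the transition
#'   fraction of emitted records.
#' @method glance svase_result
#' @export
glance.svase_result <- function(x, ...) {
  r <- x$records
  sub <- if (nrow(r)) substitution_class(r$ref, r$alt) else NULL
  tibble::tibble(
    n_reads = x$stage_counts$input_reads,
    n_reads_pass = x$stage_counts$qc_pass,
    n_junctions = nrow(x$junctions),
    n_junctions_novel = sum(x$junctions$status %in% c("novel", "shift")),
    n_records = nrow(r),
    transition_fraction = if (nrow(r)) mean(sub$is_transition) else NA_real_,
    editing_pair_fraction = if (nrow(r)) mean(sub$is_editing_pair) else NA_real_)
}

#' Plot a run's summary characteristics
#' @param object A `svase_result`.
#' @param which,universe See [autoplot.svase_summary()].
#' @param ... Unused.
#' @method autoplot svase_result
#' @export
autoplot.svase_result <- function(object, which = "substitutions",
                                  universe = "all", ...) {
  autoplot(summarize_svase(object$records, object$junctions),
           which = which, universe = universe)
}
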