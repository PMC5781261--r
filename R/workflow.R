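#' Configuration of an iterative assembly run
#'
#' Defaults mirror the workflow's stock behaviour: at most 5 iterations or a
#' cumulative alignment rate (utilisation) of 70%, whichever comes first,
#' with the whole remaining read pool (`subsample_fraction = 1`) fed to the
#' assembler each round.
#'
#' @param subsample_fraction A single fraction in `(0, 1]`, or a vector of
#'   per-iteration fractions (the last value repeats once the list is
#'   exhausted). 1 feeds the entire remaining pool without drawing from the
#'   RNG.
#' @param max_iterations Maximum number of assembly rounds (default 5).
#' @param align_threshold_pct Stop once cumulative utilisation reaches this
#'   percentage (default 70).
#' @param assembler Backend name (see [list_backends()]).
#' @param assembler_params An [assembler_params()].
#' @param align_params An [align_params()].
#' @param seed Integer seed; one RNG stream is seeded per run and consumed
#'   in iteration order.
#' @param merge Write a single merged contig FASTA when outputs are written
#'   (the combined assembly is always computed).
#' @param final_reassembly Additionally re-assemble the combined contigs into
#'   a final assembly (see [final_reassembly()]).
#' @param passthrough Free-form option string recorded verbatim in the run
#'   log (for parity with wrapped external aligners; the builtin aligner
#'   only honours `align_params`).
#' @return An `itermeta_config` list.
#' @export
itermeta_config <- function(subsample_fraction = 1,
                            max_iterations = 5,
                            align_threshold_pct = 70,
                            assembler = "builtin",
                            assembler_params = itermeta::assembler_params(),
                            align_params = itermeta::align_params(),
                            seed = 1,
                            merge = TRUE,
                            final_reassembly = FALSE,
                            passthrough = NULL) {
  if (any(subsample_fraction <= 0 | subsample_fraction > 1)) {
    abort("every `subsample_fraction` must be in (0, 1]")
  }
  if (max_iterations < 1) abort("`max_iterations` must be >= 1")
  if (align_threshold_pct < 0 || align_threshold_pct > 100) {
    abort("`align_threshold_pct` must be in [0, 100]")
  }
  structure(list(subsample_fraction = subsample_fraction,
                 max_iterations = as.integer(max_iterations),
                 align_threshold_pct = align_threshold_pct,
                 assembler = assembler,
                 assembler_params = assembler_params,
                 align_params = align_params,
                 seed = as.integer(seed),
                 merge = isTRUE(merge),
                 final_reassembly = isTRUE(final_reassembly),
                 passthrough = passthrough),
            class = "itermeta_config")
}

#' Subsample fraction for a given iteration
#'
#' A scalar fraction applies to every iteration; with a vector, the i-th
#' value is used and the last value repeats beyond the end of the list.
#'
#' @param config An [itermeta_config()].
#' @param i Iteration index (1-based).
#' @return A single fraction in `(0, 1]`.
#' @export
fraction_for_iteration <- function(config, i) {
  stopifnot(i >= 1)
  f <- config$subsample_fraction
  f[min(i, length(f))]
}

#' Random subsample of reads
#'
#' Simple random sample without replacement of size
#' `max(1, round(fraction * n))`, in original read order. `fraction = 1`
#' returns the full set without consuming the RNG.
#'
#' @param reads Reads tibble.
#' @param fraction Fraction in `(0, 1]`.
#' @return A reads tibble.
#' @export
subsample_reads <- function(reads, fraction) {
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1]")
  n <- nrow(reads)
  if (n == 0L) abort("cannot subsample an empty read set")
  if (fraction == 1) return(reads)
  size <- max(1L, round(fraction * n))
  reads[sort(sample.int(n, size)), ]
}

#' Run one assembly iteration
#'
#' Subsamples the candidate pool, assembles the subsample, then aligns *all*
#' candidates (not just the subsample) against the new contigs: aligned
#' reads are utilised and excluded from subsequent rounds, the rest carry
#' over. Contig ids gain an `it<I>_` prefix recording provenance.
#'
#' @param candidates Reads not yet utilised.
#' @param config An [itermeta_config()].
#' @param i Iteration index.
#' @return A list: `result` (iteration record: contigs, hits, counts) and
#'   `remaining` (still-unaligned reads).
#' @export
run_iteration <- function(candidates, config, i) {
  if (nrow(candidates) == 0L) abort("no candidate reads for iteration")
  frac <- fraction_for_iteration(config, i)
  sub <- subsample_reads(candidates, frac)
  contigs <- assemble_with_backend(config$assembler, sub,
                                   config$assembler_params)
  if (nrow(contigs) > 0L) {
    contigs$iteration <- as.integer(i)
    contigs$id <- sprintf("it%d_%s", i, contigs$id)
  }
  part <- partition_reads(candidates, contigs, config$align_params)
  hits <- part$hits
  if (nrow(hits) > 0L) hits$iteration <- as.integer(i)
  list(
    result = list(iteration = as.integer(i),
                  n_candidates = nrow(candidates),
                  n_subsampled = nrow(sub),
                  subsample_fraction = frac,
                  contigs = contigs,
                  hits = hits,
                  n_newly_aligned = nrow(part$hits),
                  n_too_short = part$n_too_short),
    remaining = part$unaligned
  )
}

#' Decide whether the workflow should stop
#'
#' Reasons, in order of precedence: all configured iterations completed;
#' cumulative utilisation reached the alignment threshold; no unaligned
#' reads remain; the last iteration utilised zero new reads (stall guard,
#' which prevents spinning forever on unassemblable residue).
#'
#' @param state A list with `n_iterations`, `cumulative_utilisation_pct`,
#'   `n_remaining`, `last_newly_aligned`.
#' @param config An [itermeta_config()].
#' @return A reason string, or `NULL` to continue.
#' @export
should_stop <- function(state, config) {
  if (state$n_iterations >= config$max_iterations) return("max_iterations")
  if (state$cumulative_utilisation_pct >= config$align_threshold_pct) {
    return("align_threshold")
  }
  if (state$n_remaining == 0L) return("all_reads_utilised")
  if (state$last_newly_aligned == 0L) return("stalled")
  NULL
}

#' Run the iterative assembly workflow
#'
#' Loops subsample -> assemble -> align -> assess until a stopping criterion
#' fires, then computes per-iteration and combined assembly statistics. The
#' run is fully deterministic given `config$seed`.
#'
#' @param reads Input reads tibble (see [read_fastx()]) or character vector.
#' @param config An [itermeta_config()].
#' @param out_dir Optional directory; when given, per-iteration FASTA,
#'   combined (and final) FASTA, `stats.tsv`/`stats.json`, `run.log` and the
#'   unaligned residue FASTQ are written there.
#' @return An `itermeta_result`: `iterations` (list of iteration records),
#'   `combined` (contigs tibble), `final` (contigs tibble or `NULL`),
#'   `stats` (per-iteration + combined tibble), `unaligned` (residue reads),
#'   `run_log` (config echo, stop reason, counts).
#' @seealso [tidy.itermeta_result()], [glance.itermeta_result()],
#'   [autoplot.itermeta_result()]
#' @export
itermeta_run <- function(reads, config = itermeta_config(), out_dir = NULL) {
  reads <- as_reads_tibble(reads)
  if (nrow(reads) == 0L) abort("input read set is empty")
  t0 <- Sys.time()
  withr::local_seed(config$seed)

  total <- nrow(reads)
  candidates <- reads
  iterations <- list()
  cum_aligned <- 0L
  stop_reason <- NULL
  repeat {
    i <- length(iterations) + 1L
    step <- run_iteration(candidates, config, i)
    res <- step$result
    cum_aligned <- cum_aligned + res$n_newly_aligned
    res$cumulative_aligned <- cum_aligned
    res$cumulative_utilisation_pct <- alignment_rate(cum_aligned, total)
    iterations[[i]] <- res
    candidates <- step$remaining
    stop_reason <- should_stop(
      list(n_iterations = i,
           cumulative_utilisation_pct = res$cumulative_utilisation_pct,
           n_remaining = nrow(candidates),
           last_newly_aligned = res$n_newly_aligned),
      config)
    if (!is.null(stop_reason)) break
  }

  combined <- merge_assemblies(purrr::map(iterations, "contigs"))
  final <- NULL
  if (config$final_reassembly && nrow(combined) > 0L) {
    final <- final_reassembly(combined, config)
  }

  stats <- compute_run_stats(iterations, combined, total)
  run_log <- list(
    seed = config$seed,
    assembler = config$assembler,
    k = config$assembler_params$k,
    subsample_fraction = config$subsample_fraction,
    max_iterations = config$max_iterations,
    align_threshold_pct = config$align_threshold_pct,
    passthrough = config$passthrough,
    n_input_reads = total,
    n_iterations = length(iterations),
    stop_reason = stop_reason,
    n_utilised = cum_aligned,
    n_unaligned = nrow(candidates),
    n_too_short = sum(vapply(iterations, `[[`, integer(1), "n_too_short")),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  result <- structure(
    list(iterations = iterations, combined = combined, final = final,
         stats = stats, unaligned = candidates, run_log = run_log,
         config = config),
    class = "itermeta_result")
  if (!is.null(out_dir)) write_run_outputs(result, out_dir)
  result
}

compute_run_stats <- function(iterations, combined, total) {
  per_iter <- purrr::map_dfr(iterations, function(res) {
    cov <- if (nrow(res$contigs) > 0L && nrow(res$hits) > 0L) {
      coverage_profile(res$contigs, res$hits)
    } else if (nrow(res$contigs) > 0L) {
      coverage_profile(res$contigs, res$hits, read_length = 0L)
    } else NULL
    st <- assembly_stats(res$contigs, res$cumulative_aligned, total,
                         coverage = cov)
    dplyr::bind_cols(
      tibble(iteration = as.character(res$iteration),
             n_candidates = res$n_candidates,
             n_subsampled = res$n_subsampled,
             n_newly_aligned = res$n_newly_aligned,
             cumulative_utilisation_pct = res$cumulative_utilisation_pct),
      st)
  })
  cum_aligned <- iterations[[length(iterations)]]$cumulative_aligned
  all_cov <- combined_coverage(iterations)
  combined_row <- dplyr::bind_cols(
    tibble(iteration = "combined",
           n_candidates = total,
           n_subsampled = NA_integer_,
           n_newly_aligned = cum_aligned,
           cumulative_utilisation_pct = alignment_rate(cum_aligned, total)),
    assembly_stats(combined, cum_aligned, total, coverage = all_cov))
  dplyr::bind_rows(per_iter, combined_row)
}

combined_coverage <- function(iterations) {
  vecs <- list()
  for (res in iterations) {
    if (nrow(res$contigs) == 0L) next
    cov <- if (nrow(res$hits) > 0L) coverage_profile(res$contigs, res$hits)
           else coverage_profile(res$contigs, res$hits, read_length = 0L)
    vecs <- c(vecs, unclass(cov))
  }
  if (length(vecs) == 0L) return(NULL)
  structure(vecs, class = "coverage_profile")
}

#' Merge per-iteration assemblies
#'
#' Concatenates iteration assemblies into the combined assembly, in
#' iteration order, without deduplication. Contig ids must already carry (or
#' receive here) the `it<I>_` provenance prefix; a collision is an error.
#'
#' @param assemblies List of contigs tibbles (one per iteration).
#' @return A contigs tibble.
#' @export
merge_assemblies <- function(assemblies) {
  if (length(assemblies) == 0L) abort("need at least one assembly to merge")
  assemblies <- purrr::imap(assemblies, function(a, i) {
    if (nrow(a) == 0L) return(a)
    iter <- if (all(is.na(a$iteration))) as.integer(i) else a$iteration[1]
    a$iteration <- as.integer(iter)
    no_prefix <- !grepl("^it[0-9]+_", a$id)
    a$id[no_prefix] <- sprintf("it%d_%s", iter, a$id[no_prefix])
    a
  })
  out <- dplyr::bind_rows(assemblies)
  if (anyDuplicated(out$id)) abort("contig id collision after merging")
  out
}

#' Re-assemble the combined contigs
#'
#' Feeds the combined contigs, as sequences, back into the builtin assembler
#' at the same k, so contigs from different iterations that overlap by at
#' least k-1 consistent bases merge into one. Contigs are single sequences,
#' not reads, so coverage pruning is disabled here (every contig k-mer
#' occurs once); the result is stored alongside the combined assembly,
#' replacing nothing.
#'
#' @param combined Combined contigs tibble.
#' @param config An [itermeta_config()].
#' @return A contigs tibble.
#' @export
final_reassembly <- function(combined, config = itermeta_config()) {
  if (nrow(combined) == 0L) abort("combined assembly is empty")
  p <- config$assembler_params
  params <- assembler_params(k = p$k, min_kmer_cov = 1,
                             min_contig_len = p$min_contig_len,
                             cov_cutoff = "fixed")
  contigs <- assemble_reads(combined[, c("id", "seq")], params)
  if (nrow(contigs) > 0L) contigs$id <- paste0("final_", contigs$id)
  contigs
}

#' Hits of a run as one tibble
#'
#' Binds every iteration's alignment hits, keeping the `iteration` column --
#' the input expected by [profile_from_labels()].
#'
#' @param result An `itermeta_result`.
#' @return A hits tibble with an `iteration` column.
#' @export
tidy_hits <- function(result) {
  stopifnot(inherits(result, "itermeta_result"))
  dplyr::bind_rows(purrr::map(result$iterations, "hits"))
}

write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (res in result$iterations) {
    write_fasta(res$contigs,
                file.path(out_dir, sprintf("iteration_%d.fasta",
                                           res$iteration)))
  }
  if (result$config$merge) {
    write_fasta(result$combined, file.path(out_dir, "combined.fasta"))
  }
  if (!is.null(result$final)) {
    write_fasta(result$final, file.path(out_dir, "final.fasta"))
  }
  readr::write_tsv(result$stats, file.path(out_dir, "stats.tsv"))
  jsonlite::write_json(
    list(stats = result$stats, run = result$run_log),
    file.path(out_dir, "stats.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  write_fastq(result$unaligned, file.path(out_dir, "unaligned.fastq"))
  log_lines <- c(
    sprintf("itermeta run: seed=%d assembler=%s k=%d",
            result$run_log$seed, result$run_log$assembler, result$run_log$k),
    sprintf("input reads: %d", result$run_log$n_input_reads),
    sprintf("iterations completed: %d (stop: %s)",
            result$run_log$n_iterations, result$run_log$stop_reason),
    sprintf("utilised: %d (%.2f%%); unaligned residue: %d; too short: %d",
            result$run_log$n_utilised,
            alignment_rate(result$run_log$n_utilised,
                           result$run_log$n_input_reads),
            result$run_log$n_unaligned, result$run_log$n_too_short),
    if (!is.null(result$run_log$passthrough)) {
      sprintf("passthrough (recorded verbatim): %s", result$run_log$passthrough)
    },
    sprintf("elapsed: %.1f s", result$run_log$elapsed_sec))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
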