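#' @export
print.itermeta_result <- function(x, ...) {
  rl <- x$run_log
  cat(sprintf("<itermeta_result> %d iteration(s) over %d reads (stop: %s)\n",
              rl$n_iterations, rl$n_input_reads, rl$stop_reason))
  cat(sprintf("  utilised %d reads (%.2f%%); %d contigs, %d bp combined\n",
              rl$n_utilised, alignment_rate(rl$n_utilised, rl$n_input_reads),
              nrow(x$combined), sum(nchar(x$combined$seq))))
  print(tidy(x))
  invisible(x)
}

#' Tidy per-iteration summary of a run
#'
#' One row per completed iteration with read accounting and assembly
#' statistics (the `"combined"` row of `$stats` is left out; see
#' [glance.itermeta_result()]).
#'
#' @param x An `itermeta_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.itermeta_result <- function(x, ...) {
  dplyr::filter(x$stats, .data$iteration != "combined") |>
    dplyr::mutate(iteration = as.integer(.data$iteration))
}

#' One-row summary of a run
#'
#' Combined-assembly statistics plus run metadata (iterations completed,
#' stop reason, final utilisation).
#'
#' @param x An `itermeta_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.itermeta_result <- function(x, ...) {
  comb <- dplyr::filter(x$stats, .data$iteration == "combined")
  tibble(
    n_iterations = x$run_log$n_iterations,
    stop_reason = x$run_log$stop_reason,
    n_input_reads = x$run_log$n_input_reads,
    n_utilised = x$run_log$n_utilised,
    utilisation_pct = comb$cumulative_utilisation_pct,
    n_contigs = comb$n_contigs,
    total_bp = comb$total_bp,
    n50 = comb$n50,
    longest = comb$longest,
    false_base_rate = comb$false_base_rate
  )
}

#' Plot cumulative utilisation across iterations
#'
#' @param object An `itermeta_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.itermeta_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                   y = .data$cumulative_utilisation_pct)) +
    ggplot2::geom_hline(yintercept = object$config$align_threshold_pct,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(breaks = df$iteration) +
    ggplot2::labs(x = "iteration",
                  y = "cumulative utilisation (% of input reads)",
                  title = "Read utilisation across assembly iterations",
                  subtitle = sprintf("dashed: stop threshold (%.0f%%)",
                                     object$config$align_threshold_pct)) +
    ggplot2::theme_minimal()
}

#' Plot per-iteration taxonomic profiles with significance letters
#'
#' Stacked per-iteration bars of reads assigned to each taxon; when an
#' [compare_iterations()] result is supplied, its compact letter groups are
#' printed above the bars (bars sharing a letter are not significantly
#' different).
#'
#' @param profile Profile tibble from [profile_from_labels()].
#' @param comparison Optional `iteration_comparison`.
#' @return A ggplot.
#' @export
plot_profile <- function(profile, comparison = NULL) {
  long <- tidyr::pivot_longer(profile, -"iteration", names_to = "taxon",
                              values_to = "reads")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$iteration),
                                          y = .data$reads,
                                          fill = .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "iteration", y = "reads assigned", fill = "taxon") +
    ggplot2::theme_minimal()
  if (!is.null(comparison)) {
    totals <- long |>
      dplyr::group_by(.data$iteration) |>
      dplyr::summarise(total = sum(.data$reads), .groups = "drop") |>
      dplyr::mutate(iteration = as.character(.data$iteration)) |>
      dplyr::left_join(comparison$letters, by = "iteration")
    p <- p + ggplot2::geom_text(
      data = totals,
      ggplot2::aes(x = factor(.data$iteration), y = .data$total,
                   label = .data$letters),
      vjust = -0.5, inherit.aes = FALSE)
  }
  p
}

#' @export
autoplot.iteration_comparison <- function(object, profile, ...) {
  plot_profile(profile, comparison = object)
}
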