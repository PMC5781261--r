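#' Per-iteration taxonomic read-count profile
#'
#' Tallies, for every workflow iteration, the number of aligned reads whose
#' contig carries each taxon label; the contingency table for the
#' homogeneity tests.
#'
#' @param hits Hits tibble carrying an `iteration` column (e.g. from
#'   [tidy_hits()] of a workflow result, or built manually).
#' @param contig_taxa Contig labels: a tibble (`id`/`contig_id`, `taxon`)
#'   such as [read_label_table()] returns, or a named character vector.
#'   Contigs absent from the table are counted as `"unclassified"`.
#' @return A tibble with an `iteration` column and one count column per
#'   taxon (taxa sorted alphabetically).
#' @export
profile_from_labels <- function(hits, contig_taxa) {
  taxa_map <- as_taxa_map(contig_taxa)
  if (nrow(hits) == 0L) {
    return(tibble(iteration = integer()))
  }
  stopifnot("iteration" %in% names(hits))
  taxon <- unname(taxa_map[hits$contig_id])
  taxon[is.na(taxon)] <- "unclassified"
  dplyr::tibble(iteration = hits$iteration, taxon = taxon) |>
    dplyr::count(.data$iteration, .data$taxon) |>
    tidyr::pivot_wider(names_from = "taxon", values_from = "n",
                       values_fill = 0L, names_sort = TRUE) |>
    dplyr::arrange(.data$iteration)
}

as_taxa_map <- function(contig_taxa) {
  if (is.character(contig_taxa)) {
    if (is.null(names(contig_taxa))) abort("`contig_taxa` vector must be named")
    return(contig_taxa)
  }
  if (is.data.frame(contig_taxa)) {
    idcol <- intersect(c("contig_id", "id"), names(contig_taxa))[1]
    if (is.na(idcol) || !"taxon" %in% names(contig_taxa)) {
      abort("`contig_taxa` needs an id column and a `taxon` column")
    }
    return(stats::setNames(contig_taxa$taxon, contig_taxa[[idcol]]))
  }
  abort("`contig_taxa` must be a named character vector or a data frame")
}

#' Label contigs by majority vote of their reads' truth taxa
#'
#' Stand-in for database-driven taxonomic annotation: each contig receives
#' the most frequent truth taxon among the reads aligned to it; ties break
#' lexicographically; contigs with no aligned reads are `"unclassified"`.
#'
#' @param hits Hits tibble (`read_id`, `contig_id`).
#' @param read_taxa Read truth labels: tibble (`id`, `taxon`) or named
#'   character vector.
#' @param contigs Optional contigs tibble, to include zero-hit contigs.
#' @return A tibble (`contig_id`, `taxon`).
#' @export
contig_taxa_from_truth <- function(hits, read_taxa, contigs = NULL) {
  read_map <- as_taxa_map(read_taxa)
  labelled <- tibble(contig_id = hits$contig_id,
                     taxon = unname(read_map[hits$read_id]))
  labelled$taxon[is.na(labelled$taxon)] <- "unclassified"
  voted <- labelled |>
    dplyr::count(.data$contig_id, .data$taxon) |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$taxon, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select("contig_id", "taxon")
  if (!is.null(contigs)) {
    missing <- setdiff(contigs$id, voted$contig_id)
    voted <- dplyr::bind_rows(
      voted, tibble(contig_id = missing,
                    taxon = rep("unclassified", length(missing))))
    voted <- voted[match(contigs$id, voted$contig_id), ]
  }
  voted
}

profile_matrix <- function(table) {
  if (is.matrix(table)) return(table)
  stopifnot(is.data.frame(table))
  iter_col <- intersect(c("iteration"), names(table))
  m <- as.matrix(table[, setdiff(names(table), iter_col), drop = FALSE])
  rownames(m) <- if (length(iter_col)) as.character(table$iteration)
                 else as.character(seq_len(nrow(table)))
  storage.mode(m) <- "double"
  m
}

#' Chi-square test for homogeneity of taxonomic profiles
#'
#' Pearson chi-square over the iterations-by-taxa contingency table:
#' statistic `sum((O - E)^2 / E)` with expectations from the margins,
#' `df = (r - 1)(c - 1)`. All-zero rows and columns are dropped with a
#' warning.
#'
#' @param table Profile tibble from [profile_from_labels()] or a count
#'   matrix (rows = iterations).
#' @param correct Apply Yates continuity correction (2x2 only;
#'   default `FALSE`).
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi2_homogeneity(matrix(c(10, 20, 20, 10), nrow = 2, byrow = TRUE))
chi2_homogeneity <- function(table, correct = FALSE) {
  m <- profile_matrix(table)
  zero_r <- rowSums(m) == 0
  zero_c <- colSums(m) == 0
  if (any(zero_r) || any(zero_c)) {
    warn(sprintf("dropping %d all-zero row(s) and %d all-zero column(s)",
                 sum(zero_r), sum(zero_c)))
    m <- m[!zero_r, !zero_c, drop = FALSE]
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    abort("homogeneity test needs at least 2 iterations and 2 taxa with counts")
  }
  ht <- suppressWarnings(chisq.test(m, correct = correct))
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = unname(ht$p.value))
}

#' Two-proportion z-test (pooled)
#'
#' `z = (p1 - p2) / sqrt(p(1 - p)(1/n1 + 1/n2))` with the pooled proportion
#' `p = (x1 + x2) / (n1 + n2)`; two-sided p from the normal tail. When the
#' pooled proportion is 0 or 1 the variance is zero and the comparison is
#' uninformative: `z = 0`, `p = 1`, flagged `degenerate`.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return A one-row tibble (vectorised over inputs): `statistic`,
#'   `p_value`, `degenerate`.
#' @export
#' @examples
#' two_prop_ztest(30, 100, 10, 100)
two_prop_ztest <- function(x1, n1, x2, n2) {
  if (any(n1 <= 0 | n2 <= 0)) abort("group sizes must be positive")
  if (any(x1 < 0 | x1 > n1 | x2 < 0 | x2 > n2)) {
    abort("need 0 <= x <= n in both groups")
  }
  pool <- (x1 + x2) / (n1 + n2)
  degenerate <- pool <= 0 | pool >= 1
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- ifelse(degenerate, 0, (x1 / n1 - x2 / n2) / se)
  p <- ifelse(degenerate, 1, 2 * pnorm(-abs(z)))
  tibble(statistic = z, p_value = p, degenerate = degenerate)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate correction; returns q-values in input order,
#' capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must be in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Compare per-iteration taxonomic profiles
#'
#' Runs the chi-square homogeneity test across iterations; when it rejects
#' at `alpha`, runs all pairwise-iteration, per-taxon two-proportion z-tests,
#' Benjamini-Hochberg-corrects the whole batch, and assigns compact letter
#' groups to iterations (iterations sharing a letter have no taxon whose
#' proportion differs significantly between them).
#'
#' @param table Profile tibble (with `iteration` column) or count matrix.
#' @param alpha Significance level (default 0.05).
#' @param correct Yates correction for the chi-square test.
#' @return An `iteration_comparison` list: `homogeneity` (chi-square result),
#'   `z_tests` (tibble of pairwise tests with `q_value`, empty when the
#'   profile is homogeneous), `letters` (tibble `iteration`, `letters`),
#'   `alpha`.
#' @export
compare_iterations <- function(table, alpha = 0.05, correct = FALSE) {
  m <- profile_matrix(table)
  iters <- rownames(m)
  homog <- chi2_homogeneity(m, correct = correct)
  empty_z <- tibble(iter_a = character(), iter_b = character(),
                    taxon = character(), x1 = numeric(), n1 = numeric(),
                    x2 = numeric(), n2 = numeric(), statistic = numeric(),
                    p_value = numeric(), q_value = numeric())
  if (homog$p_value >= alpha) {
    letters <- tibble(iteration = iters,
                      letters = rep("a", length(iters)))
    return(structure(list(homogeneity = homog, z_tests = empty_z,
                          letters = letters, alpha = alpha),
                     class = "iteration_comparison"))
  }
  n_row <- rowSums(m)
  pairs <- utils::combn(seq_along(iters), 2)
  z_tests <- purrr::map_dfr(seq_len(ncol(pairs)), function(pi) {
    i <- pairs[1, pi]; j <- pairs[2, pi]
    purrr::map_dfr(colnames(m), function(t) {
      zt <- two_prop_ztest(m[i, t], n_row[i], m[j, t], n_row[j])
      tibble(iter_a = iters[i], iter_b = iters[j], taxon = t,
             x1 = m[i, t], n1 = n_row[i], x2 = m[j, t], n2 = n_row[j],
             statistic = zt$statistic, p_value = zt$p_value)
    })
  })
  z_tests$q_value <- bh_adjust(z_tests$p_value)
  sig_pair <- z_tests |>
    dplyr::group_by(.data$iter_a, .data$iter_b) |>
    dplyr::summarise(sig = any(.data$q_value < alpha), .groups = "drop")
  adj <- matrix(TRUE, length(iters), length(iters),
                dimnames = list(iters, iters))
  for (r in seq_len(nrow(sig_pair))) {
    if (sig_pair$sig[r]) {
      adj[sig_pair$iter_a[r], sig_pair$iter_b[r]] <- FALSE
      adj[sig_pair$iter_b[r], sig_pair$iter_a[r]] <- FALSE
    }
  }
  letters <- letter_groups(adj)
  structure(list(homogeneity = homog, z_tests = z_tests,
                 letters = tibble(iteration = iters, letters = letters),
                 alpha = alpha),
            class = "iteration_comparison")
}

# Greedy clique cover of the non-significance graph: every non-significant
# pair ends up sharing at least one letter, and no significant pair shares
# any. Deterministic in iteration order.
letter_groups <- function(adj) {
  n <- nrow(adj)
  cliques <- list()
  covered <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (!adj[i, j] || covered[i, j]) next
      clique <- c(i, j)
      for (v in seq_len(n)) {
        if (v %in% clique) next
        if (all(adj[v, clique])) clique <- sort(c(clique, v))
      }
      for (a in clique) for (b in clique) covered[a, b] <- TRUE
      cliques[[length(cliques) + 1L]] <- clique
    }
  }
  in_any <- unique(unlist(cliques))
  for (v in setdiff(seq_len(n), in_any)) {
    cliques[[length(cliques) + 1L]] <- v
  }
  labels <- rep("", n)
  for (ci in seq_along(cliques)) {
    lab <- make_letter(ci)
    for (v in cliques[[ci]]) labels[v] <- paste0(labels[v], lab)
  }
  labels
}

make_letter <- function(i) {
  # a..z, then aa, ab, ...
  out <- ""
  i <- i - 1L
  repeat {
    out <- paste0(letters[(i %% 26L) + 1L], out)
    i <- i %/% 26L
    if (i == 0L) break
    i <- i - 1L
  }
  out
}

#' @export
print.iteration_comparison <- function(x, ...) {
  cat(sprintf("<iteration_comparison> chi-square = %.4g (df=%d), p = %.4g\n",
              x$homogeneity$statistic, x$homogeneity$df,
              x$homogeneity$p_value))
  if (nrow(x$z_tests) > 0) {
    cat(sprintf("  %d pairwise z-tests, %d significant after BH (alpha=%g)\n",
                nrow(x$z_tests), sum(x$z_tests$q_value < x$alpha), x$alpha))
  } else {
    cat("  profile homogeneous; no pairwise tests run\n")
  }
  cat("  letters:", paste(sprintf("%s=%s", x$letters$iteration,
                                  x$letters$letters), collapse = " "), "\n")
  invisible(x)
}

#' @rdname compare_iterations
#' @param x An `iteration_comparison`.
#' @param ... Unused.
#' @export
tidy.iteration_comparison <- function(x, ...) x$z_tests

#' @rdname compare_iterations
#' @export
glance.iteration_comparison <- function(x, ...) {
  dplyr::mutate(x$homogeneity,
                n_z_tests = nrow(x$z_tests),
                n_significant = sum(x$z_tests$q_value < x$alpha),
                alpha = x$alpha)
}
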