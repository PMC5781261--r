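#' N50 of contig lengths
#'
#' The contig length at which 50% of the total assembly is contained in
#' contigs of equal or greater length: sort lengths descending and return the
#' first length whose running sum reaches at least half the total.
#'
#' @param lengths Positive integer vector of contig lengths.
#' @return A single integer length.
#' @export
#' @examples
#' n50(c(40, 30, 20, 10)) # 30
n50 <- function(lengths) {
  if (length(lengths) == 0L) abort("cannot compute N50 of an empty assembly")
  if (any(lengths <= 0)) abort("contig lengths must be positive")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  as.integer(s[which(cumsum(s) >= sum(s) / 2)[1L]])
}

#' Cumulative alignment rate (utilisation)
#'
#' Percentage of the initially provided reads that align to the assembly:
#' `100 * n_aligned / n_total`.
#'
#' @param n_aligned Cumulative number of aligned (utilised) reads.
#' @param n_total Total number of input reads.
#' @return Percent in `[0, 100]`.
#' @export
alignment_rate <- function(n_aligned, n_total) {
  if (n_total <= 0) abort("`n_total` must be positive")
  if (n_aligned < 0 || n_aligned > n_total) {
    abort("`n_aligned` must be between 0 and `n_total`")
  }
  100 * n_aligned / n_total
}

#' False-base rate of an assembly
#'
#' Percentage of assembly positions covered by zero reads when the input is
#' mapped back -- bases with no read-level evidence.
#'
#' @param coverage A [coverage_profile()].
#' @return Percent in `[0, 100]`.
#' @export
false_base_rate <- function(coverage) {
  total <- sum(vapply(coverage, length, integer(1)))
  if (total == 0L) abort("cannot compute false-base rate of an empty assembly")
  zero <- sum(vapply(coverage, function(v) sum(v == 0L), integer(1)))
  100 * zero / total
}

#' Contig score from coverage and identity
#'
#' `coverage_pct / 100 * identity_pct`, ranging from 0 (no matching region)
#' to 100 (the entire contig precisely matches a reference region).
#'
#' @param coverage_pct Percent of the contig covered by its best reference
#'   match.
#' @param identity_pct Percent identity within the matched region.
#' @return Numeric score(s) in `[0, 100]`.
#' @export
contig_score <- function(coverage_pct, identity_pct) {
  if (any(coverage_pct < 0 | coverage_pct > 100, na.rm = TRUE) ||
      any(identity_pct < 0 | identity_pct > 100, na.rm = TRUE)) {
    abort("coverage and identity percentages must be in [0, 100]")
  }
  coverage_pct / 100 * identity_pct
}

#' Best reference match and contig score per contig
#'
#' For each contig, finds the reference placement maximising identical bases
#' via exact seed anchoring (default 31-mers) followed by the best-scoring
#' ungapped segment along each candidate diagonal (match +1, mismatch -2),
#' on both strands. The matched region is a single maximal ungapped segment.
#' A contig sharing no seed with any genome scores 0.
#'
#' @param contigs Contigs tibble.
#' @param genomes Reference genomes tibble (`genome_id`/`id`, `seq`).
#' @param seed_len Anchor seed length (default 31).
#' @return A tibble: `contig_id`, `genome_id`, `strand`, `coverage_pct`,
#'   `identity_pct`, `score`.
#' @export
best_reference_match <- function(contigs, genomes, seed_len = 31) {
  contigs <- as_reads_tibble(contigs, "contigs")
  if (is.data.frame(genomes) && "genome_id" %in% names(genomes)) {
    genomes <- dplyr::rename(genomes, id = "genome_id")
  }
  genomes <- as_reads_tibble(genomes, "genomes")
  if (nrow(genomes) == 0L) abort("`genomes` must be non-empty")
  res <- ref_match_cpp(contigs$seq, genomes$seq, as.integer(seed_len))
  tibble(
    contig_id = contigs$id,
    genome_id = ifelse(is.na(res$genome), NA_character_,
                       genomes$id[res$genome]),
    strand = res$strand,
    coverage_pct = res$coverage_pct,
    identity_pct = res$identity_pct,
    score = contig_score(res$coverage_pct, res$identity_pct)
  )
}

#' Summary statistics of one assembly
#'
#' N50, length extremes, the standard deviation of contig lengths, the
#' cumulative alignment rate, and (when a coverage profile is given) the
#' false-base rate.
#'
#' @param contigs Contigs tibble.
#' @param n_aligned Cumulative aligned read count attributed to this
#'   assembly.
#' @param n_total Total input reads.
#' @param coverage Optional [coverage_profile()] for the false-base rate.
#' @param sd_type `"population"` (divide by n, default) or `"sample"`.
#' @return One-row tibble: `n_contigs`, `total_bp`, `n50`, `longest`,
#'   `shortest`, `len_sd`, `alignment_rate`, `false_base_rate`.
#' @export
assembly_stats <- function(contigs, n_aligned, n_total, coverage = NULL,
                           sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (nrow(contigs) == 0L) {
    return(tibble(n_contigs = 0L, total_bp = 0L, n50 = NA_integer_,
                  longest = NA_integer_, shortest = NA_integer_,
                  len_sd = NA_real_,
                  alignment_rate = alignment_rate(n_aligned, n_total),
                  false_base_rate = NA_real_))
  }
  lens <- nchar(contigs$seq)
  len_sd <- if (sd_type == "population") {
    sqrt(mean((lens - mean(lens))^2))
  } else {
    sd(lens)
  }
  tibble(
    n_contigs = length(lens),
    total_bp = as.integer(sum(lens)),
    n50 = n50(lens),
    longest = as.integer(max(lens)),
    shortest = as.integer(min(lens)),
    len_sd = len_sd,
    alignment_rate = alignment_rate(n_aligned, n_total),
    false_base_rate = if (is.null(coverage)) NA_real_
                      else false_base_rate(coverage)
  )
}
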