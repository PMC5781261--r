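#' Specify a synthetic metagenome community
#'
#' Describes an uneven-abundance community of single-genome species and the
#' shotgun read set to draw from it. The defaults emulate, at desk scale, a
#' simulated benchmark community in which species abundances decline along a
#' gradient from 0.66% to 0.22%: 20 genomes of 5--10 kb, 200,000 single-end
#' 100 bp reads, and a 1% per-base substitution error rate.
#'
#' @param n_genomes Number of species (one genome each).
#' @param genome_length Either a single length in bp or a `c(min, max)` range
#'   from which genome lengths are drawn uniformly.
#' @param abundance_max,abundance_min Endpoints of the abundance gradient
#'   (fractions, renormalised to sum to 1 across genomes).
#' @param total_reads Number of reads to simulate.
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param abundance_shape `"linear"` (rank-linear gradient, default) or
#'   `"log"` (log-uniform between the endpoints).
#' @param seed Integer RNG seed; all generation is deterministic given it.
#' @return A `community_spec` list.
#' @seealso [simulate_community()]
#' @export
community_spec <- function(n_genomes = 20,
                           genome_length = c(5000, 10000),
                           abundance_max = 0.0066,
                           abundance_min = 0.0022,
                           total_reads = 200000,
                           read_length = 100,
                           error_rate = 0.01,
                           abundance_shape = c("linear", "log"),
                           seed = 1) {
  abundance_shape <- match.arg(abundance_shape)
  stopifnot(n_genomes >= 1, total_reads >= 1, read_length >= 1)
  if (!(length(genome_length) %in% c(1L, 2L)) || any(genome_length < 1)) {
    abort("`genome_length` must be a positive length or a c(min, max) range")
  }
  if (length(genome_length) == 2L && genome_length[1] > genome_length[2]) {
    abort("`genome_length` range must have min <= max")
  }
  if (!(abundance_max >= abundance_min && abundance_min > 0)) {
    abort("need abundance_max >= abundance_min > 0")
  }
  if (error_rate < 0 || error_rate >= 1) abort("`error_rate` must be in [0, 1)")
  structure(
    list(n_genomes = as.integer(n_genomes),
         genome_length = as.integer(genome_length),
         abundance_max = abundance_max, abundance_min = abundance_min,
         total_reads = as.integer(total_reads),
         read_length = as.integer(read_length),
         error_rate = error_rate, abundance_shape = abundance_shape,
         seed = as.integer(seed)),
    class = "community_spec"
  )
}

#' Generate random genomes for a community
#'
#' Draws `n_genomes` i.i.d. uniform-composition genome sequences of the
#' requested length (or length range). Deterministic given `spec$seed`.
#'
#' @param spec A [community_spec()].
#' @return A tibble with columns `genome_id`, `seq`, `length`.
#' @export
generate_genomes <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  if (min(spec$genome_length) < spec$read_length) {
    abort("genome_length must be >= read_length")
  }
  withr::with_seed(spec$seed, generate_genomes_impl(spec))
}

generate_genomes_impl <- function(spec) {
  n <- spec$n_genomes
  lens <- if (length(spec$genome_length) == 1L) {
    rep(spec$genome_length, n)
  } else {
    spec$genome_length[1] +
      floor(runif(n) * (spec$genome_length[2] - spec$genome_length[1] + 1L))
  }
  seqs <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  tibble(genome_id = sprintf("g%03d", seq_len(n)), seq = seqs,
         length = as.integer(lens))
}

#' Assign a rank-gradient abundance profile
#'
#' Interpolates abundances between `abundance_max` and `abundance_min` across
#' genome ranks (linearly by default, log-uniformly with
#' `abundance_shape = "log"`), then renormalises to sum to 1.
#'
#' @param spec A [community_spec()].
#' @return A numeric vector of fractions summing to 1.
#' @export
assign_abundances <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  n <- spec$n_genomes
  if (n == 1L) return(1)
  raw <- switch(spec$abundance_shape,
    linear = seq(spec$abundance_max, spec$abundance_min, length.out = n),
    log = exp(seq(log(spec$abundance_max), log(spec$abundance_min),
                  length.out = n))
  )
  raw / sum(raw)
}

#' Simulate shotgun reads from genomes
#'
#' Each read is drawn by choosing a source genome with probability equal to
#' its abundance, a uniform start position, a uniform strand, and i.i.d.
#' per-base substitutions at `spec$error_rate`. Read ids encode the source
#' genome and an ordinal (`<genome_id>_r<ordinal>`), so truth labels survive
#' FASTA round trips.
#'
#' @param genomes Tibble from [generate_genomes()] (columns `genome_id`,
#'   `seq`).
#' @param abundances Numeric abundance vector, one per genome, summing to 1.
#' @param spec A [community_spec()].
#' @return A tibble of reads (`id`, `seq`, `qual`, `taxon` = source genome).
#' @export
simulate_reads <- function(genomes, abundances, spec) {
  stopifnot(inherits(spec, "community_spec"))
  if (length(abundances) != nrow(genomes)) {
    abort("`abundances` must have one entry per genome")
  }
  withr::with_seed(spec$seed + 1L,
                   simulate_reads_impl(genomes, abundances, spec))
}

simulate_reads_impl <- function(genomes, abundances, spec) {
  glen <- nchar(genomes$seq)
  if (spec$read_length > min(glen)) {
    abort("read_length exceeds the shortest genome")
  }
  total <- spec$total_reads
  rl <- spec$read_length
  gidx <- sample.int(nrow(genomes), total, replace = TRUE, prob = abundances)
  starts <- 1L + floor(runif(total) * (glen[gidx] - rl + 1L))
  seqs <- substring(genomes$seq[gidx], starts, starts + rl - 1L)
  minus <- runif(total) < 0.5
  if (any(minus)) seqs[minus] <- revcomp_cpp(seqs[minus])
  if (spec$error_rate > 0) {
    seqs <- apply_substitutions_cpp(seqs, spec$error_rate)
  }
  tibble(
    id = sprintf("%s_r%07d", genomes$genome_id[gidx], seq_len(total)),
    seq = seqs,
    qual = NA_character_,
    taxon = genomes$genome_id[gidx]
  )
}

#' Simulate a complete community with truth labels
#'
#' Runs [generate_genomes()], [assign_abundances()] and [simulate_reads()]
#' under one seed and returns the complete truth set.
#'
#' @param spec A [community_spec()].
#' @return A `community_truth` list with elements `genomes` (tibble),
#'   `abundances` (numeric) and `reads` (tibble with `taxon` truth labels).
#' @export
#' @examples
#' truth <- simulate_community(community_spec(
#'   n_genomes = 3, genome_length = 2000, total_reads = 500, seed = 42))
#' truth$abundances
simulate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  genomes <- generate_genomes(spec)
  abundances <- assign_abundances(spec)
  reads <- simulate_reads(genomes, abundances, spec)
  structure(list(genomes = genomes, abundances = abundances, reads = reads,
                 spec = spec),
            class = "community_truth")
}

#' @export
print.community_truth <- function(x, ...) {
  cat(sprintf(
    "<community_truth> %d genomes (%d-%d bp), %d reads x %d bp, error %.2f%%, seed %d\n",
    nrow(x$genomes), min(x$genomes$length), max(x$genomes$length),
    nrow(x$reads), x$spec$read_length, 100 * x$spec$error_rate, x$spec$seed))
  invisible(x)
}

#' Write a simulated community to disk
#'
#' Writes `reads.fastq`, `genomes.fasta` and the `truth.tsv` label table
#' consumed by [read_label_table()].
#'
#' @param truth A `community_truth` from [simulate_community()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_community <- function(truth, out_dir) {
  stopifnot(inherits(truth, "community_truth"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reads = file.path(out_dir, "reads.fastq"),
             genomes = file.path(out_dir, "genomes.fasta"),
             truth = file.path(out_dir, "truth.tsv"))
  write_fastq(truth$reads, paths[["reads"]])
  write_fasta(truth$genomes[, c("genome_id", "seq")] |>
                dplyr::rename(id = "genome_id"), paths[["genomes"]])
  writeLines(c("# read_id\ttaxon",
               paste0(truth$reads$id, "\t", truth$reads$taxon)),
             paths[["truth"]])
  invisible(paths)
}
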