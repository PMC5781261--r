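#' Assembler parameters
#'
#' Parameters for the builtin de Bruijn unitig assembler. `k` must be odd
#' (avoids reverse-complement palindromic k-mers) and at most 31 (2-bit
#' encoding). The coverage cutoff is resolved per assembly: with
#' `cov_cutoff = "auto"` (the default) it is
#' `max(min_kmer_cov, floor(auto_frac * expected_coverage))`, where expected
#' coverage is estimated as the median k-mer count over k-mer instances --
#' the same idea as assemblers that derive a coverage cutoff from an
#' automatically estimated expected coverage. With `"fixed"` the cutoff is
#' `min_kmer_cov` exactly.
#'
#' @param k K-mer size (odd, 3--31).
#' @param min_kmer_cov Minimum k-mer count kept by pruning (default 2 drops
#'   singleton error k-mers).
#' @param min_contig_len Minimum emitted contig length (default `2k - 1`,
#'   i.e. at least k k-mers).
#' @param cov_cutoff `"auto"` or `"fixed"` (see Details).
#' @param auto_frac Fraction of estimated expected coverage used as the auto
#'   cutoff (default 0.5).
#' @return An `assembler_params` list.
#' @export
assembler_params <- function(k = 31, min_kmer_cov = 2,
                             min_contig_len = 2 * k - 1,
                             cov_cutoff = c("auto", "fixed"),
                             auto_frac = 0.5) {
  cov_cutoff <- match.arg(cov_cutoff)
  k <- as.integer(k)
  if (k < 3L || k > 31L) abort("`k` must be between 3 and 31")
  if (k %% 2L == 0L) abort("`k` must be odd")
  if (min_kmer_cov < 1) abort("`min_kmer_cov` must be >= 1")
  if (min_contig_len < k) abort("`min_contig_len` must be >= k")
  structure(list(k = k, min_kmer_cov = as.integer(min_kmer_cov),
                 min_contig_len = as.integer(min_contig_len),
                 cov_cutoff = cov_cutoff, auto_frac = auto_frac),
            class = "assembler_params")
}

#' Build a de Bruijn graph from reads
#'
#' Counts canonical k-mers (lexicographic minimum of a k-mer and its reverse
#' complement) over all reads; k-mers containing `N` are skipped.
#'
#' @param reads Reads tibble (or character vector of sequences).
#' @param k Odd k-mer size, at most 31.
#' @return A `dbg_graph` handle; inspect with [graph_kmers()] /
#'   [graph_size()], reduce with [prune_graph()], and extract contigs with
#'   [extract_unitigs()].
#' @export
build_graph <- function(reads, k) {
  reads <- as_reads_tibble(reads)
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 3L || k > 31L) abort("`k` must be odd, 3..31")
  if (nrow(reads) == 0L || !any(nchar(reads$seq) >= k)) {
    abort("no usable kmers: no read is at least k bases long")
  }
  ptr <- dbg_build_cpp(reads$seq, k)
  if (dbg_size_cpp(ptr) == 0) abort("no usable kmers (only ambiguous bases?)")
  structure(list(ptr = ptr, k = k), class = "dbg_graph")
}

#' @export
print.dbg_graph <- function(x, ...) {
  cat(sprintf("<dbg_graph> k=%d, %d canonical kmers\n", x$k, graph_size(x)))
  invisible(x)
}

#' Number of canonical k-mers in a graph
#' @param graph A `dbg_graph`.
#' @return Integer count of stored canonical k-mers.
#' @export
graph_size <- function(graph) {
  stopifnot(inherits(graph, "dbg_graph"))
  as.integer(dbg_size_cpp(graph$ptr))
}

#' Materialise a graph's k-mers and counts
#'
#' Intended for inspection and testing on small graphs.
#'
#' @param graph A `dbg_graph`.
#' @return A tibble with columns `kmer` (canonical spelling) and `count`,
#'   sorted by k-mer.
#' @export
graph_kmers <- function(graph) {
  stopifnot(inherits(graph, "dbg_graph"))
  as_tibble(dbg_kmers_cpp(graph$ptr))
}

#' Remove low-coverage k-mers
#'
#' Drops k-mers observed fewer than `min_kmer_cov` times. Idempotent.
#'
#' @param graph A `dbg_graph`.
#' @param min_kmer_cov Minimum count kept.
#' @return A new pruned `dbg_graph`.
#' @export
prune_graph <- function(graph, min_kmer_cov) {
  stopifnot(inherits(graph, "dbg_graph"), min_kmer_cov >= 1)
  structure(list(ptr = dbg_prune_cpp(graph$ptr, as.integer(min_kmer_cov)),
                 k = graph$k),
            class = "dbg_graph")
}

#' Estimate expected k-mer coverage
#'
#' Median k-mer count over k-mer instances (counts weighted by count); the
#' estimate behind the automatic coverage cutoff.
#'
#' @param graph A `dbg_graph`.
#' @return A single number (0 for an empty graph).
#' @export
expected_coverage <- function(graph) {
  stopifnot(inherits(graph, "dbg_graph"))
  dbg_weighted_median_cov_cpp(graph$ptr)
}

#' Extract unitig contigs from a graph
#'
#' Contigs are maximal non-branching paths: a unitig extends through a node
#' only while that node has a unique successor whose predecessor is also
#' unique, so no greedy extension happens through branches. Each contig is
#' emitted in the lexicographically smaller of its two orientations; output
#' is sorted by length (descending) then sequence, so results are
#' byte-deterministic.
#'
#' @param graph A pruned `dbg_graph`.
#' @param min_contig_len Drop contigs shorter than this.
#' @return Contigs tibble: `id`, `seq`, `length`, `mean_cov` (mean k-mer
#'   count along the path), `k`, `iteration` (`NA` until a workflow round
#'   claims the contigs).
#' @export
extract_unitigs <- function(graph, min_contig_len = 2 * graph$k - 1) {
  stopifnot(inherits(graph, "dbg_graph"))
  df <- dbg_unitigs_cpp(graph$ptr, as.integer(min_contig_len))
  contig_tibble(df$seq, df$mean_cov, graph$k)
}

contig_tibble <- function(seqs, mean_cov, k) {
  lens <- nchar(seqs)
  tibble(
    id = sprintf("c%05d_len%d_cov%.1f", seq_along(seqs), lens, mean_cov),
    seq = seqs,
    length = as.integer(lens),
    mean_cov = mean_cov,
    k = rep(as.integer(k), length(seqs)),
    iteration = rep(NA_integer_, length(seqs))
  )
}

#' Assemble reads with the builtin unitig assembler
#'
#' Composition of [build_graph()], coverage-cutoff resolution, [prune_graph()]
#' and [extract_unitigs()]. Deterministic: identical input and parameters give
#' byte-identical contigs.
#'
#' @param reads Reads tibble or character vector of sequences.
#' @param params An [assembler_params()].
#' @return Contigs tibble (see [extract_unitigs()]); the resolved coverage
#'   cutoff is attached as attribute `"cov_cutoff_used"`.
#' @export
#' @examples
#' reads <- c("ACGTACGTACGTACG", "CGTACGTACGTACGT")
#' assemble_reads(reads, assembler_params(k = 7, min_kmer_cov = 1,
#'                                        cov_cutoff = "fixed"))
assemble_reads <- function(reads, params = assembler_params()) {
  stopifnot(inherits(params, "assembler_params"))
  graph <- build_graph(reads, params$k)
  cutoff <- params$min_kmer_cov
  if (params$cov_cutoff == "auto") {
    est <- expected_coverage(graph)
    cutoff <- max(cutoff, as.integer(floor(params$auto_frac * est)))
  }
  if (cutoff > 1L) graph <- prune_graph(graph, cutoff)
  contigs <- extract_unitigs(graph, params$min_contig_len)
  attr(contigs, "cov_cutoff_used") <- cutoff
  contigs
}

# --- backend registry -------------------------------------------------------

.backends <- new.env(parent = emptyenv())

#' Register an assembler backend
#'
#' A backend is any function `(reads, params) -> contigs tibble` satisfying
#' the contract of [assemble_reads()]. The `"builtin"` backend is always
#' available; `"velvet"` and `"abyss"` are thin external-command adapters
#' that require the respective executable on `PATH`.
#'
#' @param name Backend name.
#' @param fun Function of `(reads, params)` returning a contigs tibble.
#' @return Invisibly, `name`.
#' @export
register_backend <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .backends)
  invisible(name)
}

#' List registered assembler backends
#' @return Character vector of backend names.
#' @export
list_backends <- function() sort(ls(.backends))

#' Assemble through a named backend
#'
#' @param name Registered backend name (see [list_backends()]).
#' @inheritParams assemble_reads
#' @return Contigs tibble.
#' @export
assemble_with_backend <- function(name, reads, params = assembler_params()) {
  if (!exists(name, envir = .backends, inherits = FALSE)) {
    abort(sprintf("unknown assembler backend '%s'; registered: %s",
                  name, paste(list_backends(), collapse = ", ")))
  }
  fun <- get(name, envir = .backends, inherits = FALSE)
  fun(reads, params)
}

# External adapter: writes reads to FASTA, runs a command template, reads the
# produced contigs back. Templates use {reads}, {out_dir}, {k}. Not exercised
# unless the executable is installed.
external_backend <- function(exe, template, contig_file) {
  force(exe); force(template); force(contig_file)
  function(reads, params) {
    if (!nzchar(Sys.which(exe))) {
      abort(sprintf(
        "assembler '%s' not found on PATH; install it or use the 'builtin' backend",
        exe))
    }
    reads <- as_reads_tibble(reads)
    work <- tempfile(paste0(exe, "_work"))
    dir.create(work)
    on.exit(unlink(work, recursive = TRUE))
    reads_fa <- file.path(work, "reads.fasta")
    write_fasta(reads, reads_fa)
    cmd <- template
    cmd <- gsub("{reads}", reads_fa, cmd, fixed = TRUE)
    cmd <- gsub("{out_dir}", work, cmd, fixed = TRUE)
    cmd <- gsub("{k}", as.character(params$k), cmd, fixed = TRUE)
    status <- system(cmd)
    if (status != 0L) abort(sprintf("backend '%s' exited with status %d", exe, status))
    contigs <- read_fastx(file.path(work, contig_file), format = "fasta")
    contig_tibble(contigs$seq, rep(NA_real_, nrow(contigs)), params$k)
  }
}

register_default_backends <- function() {
  register_backend("builtin", function(reads, params) assemble_reads(reads, params))
  register_backend("velvet", external_backend(
    "velveth",
    "velveth {out_dir} {k} -fasta -short {reads} && velvetg {out_dir} -exp_cov auto",
    "contigs.fa"))
  register_backend("abyss", external_backend(
    "abyss-pe",
    "abyss-pe -C {out_dir} k={k} name=asm se='{reads}'",
    "asm-unitigs.fa"))
}

.onLoad <- function(libname, pkgname) {
  register_default_backends()
}
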