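#' Read-alignment parameters
#'
#' The builtin aligner decides whether a read is "utilised" by an assembly:
#' a read aligns iff some placement found through an exact seed match yields
#' a full-length, end-to-end, ungapped alignment with at most
#' `max_mismatches` mismatches. This approximates the role a seed-based
#' short-read mapper plays as a yes/no utilisation oracle; the contract is
#' the aligned/unaligned partition, not SAM-level mimicry.
#'
#' @param seed_len Exact-match seed length (<= 31; default 22).
#' @param max_mismatches Mismatch cap over the full read. `NULL` (default)
#'   means `ceiling(mismatch_frac * read_length)` per read.
#' @param mismatch_frac Fraction used when `max_mismatches` is `NULL`
#'   (default 0.04).
#' @param both_strands Also consider reverse-complement placements
#'   (default `TRUE`).
#' @return An `align_params` list.
#' @export
align_params <- function(seed_len = 22, max_mismatches = NULL,
                         mismatch_frac = 0.04, both_strands = TRUE) {
  seed_len <- as.integer(seed_len)
  if (seed_len < 4L || seed_len > 31L) abort("`seed_len` must be 4..31")
  if (!is.null(max_mismatches) && max_mismatches < 0) {
    abort("`max_mismatches` must be >= 0")
  }
  structure(list(seed_len = seed_len,
                 max_mismatches = if (is.null(max_mismatches)) NULL
                                  else as.integer(max_mismatches),
                 mismatch_frac = mismatch_frac,
                 both_strands = isTRUE(both_strands)),
            class = "align_params")
}

resolve_max_mm <- function(params, read_len) {
  if (!is.null(params$max_mismatches)) {
    rep(params$max_mismatches, length(read_len))
  } else {
    as.integer(ceiling(params$mismatch_frac * read_len))
  }
}

#' Build an exact-seed index over contigs
#'
#' Indexes every `seed_len`-mer of every contig (canonically, so both strands
#' are found). Contigs shorter than the seed length are skipped with a
#' warning.
#'
#' @param contigs Contigs tibble (`id`, `seq`) or named character vector.
#' @param seed_len Seed length (default 22).
#' @return A `contig_index` with fields `contig_ids`, `contig_len`,
#'   `seed_len` and `n_positions` (number of indexed seed positions).
#' @export
index_contigs <- function(contigs, seed_len = 22) {
  contigs <- as_reads_tibble(contigs, "contigs")
  if (nrow(contigs) == 0L) abort("cannot index an empty contig set")
  seed_len <- as.integer(seed_len)
  short <- nchar(contigs$seq) < seed_len
  if (any(short)) {
    warn(sprintf("skipping %d contig(s) shorter than the seed length (%d)",
                 sum(short), seed_len))
    contigs <- contigs[!short, ]
  }
  if (nrow(contigs) == 0L) abort("all contigs are shorter than the seed length")
  ptr <- seed_index_build_cpp(contigs$seq, seed_len)
  structure(list(ptr = ptr,
                 contig_ids = contigs$id,
                 contig_len = nchar(contigs$seq),
                 seed_len = seed_len,
                 n_positions = seed_index_npos_cpp(ptr)),
            class = "contig_index")
}

#' @export
print.contig_index <- function(x, ...) {
  cat(sprintf("<contig_index> %d contigs, seed_len=%d, %.0f seed positions\n",
              length(x$contig_ids), x$seed_len, x$n_positions))
  invisible(x)
}

align_batch <- function(index, reads, params) {
  max_mm <- resolve_max_mm(params, nchar(reads$seq))
  res <- align_batch_cpp(index$ptr, reads$seq, max_mm, params$both_strands)
  tibble(
    read_id = reads$id,
    contig_id = ifelse(is.na(res$contig), NA_character_,
                       index$contig_ids[res$contig]),
    pos = res$pos,
    strand = res$strand,
    mismatches = res$mismatches,
    read_len = nchar(reads$seq),
    status = res$status
  )
}

#' Align a single read against an index
#'
#' Among placements within the mismatch cap, returns the one with fewest
#' mismatches; ties are broken by contig order, then position, then `+`
#' strand.
#'
#' @param read One-row reads tibble, or a single sequence string.
#' @param index A [index_contigs()] result.
#' @param params An [align_params()].
#' @return A one-row tibble (`read_id`, `contig_id`, `pos` 0-based, `strand`,
#'   `mismatches`) or a zero-row tibble when the read does not align.
#' @export
align_read <- function(read, index, params = align_params()) {
  read <- as_reads_tibble(read, "read")[1, ]
  hits <- align_batch(index, read, params)
  hits[hits$status == 0L, c("read_id", "contig_id", "pos", "strand",
                            "mismatches", "read_len")]
}

#' Partition reads into aligned and unaligned
#'
#' Aligns every read against the contig set; each read lands in exactly one
#' of `hits` or `unaligned`. Reads shorter than the seed length cannot be
#' tested and are counted as unaligned (reported via `n_too_short`).
#'
#' @param reads Reads tibble.
#' @param contigs Contigs tibble (may be empty: everything is unaligned).
#' @param params An [align_params()].
#' @return A list with `hits` (tibble: `read_id`, `contig_id`, `pos`,
#'   `strand`, `mismatches`, `read_len`), `unaligned` (reads tibble) and
#'   `n_too_short`.
#' @export
partition_reads <- function(reads, contigs, params = align_params()) {
  reads <- as_reads_tibble(reads)
  empty_hits <- tibble(read_id = character(), contig_id = character(),
                       pos = integer(), strand = character(),
                       mismatches = integer(), read_len = integer())
  if (is.null(contigs) || nrow(contigs) == 0L ||
      all(nchar(contigs$seq) < params$seed_len)) {
    return(list(hits = empty_hits, unaligned = reads,
                n_too_short = sum(nchar(reads$seq) < params$seed_len)))
  }
  index <- index_contigs(contigs, params$seed_len)
  res <- align_batch(index, reads, params)
  aligned <- res$status == 0L
  list(
    hits = res[aligned, c("read_id", "contig_id", "pos", "strand",
                          "mismatches", "read_len")],
    unaligned = reads[!aligned, ],
    n_too_short = sum(res$status == 2L)
  )
}

#' Per-base read coverage of contigs
#'
#' Counts, for every contig position, the number of aligned reads covering
#' it (strand-independent); the pileup behind the false-base-rate statistic.
#'
#' @param contigs Contigs tibble.
#' @param hits Hits tibble from [partition_reads()] (each hit contributes
#'   coverage over `[pos, pos + read_len)`).
#' @param read_length Fallback read length when `hits` lacks a `read_len`
#'   column.
#' @return A `coverage_profile`: named list (one integer vector per contig,
#'   length equal to the contig length).
#' @export
coverage_profile <- function(contigs, hits, read_length = NULL) {
  contigs <- as_reads_tibble(contigs, "contigs")
  lens <- nchar(contigs$seq)
  cidx <- match(hits$contig_id, contigs$id)
  if (anyNA(cidx)) abort("hits reference contigs absent from `contigs`")
  hlen <- if ("read_len" %in% names(hits)) hits$read_len
          else rep(as.integer(read_length), nrow(hits))
  if (anyNA(hlen)) abort("hit read lengths unavailable; supply `read_length`")
  vecs <- coverage_cpp(as.integer(lens), as.integer(cidx),
                       as.integer(hits$pos), as.integer(hlen))
  names(vecs) <- contigs$id
  structure(vecs, class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  total <- sum(vapply(x, length, integer(1)))
  zero <- sum(vapply(x, function(v) sum(v == 0L), integer(1)))
  cat(sprintf("<coverage_profile> %d contigs, %d bp, %.2f%% uncovered\n",
              length(x), total, if (total > 0) 100 * zero / total else 0))
  invisible(x)
}

#' Write alignment hits as TSV
#'
#' Tab-separated dump: `read_id`, `contig_id`, `pos` (0-based), `strand`,
#' `mismatches`.
#'
#' @param hits Hits tibble.
#' @param path Output path.
#' @return Invisibly, the number of rows written.
#' @export
write_hits <- function(hits, path) {
  readr::write_tsv(hits[, c("read_id", "contig_id", "pos", "strand",
                            "mismatches")], path)
  invisible(nrow(hits))
}
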