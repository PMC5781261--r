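#' Reverse complement of DNA sequences
#'
#' Vectorised reverse complement over character sequences; ambiguous bases
#' (e.g. `N`) are preserved.
#'
#' @param seqs Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAC"))
revcomp <- function(seqs) {
  stopifnot(is.character(seqs))
  revcomp_cpp(seqs)
}

# coerce the various "collection of sequences" inputs to a reads tibble
as_reads_tibble <- function(reads, arg = "reads") {
  if (is.character(reads)) {
    return(tibble(
      id = if (is.null(names(reads))) paste0("r", seq_along(reads)) else names(reads),
      seq = unname(reads),
      qual = NA_character_,
      taxon = NA_character_
    ))
  }
  if (!is.data.frame(reads) || !all(c("id", "seq") %in% names(reads))) {
    abort(sprintf("`%s` must be a data frame with `id` and `seq` columns", arg))
  }
  out <- as_tibble(reads)
  if (!"qual" %in% names(out)) out$qual <- NA_character_
  if (!"taxon" %in% names(out)) out$taxon <- NA_character_
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
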