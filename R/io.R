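#' Read sequences from FASTA or FASTQ
#'
#' Parses a FASTA or FASTQ file into a tibble of reads. The format is sniffed
#' from the first non-blank character when `format = "auto"` (`>` means FASTA,
#' `@` means FASTQ). Gzip-compressed files are handled transparently. Bases
#' are uppercased; the record id is the header up to the first whitespace.
#'
#' Record ids must be unique within one file; malformed FASTQ records
#' (quality/sequence length mismatch, truncated 4-line blocks) raise an error
#' naming the offending line.
#'
#' @param path Path to a FASTA/FASTQ file (optionally gzipped).
#' @param format One of `"auto"`, `"fasta"`, `"fastq"`.
#' @return A tibble with columns `id`, `seq`, `qual` (`NA` for FASTA) and
#'   `taxon` (always `NA`; join truth labels with [read_label_table()]).
#' @seealso [write_fasta()], [read_label_table()]
#' @export
read_fastx <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- sniff_format(path)
    if (is.na(format)) {
      # empty file: nothing to parse either way
      return(tibble(id = character(), seq = character(),
                    qual = character(), taxon = character()))
    }
  }
  out <- if (format == "fasta") read_fasta_file(path) else read_fastq_file(path)
  dup <- duplicated(out$id)
  if (any(dup)) {
    abort(sprintf("duplicate read id(s) in %s: %s", path,
                  paste(unique(out$id[dup])[1:min(3, sum(dup))], collapse = ", ")))
  }
  out
}

sniff_format <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) return(NA_character_)
    line <- trimws(line)
    if (nzchar(line)) {
      first <- substr(line, 1L, 1L)
      if (first == ">") return("fasta")
      if (first == "@") return("fastq")
      abort(sprintf("cannot sniff format of %s: first record starts with '%s'",
                    path, first))
    }
  }
}

read_fasta_file <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(set))
  tibble(
    id = ids,
    seq = toupper(as.character(set, use.names = FALSE)),
    qual = NA_character_,
    taxon = NA_character_
  )
}

read_fastq_file <- function(path) {
  lines <- readLines(path)
  # trailing blank lines are tolerated
  while (length(lines) > 0L && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0L) {
    return(tibble(id = character(), seq = character(),
                  qual = character(), taxon = character()))
  }
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("truncated FASTQ record at line %d of %s: %d leftover line(s)",
                  4L * (length(lines) %/% 4L) + 1L, path, length(lines) %% 4L))
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr) > 0L) {
    abort(sprintf("malformed FASTQ header at line %d of %s (expected '@')",
                  4L * (bad_hdr[1L] - 1L) + 1L, path))
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus) > 0L) {
    abort(sprintf("malformed FASTQ separator at line %d of %s (expected '+')",
                  4L * (bad_plus[1L] - 1L) + 3L, path))
  }
  bad_len <- which(nchar(qual) != nchar(seqs))
  if (length(bad_len) > 0L) {
    abort(sprintf(
      "FASTQ quality length mismatch at line %d of %s (record %d: %d bases, %d quality characters)",
      4L * (bad_len[1L] - 1L) + 4L, path, bad_len[1L],
      nchar(seqs[bad_len[1L]]), nchar(qual[bad_len[1L]])))
  }
  tibble(
    id = sub("\\s.*$", "", substring(hdr, 2L)),
    seq = toupper(seqs),
    qual = qual,
    taxon = NA_character_
  )
}

#' Write sequences to a wrapped FASTA file
#'
#' @param records A tibble with `id` and `seq` columns (reads or contigs), or
#'   a named character vector of sequences.
#' @param path Output path.
#' @param line_width Sequence line wrap width (default 70).
#' @return Invisibly, the number of records written.
#' @export
write_fasta <- function(records, path, line_width = 70) {
  records <- as_reads_tibble(records, "records")
  if (nrow(records) > 0 && any(!nzchar(records$seq))) {
    abort("cannot write records with empty sequences")
  }
  set <- Biostrings::DNAStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, filepath = path, width = line_width)
  invisible(nrow(records))
}

# minimal FASTQ writer for the unaligned-residue output; fabricates uniform
# qualities when none are carried
write_fastq <- function(records, path) {
  records <- as_reads_tibble(records, "records")
  qual <- ifelse(is.na(records$qual), strrep("I", nchar(records$seq)),
                 records$qual)
  con <- file(path, "wt")
  on.exit(close(con))
  if (nrow(records) > 0) {
    writeLines(paste0("@", records$id, "\n", records$seq, "\n+\n", qual), con)
  }
  invisible(nrow(records))
}

#' Read a two-column id-to-taxon label table
#'
#' Reads a TSV with two columns (`id`, `taxon`); lines starting with `#` and
#' blank lines are ignored. A duplicated id is allowed only when mapped to the
#' same taxon.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `id` and `taxon` (one row per distinct id).
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield != 2L)
  if (length(bad) > 0L) {
    abort(sprintf("label table %s line %d: expected 2 tab-separated fields, got %d",
                  path, idx[bad[1L]], nfield[bad[1L]]))
  }
  out <- tibble(
    id = vapply(parts, `[[`, character(1), 1L),
    taxon = vapply(parts, `[[`, character(1), 2L)
  )
  conflicts <- dplyr::distinct(out) |>
    dplyr::count(.data$id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(conflicts) > 0L) {
    abort(sprintf("label table %s: id '%s' mapped to multiple taxa",
                  path, conflicts$id[1L]))
  }
  dplyr::distinct(out)
}
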