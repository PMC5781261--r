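# Independent oracles and fixture builders, deliberately implemented with
# plain base R (no package internals) so they can cross-check the compiled
# paths.

rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

revcomp_r <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# canonical k-mer tally by string manipulation
canonical_kmers_r <- function(seqs, k) {
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    km <- substring(s, 1:(n - k + 1), k:n)
    km <- km[!grepl("[^ACGT]", km)]
    rc <- revcomp_r(km)
    pmin(km, rc)
  }))
  if (length(kmers) == 0) return(integer())
  table(kmers)
}

# brute-force N50 straight from the definition
n50_brute <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(as.numeric(s)) / 2
  run <- 0
  for (l in s) {
    run <- run + l
    if (run >= half) return(l)
  }
}

# exhaustive ungapped scan of every placement of a read on every contig and
# strand; returns the minimum mismatch count over all placements (Inf when
# the read is longer than every contig)
align_brute <- function(read, contig_seqs, both_strands = TRUE) {
  read <- toupper(read)
  queries <- if (both_strands) c(read, revcomp_r(read)) else read
  L <- nchar(read)
  best <- Inf
  for (cs in contig_seqs) {
    n <- nchar(cs)
    if (n < L) next
    cvec <- strsplit(cs, "")[[1]]
    for (q in queries) {
      qvec <- strsplit(q, "")[[1]]
      for (start in 1:(n - L + 1)) {
        mm <- sum(qvec != cvec[start:(start + L - 1)])
        if (mm < best) best <- mm
      }
    }
  }
  best
}

pearson_chi2 <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(statistic = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE))
}

# textbook step-up BH
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rep(NA_real_, m)
  sorted <- p[o] * m / seq_len(m)
  for (i in seq_len(m)) q[i] <- min(sorted[i:m], 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# reads tiling a genome so that every position (ends included) is covered
tile_reads <- function(genome, read_len, stride) {
  L <- nchar(genome)
  starts <- unique(c(seq(1, L - read_len + 1, by = stride), L - read_len + 1))
  substring(genome, starts, starts + read_len - 1)
}

# shift every base one step round A->C->G->T->A: guarantees zero identity
# with the original at every offset-0 position
base_shift <- function(s) chartr("ACGT", "CGTA", s)

# small uneven two-genome truth set used by workflow tests
two_genome_fixture <- function(seed = 11, n_reads = 6000,
                               abundances = c(0.9, 0.1)) {
  spec <- community_spec(n_genomes = 2, genome_length = 3000,
                         total_reads = n_reads, read_length = 100,
                         error_rate = 0, seed = seed)
  genomes <- generate_genomes(spec)
  reads <- simulate_reads(genomes, abundances, spec)
  list(spec = spec, genomes = genomes, reads = reads)
}
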