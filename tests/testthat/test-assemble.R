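test_that("graph construction matches a canonical k-mer tally oracle", {
  # hand case: ACGTACG at k=5 gives ACGTA, CGTAC, GTACG; GTACG canonicalises
  # onto CGTAC, so the canonical tally is {ACGTA: 1, CGTAC: 2}
  g <- build_graph("ACGTACG", k = 5)
  km <- graph_kmers(g)
  expect_equal(km$kmer, c("ACGTA", "CGTAC"))
  expect_equal(km$count, c(1L, 2L))

  withr::local_seed(21)
  reads <- vapply(rep(60, 20), rand_seq, character(1))
  km <- graph_kmers(build_graph(reads, k = 7))
  oracle <- canonical_kmers_r(reads, 7)
  expect_equal(km$count, as.integer(oracle[km$kmer]))
  expect_equal(sort(km$kmer), sort(names(oracle)))
})

test_that("reads with no usable k-mers are an error", {
  expect_error(build_graph(character(), k = 5), "no usable kmers")
  expect_error(build_graph(c("ACG", "TT"), k = 5), "no usable kmers")
  expect_error(build_graph("NNNNNNNNNN", k = 5), "no usable kmers")
})

test_that("a read and its reverse complement produce one graph with doubled counts", {
  withr::local_seed(22)
  r <- rand_seq(40)
  g1 <- graph_kmers(build_graph(r, k = 5))
  g2 <- graph_kmers(build_graph(c(r, revcomp_r(r)), k = 5))
  expect_equal(g2$kmer, g1$kmer)
  expect_equal(g2$count, 2L * g1$count)
})

test_that("pruning removes low-coverage k-mers and is idempotent", {
  withr::local_seed(23)
  reads <- c(rep(rand_seq(30), 3), rand_seq(30))
  g <- build_graph(reads, k = 9)
  expect_equal(graph_kmers(prune_graph(g, 1)), graph_kmers(g))
  p2 <- prune_graph(g, 2)
  expect_true(all(graph_kmers(p2)$count >= 2))
  expect_equal(graph_kmers(prune_graph(p2, 2)), graph_kmers(p2))
  p4 <- prune_graph(g, 4)
  expect_equal(graph_size(p4), 0L)
})

test_that("a repeat-free read assembles to itself", {
  # chosen so all canonical 5-mers are distinct (verified by the oracle)
  read <- "ACGGTCATTC"
  expect_equal(max(canonical_kmers_r(read, 5)), 1)
  contigs <- assemble_reads(read, assembler_params(
    k = 5, min_kmer_cov = 1, min_contig_len = 9, cov_cutoff = "fixed"))
  expect_equal(nrow(contigs), 1L)
  expect_true(contigs$seq %in% c(read, revcomp_r(read)))
})

test_that("disconnected reads yield one contig each", {
  r1 <- "ACGGTCATTCA"
  r2 <- "GGAGGGAAGAT"
  expect_equal(length(intersect(names(canonical_kmers_r(r1, 5)),
                                names(canonical_kmers_r(r2, 5)))), 0L)
  contigs <- assemble_reads(c(r1, r2), assembler_params(
    k = 5, min_kmer_cov = 1, min_contig_len = 9, cov_cutoff = "fixed"))
  expect_equal(nrow(contigs), 2L)
})

test_that("full tiled coverage reconstructs a random genome exactly", {
  withr::local_seed(24)
  genome <- rand_seq(2000)
  reads <- tile_reads(genome, 100, 3)
  contigs <- assemble_reads(reads, assembler_params(
    k = 31, min_kmer_cov = 1, cov_cutoff = "fixed"))
  expect_equal(nrow(contigs), 1L)
  expect_true(contigs$seq %in% c(genome, revcomp_r(genome)))
})

test_that("deep random shotgun coverage recovers nearly all genome bases", {
  withr::local_seed(25)
  genome <- rand_seq(5000)
  n_reads <- 5000 * 50 / 100 # 50x
  starts <- sample.int(5000 - 100 + 1, n_reads, replace = TRUE)
  reads <- substring(genome, starts, starts + 99)
  contigs <- assemble_reads(reads, assembler_params(k = 31))
  covered <- logical(5000)
  for (s in contigs$seq) {
    for (q in c(s, revcomp_r(s))) {
      at <- gregexpr(q, genome, fixed = TRUE)[[1]]
      for (a in at[at > 0]) covered[a:(a + nchar(q) - 1)] <- TRUE
    }
  }
  expect_gte(mean(covered), 0.95)
  # zero-error support: every contig is an exact substring of the genome
  in_genome <- vapply(contigs$seq, function(s) {
    grepl(s, genome, fixed = TRUE) || grepl(revcomp_r(s), genome, fixed = TRUE)
  }, logical(1))
  expect_true(all(in_genome))
})

test_that("unitigs are maximal: re-assembling the contigs changes nothing", {
  withr::local_seed(26)
  genome <- rand_seq(3000)
  reads <- tile_reads(genome, 80, 5)
  params <- assembler_params(k = 21, min_kmer_cov = 1, cov_cutoff = "fixed")
  contigs <- assemble_reads(reads, params)
  again <- assemble_reads(contigs$seq, params)
  expect_equal(sort(again$seq), sort(contigs$seq))
})

test_that("assembly output is byte-deterministic", {
  withr::local_seed(27)
  genome <- rand_seq(2000)
  starts <- sample.int(1901, 600, replace = TRUE)
  reads <- substring(genome, starts, starts + 99)
  params <- assembler_params(k = 21)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(assemble_reads(reads, params), f1)
  write_fasta(assemble_reads(sample(reads), params), f2) # order-insensitive too
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the automatic coverage cutoff suppresses low-coverage material", {
  withr::local_seed(28)
  gA <- rand_seq(1000); gB <- rand_seq(1000)
  reads <- c(rep(tile_reads(gA, 100, 10), 30), # ~300x
             tile_reads(gB, 100, 10))          # ~10x
  contigs <- assemble_reads(reads, assembler_params(k = 21))
  expect_gt(nrow(contigs), 0L)
  from_b <- vapply(contigs$seq, function(s) {
    grepl(s, gB, fixed = TRUE) || grepl(revcomp_r(s), gB, fixed = TRUE)
  }, logical(1))
  expect_false(any(from_b))
  # fixed cutoff keeps both genomes
  both <- assemble_reads(reads, assembler_params(k = 21, cov_cutoff = "fixed"))
  from_b2 <- vapply(both$seq, function(s) {
    grepl(s, gB, fixed = TRUE) || grepl(revcomp_r(s), gB, fixed = TRUE)
  }, logical(1))
  expect_true(any(from_b2))
})

test_that("backend registry delegates, rejects unknown names, and accepts mocks", {
  withr::local_seed(29)
  reads <- tile_reads(rand_seq(500), 80, 4)
  params <- assembler_params(k = 21, min_kmer_cov = 1, cov_cutoff = "fixed")
  expect_equal(assemble_with_backend("builtin", reads, params),
               assemble_reads(reads, params), ignore_attr = TRUE)
  expect_error(assemble_with_backend("nope", reads, params), "builtin")
  expect_true(all(c("builtin", "velvet", "abyss") %in% list_backends()))
  # external adapter fails actionably when the executable is absent
  if (Sys.which("velveth") == "") {
    expect_error(assemble_with_backend("velvet", reads, params), "PATH")
  }
  # a mock backend that echoes reads as contigs completes a workflow round
  register_backend("echo", function(reads, params) {
    tibble::tibble(id = paste0("c", seq_len(nrow(reads))), seq = reads$seq,
                   length = nchar(reads$seq), mean_cov = 1,
                   k = params$k, iteration = NA_integer_)
  })
  fx <- two_genome_fixture(seed = 30, n_reads = 300)
  res <- itermeta_run(fx$reads, itermeta_config(
    max_iterations = 1, assembler = "echo", seed = 30))
  expect_equal(res$run_log$n_iterations, 1L)
  expect_gt(res$run_log$n_utilised, 0L)
})

test_that("parameter validation enforces odd k and sane bounds", {
  expect_error(assembler_params(k = 32), "odd|31")
  expect_error(assembler_params(k = 22), "odd")
  expect_error(assembler_params(k = 21, min_contig_len = 10), ">= k")
  expect_error(build_graph("ACGTACGT", k = 4), "odd")
})
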