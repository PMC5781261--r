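test_that("subsampling honours the size contract and seeding", {
  reads <- tibble::tibble(id = paste0("r", 1:1000), seq = strrep("A", 30))
  full <- withr::with_seed(61, subsample_reads(reads, 1))
  expect_identical(full, reads)
  # fraction 1 consumes no randomness
  withr::with_seed(61, {
    before <- .Random.seed
    subsample_reads(reads, 1)
    expect_identical(.Random.seed, before)
  })
  quarter <- withr::with_seed(61, subsample_reads(reads, 0.25))
  expect_equal(nrow(quarter), 250L)
  expect_equal(anyDuplicated(quarter$id), 0L)
  again <- withr::with_seed(61, subsample_reads(reads, 0.25))
  expect_identical(quarter, again)
  expect_error(subsample_reads(reads, 0), "fraction")
  expect_error(subsample_reads(reads[0, ], 0.5), "empty")
})

test_that("per-iteration fractions recycle the last value", {
  cfg <- itermeta_config(subsample_fraction = 0.25)
  expect_equal(fraction_for_iteration(cfg, 3), 0.25)
  cfg2 <- itermeta_config(subsample_fraction = c(1, 0.5))
  expect_equal(fraction_for_iteration(cfg2, 1), 1)
  expect_equal(fraction_for_iteration(cfg2, 2), 0.5)
  expect_equal(fraction_for_iteration(cfg2, 3), 0.5)
  cfg3 <- itermeta_config(subsample_fraction = rep(0.033, 5),
                          max_iterations = 5, align_threshold_pct = 99)
  expect_equal(fraction_for_iteration(cfg3, 5), 0.033)
  expect_error(itermeta_config(subsample_fraction = 1.2), "\\(0, 1\\]")
})

test_that("one iteration conserves reads between hits and remainder", {
  fx <- two_genome_fixture(seed = 62, n_reads = 1000)
  cfg <- itermeta_config(seed = 62, assembler_params = assembler_params(
    k = 21, cov_cutoff = "fixed"))
  step <- withr::with_seed(62, run_iteration(fx$reads, cfg, 1))
  res <- step$result
  expect_equal(res$n_newly_aligned + nrow(step$remaining), res$n_candidates)
  expect_true(all(startsWith(res$contigs$id, "it1_")))
  expect_equal(unique(res$contigs$iteration), 1L)

  # an assembler that produces nothing leaves all candidates in play
  register_backend("null", function(reads, params) {
    assemble_reads(reads, params)[0, ]
  })
  cfg0 <- itermeta_config(assembler = "null", seed = 62)
  step0 <- withr::with_seed(62, run_iteration(fx$reads, cfg0, 1))
  expect_equal(step0$result$n_newly_aligned, 0L)
  expect_equal(nrow(step0$remaining), 1000L)
})

test_that("stopping reasons fire in the documented order", {
  cfg <- itermeta_config(max_iterations = 5, align_threshold_pct = 70)
  st <- function(i, util, remaining, last) {
    list(n_iterations = i, cumulative_utilisation_pct = util,
         n_remaining = remaining, last_newly_aligned = last)
  }
  expect_equal(should_stop(st(5, 50, 100, 10), cfg), "max_iterations")
  expect_equal(should_stop(st(2, 71.2, 100, 10), cfg), "align_threshold")
  expect_equal(should_stop(st(2, 50, 0, 10), cfg), "all_reads_utilised")
  expect_equal(should_stop(st(2, 50, 100, 0), cfg), "stalled")
  expect_null(should_stop(st(2, 50, 100, 10), cfg))
})

test_that("iteration recycling recovers reads a single pass misses", {
  fx <- two_genome_fixture(seed = 63, n_reads = 6000)
  res <- itermeta_run(fx$reads, itermeta_config(
    max_iterations = 3, align_threshold_pct = 100, seed = 63))
  df <- tidy(res)
  expect_gt(df$cumulative_utilisation_pct[2], df$cumulative_utilisation_pct[1])
  # monotone non-decreasing utilisation
  expect_true(all(diff(df$cumulative_utilisation_pct) >= 0))
  # conservation over the whole run
  expect_equal(sum(df$n_newly_aligned) + nrow(res$unaligned), 6000L)
  # a read is utilised in at most one iteration
  all_hits <- tidy_hits(res)
  expect_equal(anyDuplicated(all_hits$read_id), 0L)
  # combined assembly is the disjoint union of the per-iteration sets
  expect_equal(nrow(res$combined),
               sum(vapply(res$iterations,
                          function(x) nrow(x$contigs), integer(1))))
  expect_equal(anyDuplicated(res$combined$id), 0L)
})

test_that("a single full-fraction iteration is a plain base assembly", {
  fx <- two_genome_fixture(seed = 64, n_reads = 800)
  res <- itermeta_run(fx$reads, itermeta_config(
    max_iterations = 1, subsample_fraction = 1, seed = 64))
  expect_equal(length(res$iterations), 1L)
  expect_equal(res$run_log$stop_reason, "max_iterations")
  direct <- assemble_reads(fx$reads, res$config$assembler_params)
  expect_equal(res$combined$seq, direct$seq)
})

test_that("runs are byte-identical under a fixed seed", {
  fx <- two_genome_fixture(seed = 65, n_reads = 2000)
  cfg <- itermeta_config(subsample_fraction = 0.5, max_iterations = 3,
                         align_threshold_pct = 100, seed = 65)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- itermeta_run(fx$reads, cfg, out_dir = d1)
  r2 <- itermeta_run(fx$reads, cfg, out_dir = d2)
  for (f in c("combined.fasta", "stats.tsv", "unaligned.fastq")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_identical(r1$stats, r2$stats)
})

test_that("final utilisation is stable across subsampling seeds", {
  fx <- two_genome_fixture(seed = 66, n_reads = 4000)
  utils <- vapply(1:3, function(s) {
    res <- itermeta_run(fx$reads, itermeta_config(
      subsample_fraction = 0.5, max_iterations = 3,
      align_threshold_pct = 100, seed = s))
    glance(res)$utilisation_pct
  }, numeric(1))
  expect_lt(max(utils) - min(utils), 2)
})

test_that("merging prefixes provenance and rejects collisions", {
  a1 <- tibble::tibble(id = paste0("c", 1:10), seq = strrep("A", 50),
                       length = 50L, mean_cov = 1, k = 21L,
                       iteration = NA_integer_)
  merged <- merge_assemblies(list(a1, a1, a1))
  expect_equal(nrow(merged), 30L)
  expect_true(all(grepl("^it[123]_", merged$id)))
  expect_equal(merged$iteration, rep(1:3, each = 10))
  single <- merge_assemblies(list(a1))
  expect_equal(single$id, paste0("it1_", a1$id))
  expect_error(merge_assemblies(list(merged, merged)), "collision")
})

test_that("final reassembly merges overlapping contigs and preserves disjoint ones", {
  withr::local_seed(67)
  genome <- rand_seq(400)
  k <- 21
  combined <- tibble::tibble(
    id = c("it1_a", "it2_b"),
    seq = c(substring(genome, 1, 220), substring(genome, 180, 400)),
    length = c(220L, 221L), mean_cov = 1, k = as.integer(k),
    iteration = c(1L, 2L))
  cfg <- itermeta_config(assembler_params = assembler_params(k = k))
  fin <- final_reassembly(combined, cfg)
  expect_equal(nrow(fin), 1L)
  expect_true(fin$seq %in% c(genome, revcomp_r(genome)))
  expect_lte(sum(fin$length), sum(combined$length))

  apart <- tibble::tibble(
    id = c("it1_a", "it2_b"),
    seq = c(rand_seq(150), rand_seq(150)),
    length = 150L, mean_cov = 1, k = as.integer(k), iteration = 1:2)
  fin2 <- final_reassembly(apart, cfg)
  expect_setequal(
    fin2$seq,
    vapply(apart$seq, function(s) min(s, revcomp_r(s)), character(1)))
})

test_that("run outputs land on disk with stats in both formats", {
  fx <- two_genome_fixture(seed = 68, n_reads = 600)
  d <- withr::local_tempdir()
  res <- itermeta_run(fx$reads, itermeta_config(
    max_iterations = 2, align_threshold_pct = 100, seed = 68,
    final_reassembly = TRUE), out_dir = d)
  expect_true(file.exists(file.path(d, "iteration_1.fasta")))
  expect_true(file.exists(file.path(d, "combined.fasta")))
  expect_true(file.exists(file.path(d, "stats.json")))
  expect_true(file.exists(file.path(d, "run.log")))
  js <- jsonlite::read_json(file.path(d, "stats.json"))
  expect_equal(length(js$stats), nrow(res$stats))
  expect_equal(js$run$n_input_reads, 600L)
  back <- read_fastx(file.path(d, "combined.fasta"))
  expect_equal(back$seq, res$combined$seq)
})
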