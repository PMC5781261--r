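test_that("profiles tally aligned reads per iteration and taxon", {
  no_hits <- tibble::tibble(iteration = integer(), read_id = character(),
                            contig_id = character())
  expect_equal(nrow(profile_from_labels(no_hits, c(c1 = "A"))), 0L)

  hits <- tibble::tibble(
    iteration = c(1L, 1L, 1L, 2L, 2L),
    read_id = paste0("r", 1:5),
    contig_id = c("c1", "c1", "c2", "c2", "c3"))
  prof <- profile_from_labels(hits, c(c1 = "Firmicutes", c2 = "Firmicutes"))
  expect_equal(names(prof), c("iteration", "Firmicutes", "unclassified"))
  expect_equal(prof$Firmicutes, c(3L, 1L))
  expect_equal(prof$unclassified, c(0L, 1L)) # c3 unlabelled
  expect_equal(rowSums(prof[-1]), c(3, 2), ignore_attr = TRUE)
})

test_that("contig labels come from a majority vote with deterministic ties", {
  hits <- tibble::tibble(
    read_id = paste0("r", 1:14),
    contig_id = c(rep("c1", 10), rep("c2", 4)))
  labels <- c(stats::setNames(rep(c("A", "B"), c(9, 1)), paste0("r", 1:10)),
              stats::setNames(rep(c("B", "A"), 2), paste0("r", 11:14)))
  out <- contig_taxa_from_truth(hits, labels,
                                contigs = tibble::tibble(
                                  id = c("c1", "c2", "c3")))
  expect_equal(out$taxon[out$contig_id == "c1"], "A") # 9 vs 1
  expect_equal(out$taxon[out$contig_id == "c2"], "A") # 2-2 tie, lexicographic
  expect_equal(out$taxon[out$contig_id == "c3"], "unclassified")
})

test_that("truth-pure contigs give a profile equal to the read-truth tally", {
  fx <- two_genome_fixture(seed = 51, n_reads = 2000,
                           abundances = c(0.6, 0.4))
  res <- itermeta_run(fx$reads, itermeta_config(
    max_iterations = 1, align_threshold_pct = 100, seed = 51,
    assembler_params = assembler_params(k = 21, cov_cutoff = "fixed")))
  hits <- tidy_hits(res)
  truth_labels <- stats::setNames(fx$reads$taxon, fx$reads$id)
  ct <- contig_taxa_from_truth(hits, truth_labels)
  prof <- profile_from_labels(hits, ct)
  tally <- table(truth_labels[hits$read_id])
  for (g in names(tally)) {
    expect_equal(prof[[g]], as.integer(tally[[g]]))
  }
})

test_that("chi-square homogeneity matches the closed form", {
  res <- chi2_homogeneity(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-4)
  expect_equal(res$df, 1L)
  expect_equal(res$p_value, 0.00982, tolerance = 1e-3)

  same <- chi2_homogeneity(matrix(c(5, 10, 15, 5, 10, 15), 2, byrow = TRUE))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  withr::local_seed(52)
  for (i in 1:100) {
    m <- matrix(5 + rpois(12, 30), 3, 4)
    got <- chi2_homogeneity(m)
    want <- pearson_chi2(m)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-6)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-6)
    expect_equal(got$df, want$df)
  }
})

test_that("degenerate profile rows and columns are dropped or rejected", {
  m <- matrix(c(10, 20, 0, 20, 10, 0), 2, byrow = TRUE)
  expect_warning(res <- chi2_homogeneity(m), "all-zero")
  expect_equal(res$df, 1L)
  expect_error(suppressWarnings(
    chi2_homogeneity(matrix(c(5, 5, 0, 0), 2, byrow = TRUE))), "at least 2")
})

test_that("pooled z-test matches the closed form and prop.test", {
  res <- two_prop_ztest(30, 100, 10, 100)
  expect_equal(res$statistic, 3.5355, tolerance = 1e-4)
  expect_equal(res$p_value, 4.07e-4, tolerance = 1e-2)

  eq <- two_prop_ztest(10, 100, 10, 100)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  flip <- two_prop_ztest(10, 100, 30, 100)
  expect_equal(flip$statistic, -res$statistic)
  expect_equal(flip$p_value, res$p_value)

  degen <- two_prop_ztest(0, 50, 0, 80)
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)

  withr::local_seed(53)
  for (i in 1:100) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    x1 <- sample.int(n1 - 1, 1); x2 <- sample.int(n2 - 1, 1)
    mine <- two_prop_ztest(x1, n1, x2, n2)
    ref <- suppressWarnings(prop.test(c(x1, x2), c(n1, n2), correct = FALSE))
    expect_equal(mine$statistic^2, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-6)
  }
})

test_that("BH adjustment reproduces the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::local_seed(54)
  for (i in 1:50) {
    p <- runif(sample(2:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_brute(p))
    expect_true(all(q >= p))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm])
  }
})

test_that("iteration comparison assigns letters consistent with the tests", {
  # homogeneous: one letter, no z-tests
  homog <- matrix(c(50, 50, 48, 52, 51, 49), 3, byrow = TRUE,
                  dimnames = list(1:3, c("A", "B")))
  cmp <- compare_iterations(homog)
  expect_equal(nrow(cmp$z_tests), 0L)
  expect_equal(unique(cmp$letters$letters), "a")

  # one taxon shifts 10% -> 30% between two iterations of 1000 reads
  shift <- matrix(c(100, 900, 300, 700), 2, byrow = TRUE,
                  dimnames = list(1:2, c("Bacteroidetes", "other")))
  cmp2 <- compare_iterations(shift)
  expect_lt(cmp2$homogeneity$p_value, 0.05)
  sig <- cmp2$z_tests[cmp2$z_tests$q_value < 0.05, ]
  expect_true("Bacteroidetes" %in% sig$taxon)
  expect_equal(sort(unique(cmp2$letters$letters)), c("a", "b"))

  # letter partition is invariant to relabelling iterations
  m <- matrix(c(100, 900, 300, 700, 110, 890), 3, byrow = TRUE,
              dimnames = list(c("1", "2", "3"), c("A", "B")))
  part1 <- compare_iterations(m)$letters
  perm <- m[c(2, 1, 3), ]
  rownames(perm) <- c("1", "2", "3")
  part2 <- compare_iterations(perm)$letters
  same_group1 <- outer(part1$letters, part1$letters, Vectorize(function(a, b)
    length(intersect(strsplit(a, "")[[1]], strsplit(b, "")[[1]])) > 0))
  same_group2 <- outer(part2$letters, part2$letters, Vectorize(function(a, b)
    length(intersect(strsplit(a, "")[[1]], strsplit(b, "")[[1]])) > 0))
  expect_equal(same_group1[c(2, 1, 3), c(2, 1, 3)], same_group2,
               ignore_attr = TRUE)
})

test_that("tidy and glance expose the comparison results", {
  shift <- matrix(c(100, 900, 300, 700), 2, byrow = TRUE,
                  dimnames = list(1:2, c("A", "B")))
  cmp <- compare_iterations(shift)
  expect_equal(tidy(cmp), cmp$z_tests)
  g <- glance(cmp)
  expect_equal(g$n_z_tests, nrow(cmp$z_tests))
  expect_true(g$n_significant >= 1)
})
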