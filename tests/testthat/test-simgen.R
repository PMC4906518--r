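test_that("simulate_subject_pair plants exactly the requested substitutions", {
  pair <- simulate_subject_pair(seed = 1)
  expect_equal(nrow(pair$snps), 152L)
  d <- strsplit(pair$genomes$sequence[[1]], "")[[1]]
  r <- strsplit(pair$genomes$sequence[[2]], "")[[1]]
  expect_equal(sum(d != r), 152L)           # Hamming distance == planted count
  expect_equal(which(d != r) - 1L, pair$snps$pos)
  expect_true(all(pair$snps$donor_allele != pair$snps$recipient_allele))

  none <- simulate_subject_pair(
    subject_pair_profile(n_mito_substitutions = 0), seed = 2)
  expect_equal(none$genomes$sequence[[1]], none$genomes$sequence[[2]])
  expect_equal(nrow(none$snps), 0L)

  expect_error(subject_pair_profile(mito_genome_length = 100,
                                    n_mito_substitutions = 101),
               class = "cfchimera_parameter_error")
})

test_that("generators are deterministic under a fixed seed", {
  expect_identical(simulate_subject_pair(seed = 42),
                   simulate_subject_pair(seed = 42))
  pair <- make_test_pair()
  prof <- fragment_pool_profile("mito")
  expect_identical(simulate_fragment_pool(pair, prof, n = 500, seed = 9),
                   simulate_fragment_pool(pair, prof, n = 500, seed = 9))
  expect_identical(simulate_pileup(pair$genomes[1, ], 20, 0.01, seed = 5),
                   simulate_pileup(pair$genomes[1, ], 20, 0.01, seed = 5))
  expect_identical(simulate_hit_tables(default_community(5), seed = 3),
                   simulate_hit_tables(default_community(5), seed = 3))
  expect_identical(simulate_dpcr(default_dpcr_params("mito"), seed = 8),
                   simulate_dpcr(default_dpcr_params("mito"), seed = 8))
})

test_that("simulate_pileup matches its generating genome and error budget", {
  pair <- make_test_pair(L = 2000L, n_snps = 10L)
  pu <- simulate_pileup(pair$genomes[1, ], depth = 100, error_rate = 0,
                        seed = 3)
  counts <- as.matrix(pu[c("A", "C", "G", "T")])
  major <- c("A", "C", "G", "T")[max.col(counts)]
  truth <- strsplit(pair$genomes$sequence[[1]], "")[[1]]
  expect_equal(major, truth)

  zero <- simulate_pileup(pair$genomes[1, ], depth = 0, seed = 4)
  expect_equal(sum(as.matrix(zero[c("A", "C", "G", "T")])), 0)

  # expected error bases ~ L * depth * error_rate (Poisson-scale noise)
  pu2 <- simulate_pileup(pair$genomes[1, ], depth = 100, error_rate = 0.005,
                         seed = 5)
  counts2 <- as.matrix(pu2[c("A", "C", "G", "T")])
  idx <- cbind(seq_along(truth), match(truth, c("A", "C", "G", "T")))
  n_err <- sum(counts2) - sum(counts2[idx])
  expected <- 2000 * 100 * 0.005
  expect_lt(abs(n_err - expected), 5 * sqrt(expected))
})

test_that("fragment pools respect planted origin labels at SNP sites", {
  pair <- make_test_pair()
  all_recip <- simulate_fragment_pool(
    pair, fragment_pool_profile("mito", donor_fraction = 0), n = 400,
    seed = 6)
  asg <- assign_fragments(all_recip$fragments, pair$snps)
  expect_true(all(asg$assignment %in% c("recipient", "uninformative")))

  all_donor <- simulate_fragment_pool(
    pair, fragment_pool_profile("mito", donor_fraction = 1), n = 400,
    seed = 7)
  asg2 <- assign_fragments(all_donor$fragments, pair$snps)
  expect_true(all(asg2$assignment %in% c("donor", "uninformative")))
})

test_that("nuclear pools hit the planted short-fraction and stay above 20 bp", {
  pool <- simulate_fragment_pool(NULL, fragment_pool_profile("nuclear"),
                                 n = 50000, seed = 8)
  frac <- mean(pool$fragments$length < 100)
  expect_lt(abs(frac - 0.2054), 0.01)
  expect_true(all(pool$fragments$length >= 20))
  expect_true(all(pool$fragments$end > pool$fragments$start))
  expect_equal(pool$fragments$length,
               as.integer(pool$fragments$end - pool$fragments$start))
})

test_that("oversized fragments are resampled up to a cap, then error", {
  tiny <- simulate_subject_pair(
    subject_pair_profile(mito_genome_length = 25L, n_mito_substitutions = 2L),
    seed = 1)
  expect_error(
    simulate_fragment_pool(tiny, fragment_pool_profile("mito"), n = 5,
                           seed = 2),
    class = "cfchimera_simulation_error")
})

test_that("capture filtering is a per-fragment Bernoulli thinning", {
  pool <- simulate_fragment_pool(make_test_pair(),
                                 fragment_pool_profile("mito"),
                                 n = 2000, seed = 10)
  everything <- capture_model("ssDNA", midpoint = -1e6, plateau = 1)
  kept <- apply_capture(pool$fragments, everything, seed = 1)
  expect_equal(nrow(kept), nrow(pool$fragments))

  nothing <- capture_model("dsDNA", midpoint = 1e6)
  none <- apply_capture(pool$fragments, nothing, seed = 1)
  expect_equal(nrow(none), 0L)

  partial <- apply_capture(pool$fragments, capture_model("dsDNA"), seed = 2)
  log <- attr(partial, "capture_log")
  expect_equal(log$retained + log$dropped, log$input)   # conservation
  expect_equal(log$input, nrow(pool$fragments))
})

test_that("capture probability is non-decreasing and ssDNA favors short DNA", {
  grid <- seq(20, 400)
  for (m in list(capture_model("ssDNA"), capture_model("dsDNA"))) {
    p <- capture_probability(m, grid)
    expect_true(all(p >= 0 & p <= 1))
    expect_true(all(diff(p) >= 0))
  }

  # mito-heavy pool: short mito + mixed nuclear fragments
  pair <- make_test_pair()
  mito <- simulate_fragment_pool(pair, fragment_pool_profile("mito"),
                                 n = 50000, seed = 11)$fragments
  nuc <- simulate_fragment_pool(NULL, fragment_pool_profile("nuclear"),
                                n = 50000, seed = 12)$fragments
  pool <- dplyr::bind_rows(mito, nuc)
  ratio <- function(x) sum(x$compartment == "mito") /
    sum(x$compartment == "nuclear")
  ss <- apply_capture(pool, capture_model("ssDNA"), seed = 13)
  ds <- apply_capture(pool, capture_model("dsDNA"), seed = 14)
  expect_gt(ratio(ss), ratio(ds))
})

test_that("simulated dPCR assays follow the fragmentation-model expectations", {
  assay <- simulate_dpcr(default_dpcr_params("mito"), target = "mito",
                         seed = 15)
  mu <- attr(assay, "expected")
  expect_true(all(diff(mu) < 0))            # strictly decreasing over panel
  expect_true(all(abs(assay$copies - mu) < 6 * sqrt(mu)))  # Poisson scale

  beyond <- expected_abundance(
    frag_dist_params("exponential", mean = 80, C0 = 10), 2500)
  expect_equal(beyond, 0)
})

test_that("hit-table simulation matches community structure", {
  empty <- simulate_hit_tables(default_community(0), seed = 1)
  expect_equal(nrow(empty$ss), 0L)
  expect_equal(nrow(empty$ds), 0L)

  tabs <- simulate_hit_tables(default_community(10), ss_enrichment = 1,
                              seed = 2)
  # same expectation for both preps at enrichment 1
  expect_equal(tabs$ss$taxon, tabs$ds$taxon)
  expect_lt(abs(log(sum(tabs$ss$read_count) / sum(tabs$ds$read_count))), 0.05)
})
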