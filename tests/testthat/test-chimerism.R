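snp_fixture <- tibble::tibble(
  ref = "chrM", pos = c(10L, 20L),
  donor_allele = c("A", "C"), recipient_allele = c("G", "T"))

frag_row <- function(start, end, bases, id = "f1") {
  tibble::tibble(id = id, ref = "chrM", start = start, end = end,
                 length = end - start, sample = "s1", compartment = "mito",
                 bases = bases)
}

test_that("assign_fragment follows the allele-matching rules", {
  # spans SNP at 10 only; donor allele A at offset 10
  donor_frag <- frag_row(5, 15, paste0(strrep("T", 5), "A", strrep("T", 4)))
  expect_equal(assign_fragment(donor_frag, snp_fixture), "donor")

  # no SNP overlapped
  expect_equal(assign_fragment(frag_row(30, 60, strrep("A", 30)), snp_fixture),
               "uninformative")

  # two SNPs, one donor + one recipient allele -> ambiguous
  b <- strsplit(strrep("G", 20), "")[[1]]
  b[10 - 5 + 1] <- "A"   # donor at pos 10
  b[20 - 5 + 1] <- "T"   # recipient at pos 20
  expect_equal(assign_fragment(frag_row(5, 25, paste(b, collapse = "")),
                               snp_fixture), "ambiguous")

  # third allele at a SNP -> ambiguous
  b[20 - 5 + 1] <- "G"
  expect_equal(assign_fragment(frag_row(5, 25, paste(b, collapse = "")),
                               snp_fixture), "ambiguous")

  # N at a SNP -> ambiguous
  b[10 - 5 + 1] <- "N"
  b[20 - 5 + 1] <- "C"
  expect_equal(assign_fragment(frag_row(5, 25, paste(b, collapse = "")),
                               snp_fixture), "ambiguous")
})

test_that("half-open interval arithmetic includes the terminal base", {
  # SNP at 10: fragment [10, 11) covers it, fragment [5, 10) does not
  expect_equal(assign_fragment(frag_row(10, 11, "A"), snp_fixture), "donor")
  expect_equal(assign_fragment(frag_row(5, 10, "GGGGG"), snp_fixture),
               "uninformative")
})

test_that("missing bases on an informative fragment is an input error", {
  frag <- frag_row(5, 15, NA_character_)
  expect_error(assign_fragments(frag, snp_fixture),
               class = "cfchimera_input_error")
  # but a fragment overlapping nothing needs no bases
  expect_equal(assign_fragment(frag_row(50, 80, NA_character_), snp_fixture),
               "uninformative")
})

test_that("assignment agrees with a brute-force SNP re-scan", {
  pair <- make_test_pair(seed = 50)
  pool <- simulate_fragment_pool(pair, fragment_pool_profile("mito"),
                                 n = 1000, seed = 51)
  withr::local_seed(52)
  frags <- corrupt_bases(pool$fragments, rate = 0.03)
  fast <- assign_fragments(frags, pair$snps)$assignment
  slow <- brute_force_assign(frags, pair$snps)
  expect_equal(fast, slow)
  # label conservation
  expect_equal(sum(table(fast)), nrow(frags))
})

test_that("tally_sample computes donor fractions and the sample filter", {
  lab <- function(labels) tibble::tibble(
    sample = "s1", assignment = labels)
  t1 <- tally_sample(lab(c(rep("donor", 5), rep("recipient", 45))))
  expect_equal(t1$donor_fraction, 0.10)
  expect_true(t1$passed_filter)

  # 19 informative fragments -> filtered, fraction undefined
  t2 <- tally_sample(lab(c(rep("donor", 2), rep("recipient", 17),
                           rep("ambiguous", 30))))
  expect_false(t2$passed_filter)
  expect_true(is.na(t2$donor_fraction))

  t3 <- tally_sample(lab(rep("recipient", 30)))
  expect_equal(t3$donor_fraction, 0)

  t0 <- tally_sample(lab(character(0)))
  expect_equal(t0$n_total, 0L)
  expect_false(t0$passed_filter)

  counts <- t1[c("n_donor", "n_recipient", "n_ambiguous", "n_uninformative")]
  expect_equal(sum(unlist(counts)), t1$n_total)
})

test_that("adding a donor fragment never decreases the donor fraction", {
  withr::local_seed(60)
  for (i in 1:25) {
    labels <- sample(c("donor", "recipient", "ambiguous", "uninformative"),
                     60, replace = TRUE, prob = c(0.1, 0.5, 0.2, 0.2))
    base <- tally_sample(tibble::tibble(sample = "s", assignment = labels),
                         min_informative = 1)
    more <- tally_sample(tibble::tibble(sample = "s",
                                        assignment = c(labels, "donor")),
                         min_informative = 1)
    expect_gte(more$donor_fraction, base$donor_fraction)
  }
})

test_that("donor-fraction estimates recover planted fractions", {
  pair <- simulate_subject_pair(seed = 70)
  for (d in c(0.01, 0.095, 0.5)) {
    pool <- simulate_fragment_pool(
      pair, fragment_pool_profile("mito", donor_fraction = d), n = 50000,
      seed = round(1000 * d) + 7)
    tally <- tally_sample(assign_fragments(pool$fragments, pair$snps))
    n_inf <- tally$n_donor + tally$n_recipient
    expect_gte(n_inf, 20000)
    expect_lte(abs(tally$donor_fraction - d), 3 * sqrt(d * (1 - d) / n_inf))
  }
})

test_that("donor_fraction_series orders by time and keeps filtered samples", {
  tallies <- dplyr::bind_rows(
    tibble::tibble(sample = "s2", donor_fraction = 0.05, passed_filter = TRUE),
    tibble::tibble(sample = "s3", donor_fraction = NA_real_,
                   passed_filter = FALSE),
    tibble::tibble(sample = "s1", donor_fraction = 0.12, passed_filter = TRUE))
  series <- donor_fraction_series(tallies, time = c(14, 30, 7))
  expect_equal(series$sample, c("s1", "s2", "s3"))
  expect_equal(series$time, c(7, 14, 30))
  expect_equal(sum(!series$passed_filter), 1L)

  expect_equal(nrow(donor_fraction_series(tallies[0, ], time = numeric(0))), 0L)
  expect_error(donor_fraction_series(tallies[c(1, 1), ], time = c(1, 1)),
               class = "cfchimera_validation_error")
})

test_that("compare_fraction_pairs measures agreement on matched samples", {
  mk <- function(fracs, passed = TRUE) tibble::tibble(
    sample = paste0("s", seq_along(fracs)), time = seq_along(fracs),
    donor_fraction = fracs, passed_filter = passed)
  a <- mk(c(0.01, 0.05, 0.1, 0.2))
  expect_equal(compare_fraction_pairs(a, a)$pearson_r, 1.0)
  doubled <- mk(2 * c(0.01, 0.05, 0.1, 0.2))
  expect_equal(compare_fraction_pairs(a, doubled)$pearson_r, 1.0)

  too_few <- compare_fraction_pairs(mk(c(0.1, 0.2)), mk(c(0.1, 0.3)))
  expect_true(is.na(too_few$pearson_r))
  expect_match(too_few$status, "fewer than 3")

  withr::local_seed(80)
  x <- mk(rnorm(200)); y <- mk(rnorm(200))
  expect_lt(abs(compare_fraction_pairs(x, y)$pearson_r), 0.2)
})

test_that("build_nuclear_snpset keeps homozygous-different sites only", {
  g <- tibble::tibble(
    ref = "nuclear", pos = c(100L, 200L, 300L, 400L),
    donor_genotype = c("AA", "AG", "AA", "CC"),
    recipient_genotype = c("GG", "GG", "AA", "TT"))
  snps <- build_nuclear_snpset(g)
  expect_equal(snps$pos, c(100L, 400L))
  expect_equal(snps$donor_allele, c("A", "C"))
  expect_equal(snps$recipient_allele, c("G", "T"))
  skipped <- attr(snps, "skipped")
  expect_equal(unname(skipped["heterozygous"]), 1)
  expect_equal(unname(skipped["not_informative"]), 1)

  # the emitted set drives the shared assignment path
  frag <- frag_row(95, 105, strrep("A", 10))
  frag$ref <- "nuclear"; frag$compartment <- "nuclear"
  expect_equal(assign_fragment(frag, snps), "donor")
})
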