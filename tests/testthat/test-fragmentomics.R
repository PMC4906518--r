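lengths_to_fragments <- function(lengths, compartment = "mito",
                                 sample = "s1") {
  tibble::tibble(
    id = sprintf("f%04d", seq_along(lengths)), ref = "chrM", start = 0,
    end = lengths, length = as.integer(lengths), sample = sample,
    compartment = compartment)
}

test_that("length_histogram bins exactly and normalizes as asked", {
  fr <- lengths_to_fragments(c(50, 50, 166))
  h <- length_histogram(fr)
  expect_equal(h$length, c(50L, 166L))
  expect_equal(h$count, c(2L, 1L))
  expect_equal(sum(h$count), nrow(fr))         # conservation

  hf <- length_histogram(fr, normalization = "frequency")
  expect_equal(hf$value, c(2 / 3, 1 / 3))
  expect_equal(sum(hf$value), 1)

  both <- dplyr::bind_rows(
    lengths_to_fragments(rep(60, 10), compartment = "mito"),
    lengths_to_fragments(rep(166, 1000), compartment = "nuclear"))
  hr <- length_histogram(both, compartment = "mito",
                         normalization = "relative")
  expect_equal(hr$value, 10 / 1000)

  expect_error(length_histogram(fr[0, ], normalization = "frequency"),
               class = "cfchimera_undefined_error")
})

test_that("sub100_proportion uses a strict cut at 100 bp", {
  expect_equal(sub100_proportion(length_histogram(
    lengths_to_fragments(rep(99, 5)))), 1.0)
  expect_equal(sub100_proportion(length_histogram(
    lengths_to_fragments(rep(100, 5)))), 0.0)
  mixed <- length_histogram(lengths_to_fragments(c(60, 99, 100, 166)))
  expect_equal(sub100_proportion(mixed), 0.5)
})

test_that("gc_by_length_class splits at the cut and tests the difference", {
  fr <- dplyr::bind_rows(
    lengths_to_fragments(rep(4, 3)), lengths_to_fragments(rep(120, 3)))
  fr$bases <- c(rep("GGCC", 3), rep(strrep("AT", 60), 3))
  res <- gc_by_length_class(fr)
  expect_equal(res$gc_sub, 1.0)
  expect_equal(res$gc_super, 0.0)
  expect_lt(res$p_value, 0.2)

  # identical GC in both classes: direction-free p
  fr$bases <- c(rep("GCAT", 3), rep(strrep("GCAT", 30), 3))
  same <- suppressWarnings(gc_by_length_class(fr))
  expect_gt(same$p_value, 0.9)

  # empty class: means reported, p undefined
  sub_only <- fr[fr$length < 100, ]
  res2 <- gc_by_length_class(sub_only)
  expect_true(is.na(res2$p_value))
  expect_equal(res2$gc_sub, 0.5)
})

test_that("synthetic pools reproduce the class-conditional GC model", {
  pool <- simulate_fragment_pool(NULL, fragment_pool_profile("nuclear"),
                                 n = 20000, seed = 90)
  res <- gc_by_length_class(pool$fragments)
  expect_lt(abs(res$gc_sub - 0.435), 0.01)
  expect_lt(abs(res$gc_super - 0.409), 0.01)
  expect_lt(res$p_value, 1e-5)
})

test_that("smooth_running_mean uses truncated centered windows", {
  expect_equal(smooth_running_mean(rep(3, 8)), rep(3, 8))        # constants
  expect_equal(smooth_running_mean(c(0, 0, 1, 0, 0), k = 5),
               c(1 / 3, 1 / 4, 1 / 5, 1 / 4, 1 / 3))
  ramp <- 1:9
  expect_equal(smooth_running_mean(ramp)[3:7], 3:7)              # interior
  expect_equal(length(smooth_running_mean(1:7, k = 3)), 7L)
  expect_equal(smooth_running_mean(c(5), k = 1), 5)
  expect_error(smooth_running_mean(1:5, k = 4),
               class = "cfchimera_parameter_error")
  expect_error(smooth_running_mean(1:5, k = 0),
               class = "cfchimera_parameter_error")
})

test_that("modal_lengths recovers planted modes", {
  withr::local_seed(91)
  uni <- lengths_to_fragments(round(rnorm(50000, 166, 8)))
  m1 <- modal_lengths(length_histogram(uni))
  expect_lte(abs(m1$length[[1]] - 166), 2)

  bimodal <- lengths_to_fragments(c(
    20 + round(rgamma(20000, shape = 16, scale = 8 / 3)),
    round(rnorm(30000, 166, 8))))
  m2 <- modal_lengths(length_histogram(bimodal))
  expect_lte(min(abs(m2$length - 60)), 3)
  expect_lte(min(abs(m2$length - 166)), 2)
  expect_true(all(diff(m2$height) <= 0))     # descending height order

  single <- modal_lengths(length_histogram(lengths_to_fragments(77)))
  expect_equal(single$length, 77L)
})

test_that("median_shift_test measures the planted shift", {
  withr::local_seed(92)
  x <- 20 + rgamma(1855, shape = 16, scale = 8 / 3)
  same <- median_shift_test(x, x, n_resamples = 200, seed = 1)
  expect_equal(same$delta_median, 0)
  expect_true(same$p_value > 0 && same$p_value <= 1)

  shifted <- median_shift_test(x - 10, x, n_resamples = 200, seed = 1)
  expect_equal(shifted$delta_median, -10)

  expect_error(median_shift_test(1:10, 1:5),
               class = "cfchimera_parameter_error")
  expect_error(median_shift_test(numeric(0), 1:5),
               class = "cfchimera_parameter_error")

  a <- median_shift_test(x[1:265], x, n_resamples = 500, seed = 7)
  b <- median_shift_test(x[1:265], x, n_resamples = 500, seed = 7)
  expect_identical(a$resample_medians, b$resample_medians)
  expect_equal(a$spread, sd(a$resample_medians))
})
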