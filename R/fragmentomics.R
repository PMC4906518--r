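# Fragment-length and GC analyses.

#' Integer fragment-length histogram
#'
#' Bins fragment lengths at 1 bp resolution. Normalization modes: `counts`
#' (raw), `frequency` (heights sum to 1), or `relative` (heights divided by
#' the total nuclear fragment count of the same table, the convention used
#' to compare mitochondrial/microbial profiles against the nuclear
#' compartment).
#'
#' @param fragments Fragment tibble with a `length` column (or `start`/
#'   `end`).
#' @param compartment Optional compartment label to select before binning.
#' @param normalization `"counts"`, `"frequency"` or `"relative"`.
#' @return A tibble of class `length_dist` with columns `length`, `count`,
#'   `value` (normalized height) and attributes `n`, `normalization`,
#'   `reference_n`.
#' @export
length_histogram <- function(fragments,
                             compartment = NULL,
                             normalization = c("counts", "frequency",
                                               "relative")) {
  normalization <- match.arg(normalization)
  if (!"length" %in% names(fragments)) {
    fragments$length <- fragments$end - fragments$start
  }
  reference_n <- sum(fragments$compartment == "nuclear")
  if (!is.null(compartment)) {
    fragments <- fragments[fragments$compartment == compartment, , drop = FALSE]
  }
  n <- nrow(fragments)
  if (n == 0L && normalization == "frequency") {
    abort("frequency normalization is undefined for an empty selection",
          class = "cfchimera_undefined_error")
  }
  if (normalization == "relative" && reference_n == 0L) {
    abort("relative normalization requires nuclear fragments in the table",
          class = "cfchimera_undefined_error")
  }
  tab <- table(as.integer(fragments$length))
  out <- tibble(length = as.integer(names(tab)), count = as.integer(tab))
  out$value <- switch(normalization,
    counts = as.double(out$count),
    frequency = out$count / n,
    relative = out$count / reference_n)
  structure(out, class = c("length_dist", class(out)),
            n = n, normalization = normalization, reference_n = reference_n)
}

#' Proportion of fragments shorter than a length cut
#'
#' Fraction of fragments with length strictly below `cut` (default 100 bp;
#' fragments of exactly 100 bp belong to the super-100 class).
#'
#' @param dist A `length_dist` from [length_histogram()], or a fragment
#'   tibble with a `length` column.
#' @param cut Length cut in bp.
#' @return The sub-`cut` fraction.
#' @export
sub100_proportion <- function(dist, cut = 100) {
  if (inherits(dist, "length_dist")) {
    total <- sum(dist$count)
    if (total == 0L) {
      abort("sub-100 proportion is undefined for an empty distribution",
            class = "cfchimera_undefined_error")
    }
    return(sum(dist$count[dist$length < cut]) / total)
  }
  len <- dist$length %||% (dist$end - dist$start)
  if (length(len) == 0L) {
    abort("sub-100 proportion is undefined for an empty selection",
          class = "cfchimera_undefined_error")
  }
  mean(len < cut)
}

#' GC content by fragment-length class
#'
#' Computes per-fragment GC fraction (`(G + C) / length`), splits fragments
#' at the length cut, and compares the two classes with a two-sided
#' Mann-Whitney U test.
#'
#' @param fragments Fragment tibble with `bases` and `length` columns.
#' @param cut Length cut in bp (default 100; sub class is strictly below).
#' @return A one-row tibble with `gc_sub`, `gc_super`, `n_sub`, `n_super`
#'   and `p_value` (`NA` when either class is empty).
#' @export
gc_by_length_class <- function(fragments, cut = 100) {
  validate_fragments(fragments, require_bases = TRUE)
  len <- fragments$length %||% (fragments$end - fragments$start)
  gc <- gc_fraction(fragments$bases)
  sub <- gc[len < cut]
  super <- gc[len >= cut]
  p <- if (length(sub) > 0L && length(super) > 0L) {
    suppressWarnings(wilcox.test(sub, super, alternative = "two.sided")$p.value)
  } else {
    NA_real_
  }
  # complete ties leave the normal approximation undefined; no detectable
  # difference is reported as p = 1
  if (is.nan(p)) p <- 1
  tibble(gc_sub = if (length(sub)) mean(sub) else NA_real_,
         gc_super = if (length(super)) mean(super) else NA_real_,
         n_sub = length(sub), n_super = length(super), p_value = p)
}

#' Centered running-mean smoothing
#'
#' Running mean over a centered window of `k` bins; windows are truncated
#' at the series edges, so the output has the input's length.
#'
#' @param x Numeric series.
#' @param k Odd window width >= 1 (default 5, i.e. each bin averaged with
#'   its five nearest neighbors' window).
#' @return Smoothed numeric series of the same length.
#' @export
smooth_running_mean <- function(x, k = 5) {
  if (length(k) != 1L || k < 1 || k %% 2 == 0) {
    abort("`k` must be a single odd integer >= 1",
          class = "cfchimera_parameter_error")
  }
  n <- length(x)
  if (n == 0L) return(x)
  half <- (k - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Modal fragment lengths of a histogram
#'
#' Smooths the dense (zero-filled) histogram with a centered running mean
#' and reports local maxima, ordered by descending smoothed height; ties
#' between adjacent equal-height bins are broken toward the smaller length.
#'
#' @param dist A `length_dist` from [length_histogram()].
#' @param window Odd smoothing window in bins (default 5).
#' @param min_height Minimum smoothed height (as a fraction of the maximum)
#'   for a mode to be reported; suppresses noise maxima.
#' @return A tibble with `length` and `height`, one row per mode.
#' @export
modal_lengths <- function(dist, window = 5, min_height = 0.05) {
  stopifnot(inherits(dist, "length_dist"))
  if (nrow(dist) == 0L) {
    abort("modal lengths are undefined for an empty distribution",
          class = "cfchimera_undefined_error")
  }
  grid <- tibble(length = seq(min(dist$length), max(dist$length)))
  grid <- dplyr::left_join(grid, dist[c("length", "count")], by = "length")
  grid$count[is.na(grid$count)] <- 0L
  s <- smooth_running_mean(grid$count, k = window)
  n <- length(s)
  if (n == 1L) return(tibble(length = grid$length, height = s))
  left <- c(-Inf, s[-n])
  right <- c(s[-1], -Inf)
  # strictly above the left neighbor, at least the right: plateaus and
  # adjacent ties resolve toward the smaller length
  is_max <- s > left & s >= right & s >= min_height * max(s)
  out <- tibble(length = grid$length[is_max], height = s[is_max])
  out[order(-out$height, out$length), , drop = FALSE]
}

#' Resampling median-shift test for donor versus recipient fragment length
#'
#' Compares the median donor fragment length to the median of the full
#' recipient set. `n_resamples` subsamples of size `n_donor` are drawn
#' without replacement from the recipient lengths; the observed shift is
#' `median(donor) - median(recipient)`, the resample spread is the standard
#' deviation of the subsample medians, and the two-sided empirical p-value
#' is the fraction of subsample medians at least as far from the recipient
#' median as the donor median, with an add-one continuity correction.
#'
#' @param donor_lengths,recipient_lengths Numeric fragment lengths;
#'   `length(recipient_lengths) >= length(donor_lengths) >= 1`.
#' @param n_resamples Number of subsamples (default 10000).
#' @param seed Optional integer seed.
#' @return An object of class `median_shift`: list with `delta_median`,
#'   `spread`, `p_value`, `n_donor`, `n_recipient`, `n_resamples`, `seed`,
#'   and the `resample_medians`.
#' @export
median_shift_test <- function(donor_lengths, recipient_lengths,
                              n_resamples = 10000, seed = NULL) {
  n_d <- length(donor_lengths)
  n_r <- length(recipient_lengths)
  if (n_d < 1L) {
    abort("at least one donor fragment is required",
          class = "cfchimera_parameter_error")
  }
  if (n_r < n_d) {
    abort("the recipient set must be at least as large as the donor set",
          class = "cfchimera_parameter_error")
  }
  assert_scalar_number(n_resamples, "n_resamples", min = 1)
  local_seed(seed)

  m_recipient <- median(recipient_lengths)
  m_donor <- median(donor_lengths)
  resample_medians <- vapply(seq_len(n_resamples), function(i) {
    median(recipient_lengths[sample.int(n_r, n_d)])
  }, numeric(1))

  t_obs <- abs(m_donor - m_recipient)
  t_null <- abs(resample_medians - m_recipient)
  p <- (1 + sum(t_null >= t_obs)) / (n_resamples + 1)

  structure(list(
    delta_median = m_donor - m_recipient,
    spread = sd(resample_medians),
    p_value = p,
    n_donor = n_d, n_recipient = n_r,
    n_resamples = as.integer(n_resamples),
    seed = seed,
    donor_median = m_donor,
    recipient_median = m_recipient,
    resample_medians = resample_medians
  ), class = "median_shift")
}

#' @export
print.median_shift <- function(x, ...) {
  cat("Resampling median-shift test\n")
  cat(sprintf("  donor median %.1f bp vs recipient median %.1f bp (n = %d vs %d)\n",
              x$donor_median, x$recipient_median, x$n_donor, x$n_recipient))
  cat(sprintf("  delta median: %+.1f bp (resample spread %.2f bp)\n",
              x$delta_median, x$spread))
  cat(sprintf("  empirical two-sided p = %.4g (%d resamples)\n",
              x$p_value, x$n_resamples))
  invisible(x)
}
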