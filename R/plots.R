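# ggplot2 displays for each result type.

#' Plot a fragment-length histogram
#'
#' @param object A `length_dist` from [length_histogram()].
#' @param smooth Optional odd window width; when given, a running-mean
#'   smoothed profile is overlaid.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.length_dist <- function(object, smooth = NULL, ...) {
  norm <- attr(object, "normalization")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$length, y = .data$value)) +
    ggplot2::geom_col(width = 1, fill = "grey35") +
    ggplot2::labs(x = "fragment length (bp)",
                  y = switch(norm, counts = "fragments",
                             frequency = "frequency",
                             relative = "frequency relative to nuclear")) +
    ggplot2::theme_minimal()
  if (!is.null(smooth)) {
    grid <- tibble(length = seq(min(object$length), max(object$length)))
    grid <- dplyr::left_join(grid, object[c("length", "value")], by = "length")
    grid$value[is.na(grid$value)] <- 0
    grid$smoothed <- smooth_running_mean(grid$value, k = smooth)
    p <- p + ggplot2::geom_line(data = grid,
                                ggplot2::aes(y = .data$smoothed),
                                color = "firebrick", linewidth = 0.7)
  }
  p
}

#' Plot the resampling median-shift result
#'
#' Histogram of subsample medians with the recipient median (dashed) and
#' the observed donor median (solid).
#'
#' @param object A `median_shift` from [median_shift_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.median_shift <- function(object, ...) {
  df <- tibble(median = object$resample_medians)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", color = "white") +
    ggplot2::geom_vline(xintercept = object$recipient_median,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$donor_median, color = "firebrick") +
    ggplot2::labs(x = "subsample median fragment length (bp)", y = "resamples",
                  subtitle = sprintf("delta median %+.1f bp, p = %.3g",
                                     object$delta_median, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot a dPCR amplicon-panel fit
#'
#' Measured copies (points) and the fitted fragmentation-model curve on a
#' log scale.
#'
#' @param object A `dpcr_fit` from [fit_assay()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dpcr_fit <- function(object, ...) {
  pts <- object$fitted
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$amplicon_length)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "amplicon length (bp)", y = "copies",
                  subtitle = paste0(object$family, " family; ", object$status)) +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- tibble(amplicon_length = seq(min(pts$amplicon_length),
                                         max(pts$amplicon_length),
                                         length.out = 120))
    grid$fitted <- expected_abundance(object$params, grid$amplicon_length)
    p <- p + ggplot2::geom_line(data = grid,
                                ggplot2::aes(y = .data$fitted),
                                color = "firebrick")
  }
  p
}

#' Plot a preparation comparison
#'
#' Shared detection events as ssDNA versus dsDNA relative coverage on
#' log-log axes, with the identity line.
#'
#' @param object A `prep_comparison` from [compare_preps()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prep_comparison <- function(object, ...) {
  ggplot2::ggplot(object$events,
                  ggplot2::aes(x = .data$coverage_ds, y = .data$coverage_ss)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "relative coverage (dsDNA prep)",
                  y = "relative coverage (ssDNA prep)",
                  subtitle = sprintf(
                    "geometric-mean fold %.1f; Spearman rho %.2f",
                    object$fold_geometric, object$spearman_rho)) +
    ggplot2::theme_minimal()
}

#' Plot a donor-fraction time series
#'
#' @param series Series tibble from [donor_fraction_series()].
#' @return A ggplot object; samples failing the informative-fragment filter
#'   are drawn as open symbols.
#' @export
plot_donor_fraction_series <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(x = .data$time,
                                       y = .data$donor_fraction)) +
    ggplot2::geom_line(color = "grey60", na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$passed_filter), size = 2,
                        na.rm = TRUE) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "passed filter") +
    ggplot2::labs(x = "time post-transplant", y = "donor fraction") +
    ggplot2::theme_minimal()
}
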