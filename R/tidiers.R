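# broom-style tidiers for fitted objects.

#' @rdname fit_assay
#' @param x A `dpcr_fit` object.
#' @param ... Unused.
#' @export
tidy.dpcr_fit <- function(x, ...) {
  if (is.null(x$estimate)) {
    return(tibble(term = character(), estimate = double(),
                  std_error = double()))
  }
  terms <- names(x$estimate)
  se_log <- sqrt(pmax(diag(x$vcov_log), 0))
  # log-scale fit: delta-method standard errors on the natural scale;
  # meanlog is fitted on its own scale
  se <- abs(x$estimate) * se_log
  if ("meanlog" %in% terms) se[terms == "meanlog"] <- se_log[terms == "meanlog"]
  tibble(term = terms, estimate = unname(x$estimate), std_error = unname(se))
}

#' @rdname fit_assay
#' @export
glance.dpcr_fit <- function(x, ...) {
  tibble(family = x$family, converged = x$converged, status = x$status,
         n = x$n,
         sigma_log = if (x$converged) sd(x$fitted$residual_log) else NA_real_,
         mean_fragment_length = if (x$converged) frag_dist_mean(x$params) else NA_real_)
}

#' @rdname median_shift_test
#' @param x A `median_shift` object.
#' @param ... Unused.
#' @export
tidy.median_shift <- function(x, ...) {
  tibble(delta_median = x$delta_median, spread = x$spread,
         p_value = x$p_value, n_donor = x$n_donor,
         n_recipient = x$n_recipient, n_resamples = x$n_resamples)
}

#' @rdname median_shift_test
#' @export
glance.median_shift <- function(x, ...) tidy(x)

#' @rdname compare_preps
#' @param x A `prep_comparison` object.
#' @param ... Unused.
#' @export
tidy.prep_comparison <- function(x, ...) x$events

#' @rdname compare_preps
#' @export
glance.prep_comparison <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n_shared = nrow(x$events),
           fold_geometric = x$fold_geometric,
           fold_arithmetic = x$fold_arithmetic,
           spearman_rho = x$spearman_rho,
           mann_whitney_p = x$mann_whitney_p,
           status = x$status),
    x$overlap)
}
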