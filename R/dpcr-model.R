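# dPCR amplicon-length fragmentation model.
#
# Only fragments that fully span an amplicon amplify. Under random
# fragmentation, a fragment of length L contains max(L - a + 1, 0) intact
# start positions for an amplicon of length a, so the measured
# genome-equivalent concentration follows
#   C(a) = C0 * E[(L - a + 1)+] / E[L]
# where f(L) is the fragment-length density and C0 the concentration of
# intact loci extrapolated to zero amplicon length. C(a) is non-increasing
# in a and C(1) = C0 for any finite-mean family.

FRAG_FAMILIES <- c("exponential", "gamma", "lognormal")
INTEGRATION_RANGE <- c(1, 2000)

#' Fragment-length distribution parameters for the dPCR model
#'
#' @param family `"exponential"` (parameter `mean`), `"gamma"` (`shape`,
#'   `scale`) or `"lognormal"` (`meanlog`, `sdlog`).
#' @param C0 Amplitude: genome-equivalent copies at amplicon length
#'   extrapolated to zero.
#' @param ... Family parameters (see `family`); all scale/shape parameters
#'   must be positive.
#' @return A list of class `frag_dist_params`.
#' @examples
#' frag_dist_params("exponential", mean = 80, C0 = 1000)
#' @export
frag_dist_params <- function(family = FRAG_FAMILIES, C0 = 1, ...) {
  family <- match.arg(family)
  pars <- list(...)
  needed <- switch(family,
    exponential = "mean",
    gamma = c("shape", "scale"),
    lognormal = c("meanlog", "sdlog"))
  missing <- setdiff(needed, names(pars))
  if (length(missing) > 0L) {
    abort(sprintf("family '%s' requires parameter(s): %s", family,
                  paste(missing, collapse = ", ")),
          class = "cfchimera_parameter_error")
  }
  pos_pars <- setdiff(needed, "meanlog")
  for (p in pos_pars) assert_scalar_number(pars[[p]], p, min = 1e-9)
  assert_scalar_number(C0, "C0", min = 0)
  structure(list(family = family, params = pars[needed], C0 = C0),
            class = "frag_dist_params")
}

frag_density <- function(params) {
  p <- params$params
  switch(params$family,
    exponential = function(L) dexp(L, rate = 1 / p$mean),
    gamma = function(L) dgamma(L, shape = p$shape, scale = p$scale),
    lognormal = function(L) dlnorm(L, meanlog = p$meanlog, sdlog = p$sdlog))
}

integrate_safely <- function(f, lower, upper) {
  res <- tryCatch(
    integrate(f, lower, upper, rel.tol = 1e-9, subdivisions = 500L),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$value)) {
    abort("non-finite integral in fragmentation model",
          class = "cfchimera_numeric_error")
  }
  res$value
}

#' Mean fragment length implied by a parameter set
#'
#' Computed by numeric integration over the model's 1-2000 bp support.
#'
#' @param params A [frag_dist_params()].
#' @return Mean fragment length in bp.
#' @export
frag_dist_mean <- function(params) {
  stopifnot(inherits(params, "frag_dist_params"))
  f <- frag_density(params)
  num <- integrate_safely(function(L) L * f(L),
                          INTEGRATION_RANGE[1], INTEGRATION_RANGE[2])
  den <- integrate_safely(f, INTEGRATION_RANGE[1], INTEGRATION_RANGE[2])
  num / den
}

#' Expected dPCR abundance as a function of amplicon length
#'
#' Evaluates `C(a) = C0 * E[(L - a + 1)+] / E[L]` under the fragment-length
#' density, by numeric integration on 1-2000 bp. The curve is non-increasing
#' in `a` and equals `C0` at `a = 1`.
#'
#' @param params A [frag_dist_params()].
#' @param amplicon_length Amplicon lengths in bp (>= 1), vectorized.
#' @return Expected copies at each amplicon length.
#' @examples
#' p <- frag_dist_params("exponential", mean = 80, C0 = 1000)
#' expected_abundance(p, c(49, 100, 304))
#' @export
expected_abundance <- function(params, amplicon_length) {
  stopifnot(inherits(params, "frag_dist_params"))
  if (any(amplicon_length < 1)) {
    abort("amplicon lengths must be >= 1 bp", class = "cfchimera_parameter_error")
  }
  f <- frag_density(params)
  norm <- integrate_safely(function(L) L * f(L),
                           INTEGRATION_RANGE[1], INTEGRATION_RANGE[2])
  vapply(amplicon_length, function(a) {
    lo <- max(a - 1, INTEGRATION_RANGE[1])
    if (lo >= INTEGRATION_RANGE[2]) return(0)
    kern <- integrate_safely(function(L) pmax(L - a + 1, 0) * f(L),
                             lo, INTEGRATION_RANGE[2])
    params$C0 * kern / norm
  }, numeric(1))
}

#' Fit the fragmentation model to a dPCR amplicon panel
#'
#' Weighted least squares on log-scale abundances over the family parameters
#' and the amplitude `C0`, with weights proportional to the measured counts
#' (multiplicative noise across the panel's length range). Panels whose
#' measurements do not decrease over the panel (log-range below 5%) are
#' rejected as non-identifiable: a flat panel is incompatible with any
#' finite-mean fragment-length family.
#'
#' @param assay Assay tibble with columns `amplicon_length` and `copies`
#'   (one target; see [read_dpcr()] / [simulate_dpcr()]).
#' @param family Fragment-length family to fit.
#' @return An object of class `dpcr_fit`: list with `family`, `estimate`
#'   (named vector including `C0`), `vcov_log` (covariance of the
#'   log-parameters), `fitted` tibble, `converged`, `status`, `n`.
#' @export
fit_assay <- function(assay, family = FRAG_FAMILIES) {
  family <- match.arg(family)
  assert_columns(assay, c("amplicon_length", "copies"), "dPCR assay")
  if ("target" %in% names(assay) && length(unique(assay$target)) > 1L) {
    abort("fit one target at a time", class = "cfchimera_input_error")
  }
  a <- as.double(assay$amplicon_length)
  y <- as.double(assay$copies)
  if (length(a) < 3L) {
    abort("at least 3 panel points are required for fitting",
          class = "cfchimera_validation_error")
  }
  if (any(y <= 0)) {
    return(failed_fit(family, assay, "non-positive measurements"))
  }
  ly <- log(y)
  if (diff(range(ly)) < 0.05) {
    return(failed_fit(family, assay, "non-identifiable: no abundance gradient across the panel"))
  }
  slope <- unname(coef(lm(ly ~ a))[2])
  if (slope >= 0) {
    return(failed_fit(family, assay, "non-identifiable: abundance does not decrease with amplicon length"))
  }

  mean0 <- -1 / slope
  c0_0 <- exp(unname(coef(lm(ly ~ a))[1]) + slope)  # extrapolate to a = 1
  theta0 <- switch(family,
    exponential = c(log(c0_0), log(mean0)),
    gamma = c(log(c0_0), log(4), log(mean0 / 4)),
    lognormal = c(log(c0_0), log(mean0), log(0.6)))

  w <- y / sum(y)
  objective <- function(theta) {
    params <- theta_to_params(theta, family)
    mu <- tryCatch(expected_abundance(params, a), error = function(e) NULL)
    if (is.null(mu) || any(!is.finite(mu)) || any(mu <= 0)) return(1e10)
    sum(w * (ly - log(mu))^2)
  }
  fit <- optim(theta0, objective, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  fit <- optim(fit$par, objective, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-12))
  converged <- fit$convergence == 0 && is.finite(fit$value)
  params <- theta_to_params(fit$par, family)
  mu <- expected_abundance(params, a)

  n <- length(a)
  p <- length(fit$par)
  sigma2 <- fit$value / max(n - p, 1)
  vcov_log <- tryCatch(2 * sigma2 * solve(fit$hessian),
                       error = function(e) matrix(NA_real_, p, p))
  par_names <- c("C0", names(params$params))
  dimnames(vcov_log) <- list(par_names, par_names)

  structure(list(
    family = family,
    estimate = setNames(c(params$C0, unlist(params$params)), par_names),
    params = params,
    vcov_log = vcov_log,
    fitted = tibble(amplicon_length = a, observed = y, fitted = mu,
                    residual_log = ly - log(mu)),
    converged = converged,
    status = if (converged) "ok" else "optimizer did not converge",
    n = n
  ), class = "dpcr_fit")
}

theta_to_params <- function(theta, family) {
  switch(family,
    exponential = frag_dist_params("exponential", C0 = exp(theta[1]),
                                   mean = exp(theta[2])),
    gamma = frag_dist_params("gamma", C0 = exp(theta[1]),
                             shape = exp(theta[2]), scale = exp(theta[3])),
    lognormal = frag_dist_params("lognormal", C0 = exp(theta[1]),
                                 meanlog = theta[2], sdlog = exp(theta[3])))
}

failed_fit <- function(family, assay, status) {
  structure(list(
    family = family, estimate = NULL, params = NULL, vcov_log = NULL,
    fitted = tibble(amplicon_length = as.double(assay$amplicon_length),
                    observed = as.double(assay$copies),
                    fitted = NA_real_, residual_log = NA_real_),
    converged = FALSE, status = status, n = nrow(assay)
  ), class = "dpcr_fit")
}

#' @export
print.dpcr_fit <- function(x, ...) {
  cat("dPCR fragmentation-model fit (", x$family, " family)\n", sep = "")
  cat("status:", x$status, "\n")
  if (!is.null(x$estimate)) {
    cat("estimates:\n")
    print(round(x$estimate, 4))
  }
  invisible(x)
}

#' Genome-equivalent copy ratio between two fitted assays
#'
#' Ratio of the fitted `C0` amplitudes (intact-locus concentrations
#' extrapolated to zero amplicon length) of two assays, e.g. mitochondrial
#' over nuclear, with uncertainty propagated from both fits on the log
#' scale.
#'
#' @param fit_num,fit_den `dpcr_fit` objects for the numerator and
#'   denominator targets.
#' @return A one-row tibble with `estimate`, `std_error` and `status`;
#'   `estimate` is `NA` if either fit failed.
#' @export
copy_ratio <- function(fit_num, fit_den) {
  stopifnot(inherits(fit_num, "dpcr_fit"), inherits(fit_den, "dpcr_fit"))
  if (!fit_num$converged || !fit_den$converged) {
    return(tibble(estimate = NA_real_, std_error = NA_real_,
                  status = "undefined: at least one fit failed"))
  }
  ratio <- unname(fit_num$estimate["C0"] / fit_den$estimate["C0"])
  v <- fit_num$vcov_log["C0", "C0"] + fit_den$vcov_log["C0", "C0"]
  tibble(estimate = ratio,
         std_error = if (is.finite(v) && v >= 0) ratio * sqrt(v) else NA_real_,
         status = "ok")
}
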