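# Microbial hit filtering and relative genome coverage.

#' Filter microbial hits on identity and query coverage
#'
#' Retains rows with percent identity of at least `min_identity` across at
#' least `min_query_coverage` of the query bases (both thresholds
#' inclusive). Removal counts are recorded in the `removed` attribute.
#'
#' @param hits Hit tibble (see [read_hits()]).
#' @param min_identity Minimum mean percent identity (default 90).
#' @param min_query_coverage Minimum mean query-coverage fraction (default
#'   0.90).
#' @return The filtered hit tibble with attribute `removed`.
#' @export
filter_hits <- function(hits, min_identity = 90, min_query_coverage = 0.90) {
  validate_hits(hits)
  fail_ident <- hits$identity < min_identity
  fail_cov <- hits$query_coverage < min_query_coverage
  keep <- !fail_ident & !fail_cov
  out <- hits[keep, , drop = FALSE]
  attr(out, "removed") <- c(low_identity = sum(fail_ident),
                            low_coverage = sum(fail_cov & !fail_ident),
                            total = sum(!keep))
  out
}

#' Relative genome coverage of a taxon versus the human genome
#'
#' `(taxon_reads / taxon_genome_length) / (human_reads /
#' human_genome_length)`: per-base coverage of the microbial genome divided
#' by per-base coverage of the human genome in the same sequencing run
#' (read length cancels).
#'
#' @param taxon_reads Reads assigned to the taxon (vectorized).
#' @param taxon_genome_length Taxon genome length in bp.
#' @param human_reads Human-aligned reads in the same run.
#' @param human_genome_length Human genome length in bp (default 3.1e9).
#' @return Relative genomic coverage (dimensionless).
#' @export
relative_genome_coverage <- function(taxon_reads, taxon_genome_length,
                                     human_reads,
                                     human_genome_length = 3.1e9) {
  if (any(taxon_genome_length <= 0) || any(human_genome_length <= 0)) {
    abort("genome lengths must be > 0", class = "cfchimera_parameter_error")
  }
  if (any(human_reads <= 0)) {
    abort("relative coverage is undefined without human reads",
          class = "cfchimera_undefined_error")
  }
  (taxon_reads / taxon_genome_length) / (human_reads / human_genome_length)
}

#' Per-taxon relative abundance table from a hit table
#'
#' Applies [relative_genome_coverage()] to every row of a (typically
#' already filtered) hit table.
#'
#' @param hits Hit tibble.
#' @param human_reads Human-aligned read count for the same preparation.
#' @param human_genome_length Human genome length in bp.
#' @param prep Preparation label (`"ssDNA"`/`"dsDNA"`), recorded per row.
#' @return A tibble with `sample`, `prep`, `taxon`, `coverage`.
#' @export
relative_abundance <- function(hits, human_reads,
                               human_genome_length = 3.1e9, prep = "ssDNA") {
  validate_hits(hits)
  tibble(
    sample = if ("sample" %in% names(hits)) hits$sample else "sample1",
    prep = prep,
    taxon = hits$taxon,
    coverage = relative_genome_coverage(hits$read_count, hits$genome_length,
                                        human_reads, human_genome_length)
  )
}

#' Overlap partition of detection events between two preparations
#'
#' @param events_ss,events_ds Character vectors of detection events
#'   (typically `taxon` or `paste(taxon, sample)` keys).
#' @return A one-row tibble with `n_ss_only`, `n_ds_only`, `n_both`.
#' @export
overlap_venn <- function(events_ss, events_ds) {
  ss <- unique(events_ss)
  ds <- unique(events_ds)
  tibble(n_ss_only = length(setdiff(ss, ds)),
         n_ds_only = length(setdiff(ds, ss)),
         n_both = length(intersect(ss, ds)))
}

#' Compare relative abundances between ssDNA and dsDNA preparations
#'
#' Matches detection events (taxon x sample, each treated as a separate
#' event) across the two preparations. For events detected in both:
#' per-event ss/ds coverage ratio, the geometric mean of those ratios as the
#' headline fold change (the arithmetic mean is also reported, as per-event
#' ratios can span orders of magnitude), the Spearman correlation of the
#' coverages and a two-sided Mann-Whitney U test between the two coverage
#' sets. Events detected in only one preparation enter the overlap
#' partition.
#'
#' @param table_ss,table_ds Relative-abundance tibbles from
#'   [relative_abundance()] (columns `sample`, `taxon`, `coverage`).
#' @param detection_min Minimum coverage for an event to count as detected
#'   (default: any positive coverage).
#' @return An object of class `prep_comparison`: list with `events`
#'   (matched-event tibble), `fold_geometric`, `fold_arithmetic`,
#'   `spearman_rho`, `mann_whitney_p`, `overlap` and `status`.
#' @export
compare_preps <- function(table_ss, table_ds, detection_min = 0) {
  assert_columns(table_ss, c("sample", "taxon", "coverage"), "ssDNA table")
  assert_columns(table_ds, c("sample", "taxon", "coverage"), "dsDNA table")
  detected <- function(x) x[x$coverage > detection_min, , drop = FALSE]
  ss <- detected(table_ss)
  ds <- detected(table_ds)
  key <- function(x) paste(x$taxon, x$sample, sep = "\r")
  overlap <- overlap_venn(key(ss), key(ds))

  events <- dplyr::inner_join(ss, ds, by = c("sample", "taxon"),
                              suffix = c("_ss", "_ds")) %>%
    dplyr::mutate(ratio = .data$coverage_ss / .data$coverage_ds)
  n <- nrow(events)
  if (n >= 1L) {
    fold_geo <- exp(mean(log(events$ratio)))
    fold_ari <- mean(events$ratio)
  } else {
    fold_geo <- fold_ari <- NA_real_
  }
  if (n >= 3L) {
    rho <- suppressWarnings(
      stats::cor(events$coverage_ss, events$coverage_ds, method = "spearman"))
    mw <- suppressWarnings(
      wilcox.test(events$coverage_ss, events$coverage_ds,
                  alternative = "two.sided"))$p.value
    status <- "ok"
  } else {
    rho <- NA_real_
    mw <- NA_real_
    status <- "undefined: fewer than 3 shared events"
  }
  structure(list(
    events = events,
    fold_geometric = fold_geo,
    fold_arithmetic = fold_ari,
    spearman_rho = rho,
    mann_whitney_p = mw,
    overlap = overlap,
    status = status
  ), class = "prep_comparison")
}

#' @export
print.prep_comparison <- function(x, ...) {
  cat("ssDNA vs dsDNA preparation comparison\n")
  cat(sprintf("  shared events: %d (ss-only %d, ds-only %d)\n",
              x$overlap$n_both, x$overlap$n_ss_only, x$overlap$n_ds_only))
  if (!is.na(x$fold_geometric)) {
    cat(sprintf("  fold change (ss/ds): geometric mean %.1f, arithmetic mean %.1f\n",
                x$fold_geometric, x$fold_arithmetic))
  }
  if (!is.na(x$spearman_rho)) {
    cat(sprintf("  Spearman rho = %.3f, Mann-Whitney p = %.3g\n",
                x$spearman_rho, x$mann_whitney_p))
  }
  cat("  status:", x$status, "\n")
  invisible(x)
}
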