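# Per-fragment donor/recipient assignment and donor-fraction estimation.

ASSIGNMENT_LEVELS <- c("donor", "recipient", "ambiguous", "uninformative")

#' Assign cfDNA fragments to donor or recipient via informative SNPs
#'
#' For each fragment, collects the observed allele at every informative SNP
#' overlapped by `[start, end)` (half-open, so a SNP at the terminal base
#' counts). A fragment overlapping no SNP is `uninformative`; if all
#' observed alleles match the donor it is `donor`; if all match the
#' recipient, `recipient`; any mixture, any `N`, or any allele matching
#' neither subject makes it `ambiguous`.
#'
#' @param fragments Fragment tibble with `ref`, `start`, `end` and `bases`
#'   (sequence aligned to the reference so that position `start + i` is
#'   base `i + 1`).
#' @param snps Informative-SNP tibble (`ref`, `pos`, `donor_allele`,
#'   `recipient_allele`).
#' @return The input tibble with an added `assignment` column (one of
#'   `donor`, `recipient`, `ambiguous`, `uninformative`).
#' @export
assign_fragments <- function(fragments, snps) {
  validate_fragments(fragments)
  validate_snps(snps)
  if (!"id" %in% names(fragments)) {
    fragments$id <- sprintf("frag_%06d", seq_len(nrow(fragments)))
  }
  if (anyDuplicated(fragments$id)) {
    abort("fragment ids must be unique", class = "cfchimera_validation_error")
  }
  if (nrow(fragments) == 0L) {
    fragments$assignment <- character(0)
    return(fragments)
  }

  overlaps <- dplyr::inner_join(
    dplyr::select(fragments, "id", "ref", "start", "end", "bases"),
    dplyr::select(snps, "ref", "pos", "donor_allele", "recipient_allele"),
    by = dplyr::join_by("ref", "start" <= "pos", "end" > "pos")
  )
  if (nrow(overlaps) > 0L && anyNA(overlaps$bases)) {
    abort("fragments overlapping SNPs must carry bases for allele lookup",
          class = "cfchimera_input_error")
  }
  per_fragment <- overlaps %>%
    dplyr::mutate(
      allele = substr(.data$bases, .data$pos - .data$start + 1L,
                      .data$pos - .data$start + 1L),
      is_donor = .data$allele == .data$donor_allele,
      is_recipient = .data$allele == .data$recipient_allele
    ) %>%
    dplyr::group_by(.data$id) %>%
    dplyr::summarise(
      assignment = dplyr::case_when(
        all(.data$is_donor) ~ "donor",
        all(.data$is_recipient) ~ "recipient",
        TRUE ~ "ambiguous"),
      .groups = "drop")

  fragments$assignment <- per_fragment$assignment[
    match(fragments$id, per_fragment$id)]
  fragments$assignment[is.na(fragments$assignment)] <- "uninformative"
  fragments
}

#' Assign a single fragment
#'
#' Scalar convenience wrapper around [assign_fragments()].
#'
#' @param fragment A one-row fragment tibble.
#' @param snps Informative-SNP tibble.
#' @return One of `"donor"`, `"recipient"`, `"ambiguous"`,
#'   `"uninformative"`.
#' @export
assign_fragment <- function(fragment, snps) {
  stopifnot(nrow(fragment) == 1L)
  assign_fragments(fragment, snps)$assignment[[1]]
}

#' Tally donor/recipient assignments for one sample
#'
#' Counts assignments and computes the donor fraction as
#' `n_donor / (n_donor + n_recipient)` (ambiguous fragments excluded from
#' the denominator; an inclusive variant is also reported). Samples with
#' fewer than `min_informative` unambiguously assigned fragments fail the
#' filter and get an undefined (`NA`) donor fraction.
#'
#' @param fragments Fragment tibble for a single sample, either already
#'   carrying an `assignment` column or accompanied by `snps`.
#' @param snps Informative-SNP tibble (required when `fragments` has no
#'   `assignment` column).
#' @param min_informative Minimum number of informative (donor + recipient)
#'   fragments for a defined donor fraction (default 20).
#' @return A one-row tibble with `sample`, the four counts, `n_total`,
#'   `donor_fraction`, `donor_fraction_incl_ambiguous` and `passed_filter`.
#' @export
tally_sample <- function(fragments, snps = NULL, min_informative = 20) {
  if (!"assignment" %in% names(fragments)) {
    if (is.null(snps)) {
      abort("either an `assignment` column or `snps` must be supplied",
            class = "cfchimera_input_error")
    }
    fragments <- assign_fragments(fragments, snps)
  }
  sample_id <- if (nrow(fragments) > 0L) {
    ids <- unique(fragments$sample)
    if (length(ids) > 1L) {
      abort("tally_sample() expects fragments from a single sample",
            class = "cfchimera_input_error")
    }
    ids
  } else {
    NA_character_
  }
  counts <- table(factor(fragments$assignment, levels = ASSIGNMENT_LEVELS))
  n_donor <- as.integer(counts[["donor"]])
  n_recipient <- as.integer(counts[["recipient"]])
  n_ambiguous <- as.integer(counts[["ambiguous"]])
  n_informative <- n_donor + n_recipient
  passed <- n_informative >= min_informative
  tibble(
    sample = sample_id,
    n_donor = n_donor,
    n_recipient = n_recipient,
    n_ambiguous = n_ambiguous,
    n_uninformative = as.integer(counts[["uninformative"]]),
    n_total = nrow(fragments),
    donor_fraction = if (passed) n_donor / n_informative else NA_real_,
    donor_fraction_incl_ambiguous =
      if (passed) n_donor / (n_informative + n_ambiguous) else NA_real_,
    passed_filter = passed
  )
}

#' Order donor-fraction tallies into a time series
#'
#' Collects per-sample tallies into a time-ordered series. Filtered samples
#' remain present and flagged; no values are imputed.
#'
#' @param tallies Tibble of tallies (rows from [tally_sample()]) with an
#'   added `time` column, or separate `time` supplied here.
#' @param time Optional numeric vector of collection times matching the
#'   rows of `tallies`.
#' @return A tibble (`sample`, `time`, `donor_fraction`, `passed_filter`)
#'   sorted by time.
#' @export
donor_fraction_series <- function(tallies, time = NULL) {
  if (!is.null(time)) tallies$time <- time
  assert_columns(tallies, c("sample", "time", "donor_fraction",
                            "passed_filter"), "tally table")
  if (anyDuplicated(tallies[c("sample", "time")])) {
    abort("duplicate (sample, time) rows in the series",
          class = "cfchimera_validation_error")
  }
  out <- tallies[order(tallies$time), c("sample", "time", "donor_fraction",
                                        "passed_filter")]
  as_tibble(out)
}

#' Pearson agreement between two matched donor-fraction series
#'
#' Matches samples across two series (e.g. the same samples measured under
#' two library preparations), drops pairs where either measurement failed
#' the informative-fragment filter, and computes the Pearson correlation.
#'
#' @param series_a,series_b Series tibbles from [donor_fraction_series()].
#' @return A one-row tibble with `pearson_r`, `p_value`, `n` and `status`;
#'   the correlation is `NA` with an explanatory status when fewer than 3
#'   matched unfiltered pairs exist.
#' @export
compare_fraction_pairs <- function(series_a, series_b) {
  matched <- dplyr::inner_join(series_a, series_b, by = "sample",
                               suffix = c("_a", "_b")) %>%
    dplyr::filter(.data$passed_filter_a, .data$passed_filter_b,
                  !is.na(.data$donor_fraction_a),
                  !is.na(.data$donor_fraction_b))
  n <- nrow(matched)
  if (n < 3L) {
    return(tibble(pearson_r = NA_real_, p_value = NA_real_, n = n,
                  status = "undefined: fewer than 3 matched unfiltered pairs"))
  }
  ct <- cor.test(matched$donor_fraction_a, matched$donor_fraction_b,
                 method = "pearson")
  tibble(pearson_r = unname(ct$estimate), p_value = ct$p.value, n = n,
         status = "ok")
}

#' Build an informative-SNP set from nuclear genotyping calls
#'
#' Retains sites where donor and recipient are both homozygous for
#' different alleles, the strictest unambiguous subset for per-fragment
#' assignment, and emits them in the same informative-SNP format used for
#' mitochondrial chimerism so nuclear and mitochondrial fragments share
#' [assign_fragments()]. Heterozygous, identical-homozygous and
#' non-biallelic sites are skipped and counted in the `skipped` attribute.
#'
#' @param genotypes Tibble with columns `ref`, `pos`, `donor_genotype`,
#'   `recipient_genotype` (two-character genotype strings, e.g. `"AA"`).
#' @return An informative-SNP tibble with attribute `skipped`.
#' @export
build_nuclear_snpset <- function(genotypes) {
  assert_columns(genotypes, c("pos", "donor_genotype", "recipient_genotype"),
                 "genotype table")
  g <- genotypes
  valid_geno <- function(x) {
    nchar(x) == 2L & substr(x, 1, 1) %in% DNA_BASES &
      substr(x, 2, 2) %in% DNA_BASES
  }
  ok_format <- valid_geno(g$donor_genotype) & valid_geno(g$recipient_genotype)
  d1 <- substr(g$donor_genotype, 1, 1); d2 <- substr(g$donor_genotype, 2, 2)
  r1 <- substr(g$recipient_genotype, 1, 1); r2 <- substr(g$recipient_genotype, 2, 2)
  hom <- d1 == d2 & r1 == r2
  informative <- ok_format & hom & d1 != r1
  out <- tibble(
    ref = if ("ref" %in% names(g)) g$ref[informative] else rep("nuclear", sum(informative)),
    pos = as.integer(g$pos[informative]),
    donor_allele = d1[informative],
    recipient_allele = r1[informative]
  )
  out <- out[order(out$pos), , drop = FALSE]
  attr(out, "skipped") <- c(
    malformed = sum(!ok_format),
    heterozygous = sum(ok_format & !hom),
    not_informative = sum(ok_format & hom & d1 == r1)
  )
  validate_snps(out)
  out
}
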