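# Synthetic dPCR assays and microbial hit tables.

#' Default dPCR amplicon panel
#'
#' Eight log-spaced amplicon lengths spanning the 49-304 bp range probed by
#' the assay panel.
#'
#' @return Integer vector of amplicon lengths (bp).
#' @export
default_amplicon_panel <- function() {
  c(49L, 64L, 83L, 107L, 139L, 181L, 234L, 304L)
}

#' Packaged default dPCR fragment-length models
#'
#' Study conditions for the two compartments: a heavily fragmented
#' mitochondrial target (exponential, mean 80 bp) and a nucleosome-protected
#' nuclear target (gamma, mean 166 bp), with mitochondrial genome-equivalent
#' copies 56-fold those of the nuclear target.
#'
#' @param target `"mito"` or `"nuclear"`.
#' @param C0_nuclear Nuclear amplitude (copies); the mitochondrial amplitude
#'   is 56 times this.
#' @return A [frag_dist_params()] object.
#' @export
default_dpcr_params <- function(target = c("mito", "nuclear"),
                                C0_nuclear = 1e4) {
  target <- match.arg(target)
  switch(target,
    mito = frag_dist_params("exponential", C0 = 56 * C0_nuclear, mean = 80),
    nuclear = frag_dist_params("gamma", C0 = C0_nuclear, shape = 4,
                               scale = 41.5))
}

#' Simulate a dPCR amplicon-panel assay
#'
#' Expected concentrations per amplicon come from [expected_abundance()];
#' measured copies add Poisson noise.
#'
#' @param params A [frag_dist_params()] describing the target's
#'   fragment-length distribution and amplitude.
#' @param panel Amplicon lengths (bp).
#' @param target Target label recorded in the assay.
#' @param seed Optional integer seed.
#' @return An assay tibble with columns `target`, `amplicon_length`,
#'   `copies` and attribute `expected` (noise-free curve).
#' @export
simulate_dpcr <- function(params, panel = default_amplicon_panel(),
                          target = "mito", seed = NULL) {
  stopifnot(inherits(params, "frag_dist_params"))
  if (any(panel < 1)) {
    abort("panel amplicon lengths must be positive",
          class = "cfchimera_parameter_error")
  }
  local_seed(seed)
  mu <- expected_abundance(params, panel)
  out <- tibble(target = target, amplicon_length = as.double(panel),
                copies = as.double(rpois(length(panel), mu)))
  attr(out, "expected") <- mu
  out
}

#' Packaged default microbial community
#'
#' A deterministic 25-taxon bacterial community with genome lengths spanning
#' 1.5-8 Mb and true relative genomic coverages log-spaced over two decades,
#' sized so every taxon is comfortably detected in both library
#' preparations.
#'
#' @param n_taxa Number of taxa.
#' @return A tibble with `taxon`, `domain`, `genome_length`,
#'   `true_coverage` (relative to the human genome).
#' @export
default_community <- function(n_taxa = 25L) {
  tibble(
    taxon = sprintf("bacterium_%02d", seq_len(n_taxa)),
    domain = "bacteria",
    genome_length = round(seq(1.5e6, 8e6, length.out = n_taxa)),
    true_coverage = 10^seq(log10(0.02), log10(2), length.out = n_taxa)
  )
}

#' Simulate microbial hit tables for two library preparations
#'
#' Generates per-taxon read counts for matched ssDNA and dsDNA preparations
#' of the same community. Expected reads per taxon are proportional to
#' `true_coverage * genome_length`, scaled to the human read depth, with the
#' ssDNA preparation's counts enriched `ss_enrichment`-fold; realized counts
#' are multinomial across taxa. Identity and query-coverage summaries are
#' sampled around configurable means.
#'
#' @param community Community tibble (see [default_community()]).
#' @param ss_enrichment Fold recovery advantage of the ssDNA preparation.
#' @param human_reads Human-aligned read count per preparation.
#' @param human_genome_length Human genome length (bp).
#' @param identity_mean,identity_sd Mean/sd of per-taxon percent identity.
#' @param coverage_mean,coverage_concentration Beta parameters of the
#'   query-coverage summary.
#' @param sample Sample id attached to both tables.
#' @param seed Optional integer seed.
#' @return A list with `ss` and `ds` hit tibbles (columns of
#'   [read_hits()] plus `sample`), and `human_reads` (named vector per
#'   prep).
#' @export
simulate_hit_tables <- function(community = default_community(),
                                ss_enrichment = 74,
                                human_reads = 5e6,
                                human_genome_length = 3.1e9,
                                identity_mean = 97, identity_sd = 1.5,
                                coverage_mean = 0.97,
                                coverage_concentration = 200,
                                sample = "sample1", seed = NULL) {
  assert_columns(community, c("taxon", "genome_length", "true_coverage"),
                 "community spec")
  local_seed(seed)
  one_prep <- function(enrichment) {
    if (nrow(community) == 0L) {
      return(tibble(taxon = character(), genome_length = double(),
                    read_count = double(), identity = double(),
                    query_coverage = double(), sample = character()))
    }
    expected <- community$true_coverage * community$genome_length *
      (human_reads / human_genome_length) * enrichment
    total <- sum(expected)
    counts <- if (total > 0) {
      as.double(rmultinom(1L, round(total), expected / total)[, 1])
    } else {
      rep(0, nrow(community))
    }
    ident <- pmin(pmax(rnorm(nrow(community), identity_mean, identity_sd), 0), 100)
    k <- coverage_concentration
    qcov <- rbeta(nrow(community), coverage_mean * k, (1 - coverage_mean) * k)
    tibble(taxon = community$taxon,
           genome_length = as.double(community$genome_length),
           read_count = counts, identity = ident, query_coverage = qcov,
           sample = sample)
  }
  ss <- one_prep(ss_enrichment)
  ds <- one_prep(1)
  list(ss = ss, ds = ds,
       human_reads = c(ss = human_reads, ds = human_reads))
}
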