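# Mitochondrial consensus building and informative-SNP derivation.

#' Call a consensus sequence from a pileup
#'
#' Per position, the majority base is emitted when coverage is at least
#' `min_depth` and the majority base accounts for at least
#' `min_major_fraction` of the coverage; otherwise (including exact ties)
#' the position is called `N`. Heteroplasmy below the minor-fraction
#' threshold is thus absorbed into the consensus.
#'
#' @param pileup Pileup tibble with columns `pos` (0-based), `A`, `C`, `G`,
#'   `T` (see [read_pileup()] / [simulate_pileup()]).
#' @param id Sequence id for the returned genome row.
#' @param reference_length Declared reference length; the pileup must cover
#'   `[0, reference_length)`. Defaults to `max(pos) + 1`.
#' @param min_depth Minimum coverage to make a call (default 10).
#' @param min_major_fraction Minimum majority-base fraction (default 0.8).
#' @param circular Circularity flag for the returned genome.
#' @return A one-row genome tibble (`id`, `sequence`, `length`, `circular`).
#' @export
call_consensus <- function(pileup, id = "consensus", reference_length = NULL,
                           min_depth = 10, min_major_fraction = 0.8,
                           circular = TRUE) {
  assert_columns(pileup, c("pos", DNA_BASES), "pileup")
  L <- as.integer(reference_length %||% (max(pileup$pos) + 1L))
  if (anyDuplicated(pileup$pos)) {
    abort("pileup positions must be unique", class = "cfchimera_validation_error")
  }
  if (!setequal(pileup$pos, 0:(L - 1L))) {
    abort(sprintf("pileup must cover every position in [0, %d)", L),
          class = "cfchimera_validation_error")
  }
  ord <- order(pileup$pos)
  counts <- as.matrix(pileup[ord, DNA_BASES])
  cov <- rowSums(counts)
  top <- apply(counts, 1L, max)
  first <- max.col(counts, ties.method = "first")
  last <- max.col(counts, ties.method = "last")
  tie <- first != last
  callable <- cov >= min_depth & top / pmax(cov, 1) >= min_major_fraction &
    cov > 0 & !tie
  bases <- rep("N", L)
  bases[callable] <- DNA_BASES[first[callable]]
  tibble(id = id, sequence = paste(bases, collapse = ""), length = L,
         circular = circular)
}

#' Derive informative SNPs from two consensus sequences
#'
#' Returns the positions where donor and recipient consensus bases are both
#' unambiguous (A/C/G/T) and differ. Positions where either consensus is `N`
#' are never informative.
#'
#' @param donor,recipient Consensus genomes: one-row genome tibbles or plain
#'   sequence strings of equal length.
#' @param ref Reference id recorded in the SNP table.
#' @return An informative-SNP tibble (`ref`, `pos` 0-based, `donor_allele`,
#'   `recipient_allele`), sorted by position.
#' @export
derive_informative_snps <- function(donor, recipient, ref = "chrM") {
  d <- genome_string(donor)
  r <- genome_string(recipient)
  if (nchar(d) != nchar(r)) {
    abort("donor and recipient consensus sequences must have equal length",
          class = "cfchimera_validation_error")
  }
  db <- strsplit(d, "", fixed = TRUE)[[1]]
  rb <- strsplit(r, "", fixed = TRUE)[[1]]
  informative <- db != rb & db %in% DNA_BASES & rb %in% DNA_BASES
  pos <- which(informative)
  donor_allele <- db[pos]
  recipient_allele <- rb[pos]
  tibble(ref = rep(ref, length(pos)), pos = as.integer(pos - 1L),
         donor_allele = donor_allele, recipient_allele = recipient_allele)
}
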