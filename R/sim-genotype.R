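# Synthetic donor/recipient genotypes and sequencing pileups.

#' Subject-pair simulation profile
#'
#' Study conditions for a synthetic transplant donor-recipient pair. The
#' defaults reproduce the scale of a human mitochondrial comparison: a
#' 16,569 bp circular genome and 152 informative substitutions between the
#' two subjects (about one SNP every 109 bp).
#'
#' @param mito_genome_length Mitochondrial genome length in bp.
#' @param n_mito_substitutions Number of planted donor/recipient differences.
#' @param nuclear_snp_panel_size Number of sites on the synthetic nuclear
#'   genotyping panel (used by [simulate_nuclear_genotypes()]).
#' @return A list of class `subject_pair_profile`.
#' @export
subject_pair_profile <- function(mito_genome_length = 16569L,
                                 n_mito_substitutions = 152L,
                                 nuclear_snp_panel_size = 1000L) {
  assert_scalar_number(mito_genome_length, "mito_genome_length", min = 1)
  assert_scalar_number(n_mito_substitutions, "n_mito_substitutions", min = 0)
  if (n_mito_substitutions > mito_genome_length) {
    abort("n_mito_substitutions may not exceed the genome length",
          class = "cfchimera_parameter_error")
  }
  structure(
    list(mito_genome_length = as.integer(mito_genome_length),
         n_mito_substitutions = as.integer(n_mito_substitutions),
         nuclear_snp_panel_size = as.integer(nuclear_snp_panel_size)),
    class = "subject_pair_profile")
}

#' Simulate a donor-recipient pair with planted mitochondrial SNPs
#'
#' Draws a recipient mitochondrial genome uniformly over A/C/G/T and creates
#' the donor genome by substituting `n_mito_substitutions` unique positions,
#' each to a different base. The planted differences are returned as the
#' ground-truth informative-SNP list.
#'
#' @param profile A [subject_pair_profile()].
#' @param seed Optional integer seed; identical seeds give identical pairs.
#' @param ref Reference id used for both genomes (default `"chrM"`).
#' @return A list with elements `genomes` (tibble with rows `donor` and
#'   `recipient`: columns `id`, `sequence`, `length`, `circular`) and `snps`
#'   (truth tibble with `ref`, `pos` 0-based, `donor_allele`,
#'   `recipient_allele`, sorted by position).
#' @export
simulate_subject_pair <- function(profile = subject_pair_profile(),
                                  seed = NULL, ref = "chrM") {
  stopifnot(inherits(profile, "subject_pair_profile"))
  local_seed(seed)
  L <- profile$mito_genome_length
  n <- profile$n_mito_substitutions

  recipient <- sample(DNA_BASES, L, replace = TRUE)
  pos <- sort(sample.int(L, n))               # unique uniform positions
  donor <- recipient
  if (n > 0L) {
    # substitute each site to one of the three other bases
    shift <- sample.int(3L, n, replace = TRUE)
    old_idx <- match(recipient[pos], DNA_BASES)
    new_idx <- ((old_idx - 1L + shift) %% 4L) + 1L
    donor[pos] <- DNA_BASES[new_idx]
  }

  genomes <- tibble(
    id = c("donor", "recipient"),
    sequence = c(paste(donor, collapse = ""), paste(recipient, collapse = "")),
    length = L,
    circular = TRUE
  )
  donor_allele <- donor[pos]
  recipient_allele <- recipient[pos]
  snps <- tibble(
    ref = rep(ref, n),
    pos = as.integer(pos - 1L),               # 0-based
    donor_allele = donor_allele,
    recipient_allele = recipient_allele
  )
  list(genomes = genomes, snps = snps)
}

#' Simulate a sequencing pileup over a genome
#'
#' Per-position coverage is Poisson(`depth`); each covered base reports the
#' true genome base except with probability `error_rate`, in which case it
#' substitutes uniformly to one of the three other bases.
#'
#' @param genome A genome as a single character string, or a one-row genome
#'   tibble with a `sequence` column (as returned in
#'   `simulate_subject_pair()$genomes`).
#' @param depth Mean per-position coverage (>= 0).
#' @param error_rate Per-base substitution error probability in `[0, 0.25)`.
#' @param seed Optional integer seed.
#' @param ref Reference id recorded in the pileup.
#' @return A pileup tibble with columns `ref`, `pos` (0-based), `A`, `C`,
#'   `G`, `T`.
#' @export
simulate_pileup <- function(genome, depth = 100, error_rate = 0, seed = NULL,
                            ref = "chrM") {
  seq <- genome_string(genome)
  assert_scalar_number(depth, "depth", min = 0)
  assert_scalar_number(error_rate, "error_rate", min = 0, max = 0.25 - 1e-12)
  local_seed(seed)

  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(bases)
  cov <- rpois(L, depth)
  counts <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, DNA_BASES))
  true_idx <- match(bases, DNA_BASES)

  n_err <- if (error_rate > 0) rbinom(L, cov, error_rate) else integer(L)
  correct <- cov - n_err
  counts[cbind(seq_len(L), true_idx)] <- correct
  err_pos <- which(n_err > 0L)
  for (i in err_pos) {
    others <- setdiff(1:4, true_idx[[i]])
    split <- rmultinom(1L, n_err[[i]], rep(1 / 3, 3))[, 1]
    counts[i, others] <- counts[i, others] + split
  }

  out <- tibble(ref = rep(ref, L), pos = 0:(L - 1L))
  out[DNA_BASES] <- as.data.frame(counts)
  out
}

# Accept either a plain string or a genome tibble row.
genome_string <- function(genome) {
  if (is.character(genome) && length(genome) == 1L) return(genome)
  if (is.data.frame(genome) && "sequence" %in% names(genome) &&
      nrow(genome) == 1L) {
    return(genome$sequence[[1]])
  }
  abort("`genome` must be a single sequence string or a one-row genome tibble",
        class = "cfchimera_input_error")
}

#' Simulate nuclear genotyping-array calls for a subject pair
#'
#' Generates biallelic genotype calls at a panel of nuclear SNP sites for
#' donor and recipient, for exercising the nuclear chimerism path. Each site
#' gets two alleles; per subject the genotype is homozygous or heterozygous
#' with the given heterozygosity.
#'
#' @param profile A [subject_pair_profile()]; `nuclear_snp_panel_size` sets
#'   the number of sites.
#' @param heterozygosity Per-subject probability of a heterozygous call.
#' @param seed Optional integer seed.
#' @return A tibble with columns `ref`, `pos`, `donor_genotype`,
#'   `recipient_genotype` (two-character strings such as `"AA"` or `"AG"`).
#' @export
simulate_nuclear_genotypes <- function(profile = subject_pair_profile(),
                                       heterozygosity = 0.33, seed = NULL) {
  stopifnot(inherits(profile, "subject_pair_profile"))
  local_seed(seed)
  n <- profile$nuclear_snp_panel_size
  a1 <- sample(DNA_BASES, n, replace = TRUE)
  shift <- sample.int(3L, n, replace = TRUE)
  a2 <- DNA_BASES[((match(a1, DNA_BASES) - 1L + shift) %% 4L) + 1L]
  geno <- function() {
    het <- runif(n) < heterozygosity
    hom_allele <- ifelse(runif(n) < 0.5, a1, a2)
    ifelse(het, paste0(a1, a2), paste0(hom_allele, hom_allele))
  }
  tibble(
    ref = "nuclear",
    pos = sort(sample.int(3.1e9, n)) - 1L,
    donor_genotype = geno(),
    recipient_genotype = geno()
  )
}
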