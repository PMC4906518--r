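# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Valid compartment labels: nuclear, mito, or microbial:<taxon>.
is_valid_compartment <- function(x) {
  grepl("^(nuclear|mito|microbial:.+)$", x)
}

# Set the RNG seed for the calling frame only; a NULL seed leaves the
# caller's RNG stream untouched.
local_seed <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::local_seed(as.integer(seed), .local_envir = env)
  }
  invisible(NULL)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(min), format(max)),
          class = "cfchimera_parameter_error")
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "cfchimera_validation_error")
  }
  invisible(df)
}

# Validate a fragment table against the shared contract: 0-based half-open
# coordinates with end > start, and known compartment labels.
validate_fragments <- function(fragments, require_bases = FALSE) {
  assert_columns(fragments, c("ref", "start", "end", "sample", "compartment"),
                 "fragment table")
  bad <- fragments$end <= fragments$start
  if (any(bad)) {
    abort(sprintf("%d fragment(s) have end <= start (coordinates are 0-based, half-open)",
                  sum(bad)),
          class = "cfchimera_validation_error")
  }
  badc <- !is_valid_compartment(fragments$compartment)
  if (any(badc)) {
    abort(sprintf("invalid compartment label(s): %s",
                  paste(unique(fragments$compartment[badc]), collapse = ", ")),
          class = "cfchimera_validation_error")
  }
  if (require_bases && (!"bases" %in% names(fragments) || anyNA(fragments$bases))) {
    abort("fragment bases are required for this operation but are missing",
          class = "cfchimera_input_error")
  }
  invisible(fragments)
}

# Validate an informative-SNP table (0-based positions, donor != recipient).
validate_snps <- function(snps) {
  assert_columns(snps, c("pos", "donor_allele", "recipient_allele"), "SNP table")
  if (any(snps$donor_allele == snps$recipient_allele)) {
    abort("informative SNPs must have donor_allele != recipient_allele",
          class = "cfchimera_validation_error")
  }
  if (any(snps$donor_allele == "N" | snps$recipient_allele == "N")) {
    abort("informative SNP alleles may not be N",
          class = "cfchimera_validation_error")
  }
  if (anyDuplicated(snps$pos)) {
    abort("informative SNP positions must be unique",
          class = "cfchimera_validation_error")
  }
  invisible(snps)
}

# Per-fragment GC fraction, (G + C) / length; N counts toward length.
gc_fraction <- function(bases) {
  if (length(bases) == 0L) return(numeric(0))
  x <- Biostrings::BStringSet(bases)
  gc <- Biostrings::letterFrequency(x, letters = c("G", "C"))
  as.numeric(rowSums(gc)) / Biostrings::width(x)
}
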