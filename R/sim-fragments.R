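# Synthetic cfDNA fragment pools: length mixtures, GC structure, donor
# labels, and length-dependent capture filtering.

#' Fragment-pool simulation profile
#'
#' Study conditions for a synthetic cfDNA fragment pool of one compartment.
#' Nuclear pools are a two-component length mixture: a nucleosomal
#' Normal(166, 8) peak plus a short sub-100 bp component with weight
#' `w_short` = 0.2054. Mitochondrial and microbial pools contain the short
#' component only. The short component is `short_shift` + Gamma(shape,
#' scale), parameterized to a 60 bp mode and a 20 bp minimum. GC content is
#' class-conditional: fragments under 100 bp average 43.5% GC, fragments of
#' 100 bp and over average 40.9%, each drawn per fragment from a Beta
#' distribution with the given concentration. Donor fragments are optionally
#' shifted in length by `donor_length_offset` (default 0); the packaged
#' donor-versus-recipient fragment-size study plants a -9 bp shift, passed
#' explicitly, so that the default pool does not couple fragment length to
#' origin.
#'
#' @param compartment `"mito"`, `"nuclear"`, or a `"microbial:<taxon>"`
#'   label.
#' @param donor_fraction True per-fragment probability of donor origin.
#'   Defaults: 0.095 (mito), 0.01 (nuclear), 0 (microbial).
#' @param w_short Weight of the short component in nuclear pools (the two
#'   weights sum to 1). Ignored for mito/microbial pools, which are all
#'   short.
#' @param nucleosomal_mean,nucleosomal_sd Normal parameters of the
#'   nucleosomal peak (bp).
#' @param short_shape,short_scale,short_shift Shifted-Gamma parameters of
#'   the short component (bp); defaults give mode 60 bp, minimum 20 bp.
#' @param donor_length_offset Additive shift (bp) applied to donor fragment
#'   lengths.
#' @param gc_mean_sub100,gc_mean_super100 Class-conditional mean GC
#'   fractions for fragments under / at-or-over 100 bp.
#' @param gc_concentration Beta concentration of the per-fragment GC draw.
#' @param min_length Minimum emitted fragment length (bp).
#' @param copy_weight Relative genome-equivalent abundance of the
#'   compartment (mitochondrial genome-equivalents outnumber nuclear 56:1 in
#'   plasma); carried as metadata for multi-compartment pools.
#' @return A list of class `fragment_pool_profile`.
#' @export
fragment_pool_profile <- function(compartment = c("mito", "nuclear"),
                                  donor_fraction = NULL,
                                  w_short = 0.2054,
                                  nucleosomal_mean = 166, nucleosomal_sd = 8,
                                  short_shape = 16, short_scale = 8 / 3,
                                  short_shift = 20,
                                  donor_length_offset = NULL,
                                  gc_mean_sub100 = 0.435,
                                  gc_mean_super100 = 0.409,
                                  gc_concentration = 50,
                                  min_length = 20L,
                                  copy_weight = NULL) {
  compartment <- if (length(compartment) > 1L) compartment[[1]] else compartment
  if (!is_valid_compartment(compartment)) {
    abort("compartment must be 'nuclear', 'mito' or 'microbial:<taxon>'",
          class = "cfchimera_parameter_error")
  }
  if (is.null(donor_fraction)) {
    donor_fraction <- switch(substr(compartment, 1, 4),
                             mito = 0.095, nucl = 0.01, 0)
  }
  if (is.null(donor_length_offset)) donor_length_offset <- 0
  if (is.null(copy_weight)) {
    copy_weight <- if (compartment == "mito") 56 else 1
  }
  assert_scalar_number(donor_fraction, "donor_fraction", 0, 1)
  assert_scalar_number(w_short, "w_short", 0, 1)
  assert_scalar_number(short_shape, "short_shape", min = 1e-6)
  assert_scalar_number(short_scale, "short_scale", min = 1e-6)
  assert_scalar_number(gc_concentration, "gc_concentration", min = 1e-6)
  assert_scalar_number(gc_mean_sub100, "gc_mean_sub100", 0, 1)
  assert_scalar_number(gc_mean_super100, "gc_mean_super100", 0, 1)
  structure(
    list(compartment = compartment, donor_fraction = donor_fraction,
         w_short = w_short, nucleosomal_mean = nucleosomal_mean,
         nucleosomal_sd = nucleosomal_sd, short_shape = short_shape,
         short_scale = short_scale, short_shift = short_shift,
         donor_length_offset = donor_length_offset,
         gc_mean_sub100 = gc_mean_sub100,
         gc_mean_super100 = gc_mean_super100,
         gc_concentration = gc_concentration,
         min_length = as.integer(min_length), copy_weight = copy_weight),
    class = "fragment_pool_profile")
}

#' Draw fragment lengths from a pool profile
#'
#' Samples integer fragment lengths from the profile's mixture (short
#' component only for mito/microbial compartments), applying the donor
#' length offset when `origin = "donor"` and clamping at the profile's
#' minimum length.
#'
#' @param n Number of lengths.
#' @param profile A [fragment_pool_profile()].
#' @param origin `"recipient"` or `"donor"`.
#' @param seed Optional integer seed.
#' @return Integer vector of lengths (bp).
#' @export
simulate_fragment_lengths <- function(n, profile = fragment_pool_profile("mito"),
                                      origin = c("recipient", "donor"),
                                      seed = NULL) {
  stopifnot(inherits(profile, "fragment_pool_profile"))
  origin <- match.arg(origin)
  local_seed(seed)
  nuclear <- profile$compartment == "nuclear"
  short <- if (nuclear) runif(n) < profile$w_short else rep(TRUE, n)
  len <- numeric(n)
  n_short <- sum(short)
  len[short] <- profile$short_shift +
    rgamma(n_short, shape = profile$short_shape, scale = profile$short_scale)
  len[!short] <- rnorm(n - n_short, profile$nucleosomal_mean,
                       profile$nucleosomal_sd)
  if (origin == "donor") len <- len + profile$donor_length_offset
  pmax(as.integer(round(len)), profile$min_length)
}

#' Simulate a cfDNA fragment pool with planted donor/recipient truth
#'
#' Generates `n` fragments for one compartment. Lengths come from the
#' profile mixture; start coordinates are uniform on `[0, G - L]` (genomes
#' are treated as linear for placement, so no origin-spanning fragments);
#' each fragment is donor-derived with probability `donor_fraction`. For the
#' mitochondrial compartment, fragment bases are copied from the labeled
#' subject's genome, so alleles at informative SNP sites are consistent with
#' the fragment's true origin. Nuclear and microbial fragments carry
#' synthetic sequence drawn from the class-conditional GC model. Truth
#' labels are returned in a sidecar tibble, not in the emitted fragment
#' table.
#'
#' @param pair A subject pair from [simulate_subject_pair()] (required for
#'   mitochondrial pools; ignored otherwise).
#' @param profile A [fragment_pool_profile()].
#' @param n Number of fragments.
#' @param sample Sample id stamped on every fragment.
#' @param seed Optional integer seed.
#' @param nuclear_ref_length Nominal nuclear reference length for coordinate
#'   placement.
#' @return A list with `fragments` (tibble: `id`, `ref`, `start`, `end`,
#'   `length`, `sample`, `compartment`, `bases`) and `truth` (tibble: `id`,
#'   `origin`, `component`).
#' @export
simulate_fragment_pool <- function(pair = NULL,
                                   profile = fragment_pool_profile("mito"),
                                   n = 10000L, sample = "sample1",
                                   seed = NULL,
                                   nuclear_ref_length = 3.1e9) {
  stopifnot(inherits(profile, "fragment_pool_profile"))
  assert_scalar_number(n, "n", min = 0)
  n <- as.integer(n)
  local_seed(seed)

  mito <- profile$compartment == "mito"
  if (mito && is.null(pair)) {
    abort("a subject pair is required to simulate mitochondrial fragments",
          class = "cfchimera_input_error")
  }

  donor <- runif(n) < profile$donor_fraction
  len <- integer(n)
  comp_lab <- character(n)
  if (any(donor)) {
    len[donor] <- simulate_fragment_lengths(sum(donor), profile, "donor")
  }
  len[!donor] <- simulate_fragment_lengths(sum(!donor), profile, "recipient")
  nuclear <- profile$compartment == "nuclear"
  comp_lab <- ifelse(nuclear & len >= 100, "nucleosomal", "short")

  if (mito) {
    G <- pair$genomes$length[[1]]
    too_long <- len > G
    if (any(too_long)) {
      # oversized draws are re-drawn, up to a cap
      for (i in which(too_long)) {
        tries <- 0L
        while (len[[i]] > G) {
          tries <- tries + 1L
          if (tries > 1000L) {
            abort("could not draw a fragment shorter than the genome after 1000 tries",
                  class = "cfchimera_simulation_error")
          }
          len[[i]] <- simulate_fragment_lengths(
            1L, profile, if (donor[[i]]) "donor" else "recipient")
        }
      }
    }
    start <- floor(runif(n, 0, G - len + 1))
    donor_seq <- pair$genomes$sequence[match("donor", pair$genomes$id)]
    recip_seq <- pair$genomes$sequence[match("recipient", pair$genomes$id)]
    bases <- character(n)
    if (any(donor)) {
      bases[donor] <- substring(donor_seq, start[donor] + 1,
                                start[donor] + len[donor])
    }
    if (any(!donor)) {
      bases[!donor] <- substring(recip_seq, start[!donor] + 1,
                                 start[!donor] + len[!donor])
    }
    ref <- pair$snps$ref[1] %||% "chrM"
    if (is.na(ref)) ref <- "chrM"
  } else {
    start <- floor(runif(n, 0, nuclear_ref_length - len + 1))
    bases <- synth_gc_sequences(len, profile)
    ref <- if (nuclear) "nuclear" else profile$compartment
  }

  id <- sprintf("frag_%06d", seq_len(n))
  fragments <- tibble(
    id = id, ref = rep(ref, n), start = as.double(start),
    end = as.double(start) + len, length = len,
    sample = rep(sample, n), compartment = rep(profile$compartment, n),
    bases = bases
  )
  truth <- tibble(id = id,
                  origin = ifelse(donor, "donor", "recipient"),
                  component = comp_lab)
  list(fragments = fragments, truth = truth)
}

# Per-fragment GC target drawn from a Beta with class-conditional mean and
# fixed concentration; bases are then iid with P(G or C) = target.
synth_gc_sequences <- function(len, profile) {
  n <- length(len)
  if (n == 0L) return(character(0))
  mean_gc <- ifelse(len < 100, profile$gc_mean_sub100, profile$gc_mean_super100)
  k <- profile$gc_concentration
  gc <- rbeta(n, mean_gc * k, (1 - mean_gc) * k)
  total <- sum(len)
  u <- runif(total)
  p <- rep(gc, len)
  base <- ifelse(u < p / 2, "G",
                 ifelse(u < p, "C",
                        ifelse(u < p + (1 - p) / 2, "A", "T")))
  big <- paste(base, collapse = "")
  ends <- cumsum(len)
  substring(big, ends - len + 1, ends)
}

#' Length-dependent capture model for a library preparation
#'
#' Logistic capture-probability curve
#' `p(L) = plateau / (1 + exp(-(L - midpoint) / scale))`, non-decreasing in
#' fragment length. Defaults reflect the qualitative contrast between
#' preparations: single-stranded ligation captures fragments down to the
#' 40-60 bp DNA-isolation floor (midpoint 45), whereas double-stranded
#' protocols size-select away sub-100 bp material (midpoint 100).
#'
#' @param prep `"ssDNA"` or `"dsDNA"`.
#' @param midpoint,scale Logistic midpoint and scale in bp; defaults 45/6
#'   for ssDNA, 100/12 for dsDNA.
#' @param plateau Maximum capture probability in (0, 1].
#' @return A list of class `capture_model` with a `prob` function of length.
#' @export
capture_model <- function(prep = c("ssDNA", "dsDNA"), midpoint = NULL,
                          scale = NULL, plateau = 1) {
  prep <- match.arg(prep)
  midpoint <- midpoint %||% switch(prep, ssDNA = 45, dsDNA = 100)
  scale <- scale %||% switch(prep, ssDNA = 6, dsDNA = 12)
  assert_scalar_number(plateau, "plateau", min = 1e-12, max = 1)
  assert_scalar_number(scale, "scale", min = 1e-9)
  structure(list(prep = prep, midpoint = midpoint, scale = scale,
                 plateau = plateau),
            class = "capture_model")
}

#' Capture probability at given fragment lengths
#'
#' @param model A [capture_model()].
#' @param length Fragment lengths (bp).
#' @return Capture probabilities in `[0, 1]`.
#' @export
capture_probability <- function(model, length) {
  stopifnot(inherits(model, "capture_model"))
  model$plateau / (1 + exp(-(length - model$midpoint) / model$scale))
}

#' Filter a fragment pool through a capture model
#'
#' Each fragment is retained independently with probability `p(L)` from the
#' capture model, emulating length-dependent recovery by a library
#' preparation. Retained + dropped always equals the input size.
#'
#' @param fragments Fragment tibble.
#' @param model A [capture_model()].
#' @param seed Optional integer seed.
#' @return The retained fragment tibble, with attribute `capture_log`
#'   (tibble with `input`, `retained`, `dropped`).
#' @export
apply_capture <- function(fragments, model, seed = NULL) {
  stopifnot(inherits(model, "capture_model"))
  local_seed(seed)
  len <- fragments$length %||% (fragments$end - fragments$start)
  keep <- runif(nrow(fragments)) < capture_probability(model, len)
  out <- fragments[keep, , drop = FALSE]
  attr(out, "capture_log") <- tibble(
    prep = model$prep, input = nrow(fragments), retained = sum(keep),
    dropped = nrow(fragments) - sum(keep))
  out
}
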