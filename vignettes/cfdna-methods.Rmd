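---
title: "Models and methods for plasma cfDNA chimerism and fragmentomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for plasma cfDNA chimerism and fragmentomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfchimera)
```

cfchimera analyses plasma cell-free DNA (cfDNA) along four axes:
donor/recipient chimerism via informative mitochondrial SNPs, fragment
length and GC structure across compartments, a digital-PCR (dPCR)
fragmentation model, and microbial relative genomic coverage under two
library preparations. This vignette records the models, their assumptions,
the packaged default parameters and the reasoning behind the numerical and
design choices, in the spirit of a methods supplement.

## Coordinates and data contracts

All genomic coordinates are 0-based and half-open, in memory and on disk;
every writer stamps that convention in a `#` header. A fragment `[start,
end)` has `length = end - start`, and a SNP at position `p` is overlapped
exactly when `start <= p < end` — a SNP at the terminal base counts.
Fragment strand is ignored throughout: every analysis uses only
coordinates and base identity. `N` bases are permitted and never match any
SNP allele.

When fragments come from a paired-end alignment (BAM), one fragment is
emitted per properly paired read pair, spanning the outermost mapped
coordinates of the two mates. Secondary, supplementary, unpaired and
duplicate records are skipped and counted; the MAPQ threshold (default 20)
and duplicate handling are exposed as arguments since upstream pipelines
differ on both.

## Consensus calling and informative SNPs

`call_consensus()` emits, per position, the majority base when coverage is
at least `min_depth` (default 10) and the majority base holds at least
`min_major_fraction` (default 0.8) of the coverage; anything else —
including exact ties — becomes `N`. With mean coverage above 100-fold, a
depth floor of 10 is conservative (the probability of a position dropping
below it under Poisson coverage is negligible), and the 0.8 majority rule
means heteroplasmy below a 20% minor fraction is absorbed into the
consensus: the chimerism model is deliberately consensus-based, and indels
are out of model. `derive_informative_snps()` then lists positions where
two consensus sequences disagree and both are unambiguous; an `N` in
either subject excludes the position. Consequently false informative SNPs
require a miscalled consensus base, not merely sequencing noise — the test
suite checks that at 100-fold coverage with 0.1% substitution error the
derived set has no false positives and near-complete recall.

## Fragment assignment and the donor fraction

`assign_fragments()` classifies each fragment against the informative-SNP
list: *donor* when all observed alleles match the donor, *recipient* when
all match the recipient, *ambiguous* on any mixture, `N`, or third allele,
and *uninformative* when no SNP is overlapped. The donor fraction of a
sample is `n_donor / (n_donor + n_recipient)`. Whether ambiguous
fragments belong in the denominator is a genuinely open choice; excluding
them is the stricter reading of "informative", so that is the primary
estimate, and `tally_sample()` also reports the inclusive variant
(`donor_fraction_incl_ambiguous`) alongside. Samples with fewer than
`min_informative = 20` unambiguous fragments get an undefined donor
fraction and a `passed_filter = FALSE` flag; series functions carry
filtered samples through visibly rather than dropping or imputing them.

For nuclear chimerism, `build_nuclear_snpset()` reduces genotyping-array
calls to sites where donor and recipient are homozygous for different
alleles — the strictest subset on which a single observed allele is fully
informative — and emits them in the same SNP format, so nuclear and
mitochondrial fragments share one assignment path.

## The synthetic-data generator

The generator exists so that every downstream stage has planted ground
truth. Its defaults are the packaged study conditions:

* **Subject pair** — a 16,569 bp circular mitochondrial genome drawn
  uniformly over A/C/G/T, with 152 substitutions planted at unique uniform
  positions (about one informative SNP per 109 bp).
* **Fragment lengths** — nuclear pools mix a nucleosomal Normal(166, 8)
  component with an ultrashort component of weight 0.2054; mitochondrial
  and microbial pools are entirely ultrashort. The ultrashort law is
  `20 + Gamma(shape 16, scale 8/3)` bp: mode 60 bp, minimum 20 bp, and
  essentially all mass below 100 bp so that the sub-100 bp proportion of a
  nuclear pool equals the mixture weight. The spread was fixed once at
  sd ≈ 10.7 bp; only the mode and support of the ultrashort peak are
  anchored by observation, not its shape.
* **GC structure** — per-fragment GC targets are Beta-distributed with
  class-conditional means 0.435 (below 100 bp) and 0.409 (at or above) and
  concentration 50; bases are then drawn i.i.d. at that GC. Only the class
  means are empirically anchored; the concentration is a single choice
  giving a realistic ~7% per-fragment GC spread.
* **Origin labels** — each fragment is donor-derived with probability
  0.095 (mitochondrial) or 0.01 (nuclear). Mitochondrial fragment bases
  are copied from the labeled subject's genome, so alleles at SNP sites
  are consistent by construction; truth labels live in a sidecar tibble,
  never in the emitted table. The default pool does **not** couple length
  to origin: the −9 bp donor shift used in the fragment-size study is
  passed explicitly (`donor_length_offset`), because coupling it by
  default would shorten donor fragments, reduce their SNP overlap, and
  make the informative-fragment donor share systematically smaller than
  the planted molecular fraction — a selection effect worth studying, but
  not a sensible default for estimator-recovery work.
* **Placement** — start positions are uniform on `[0, G − L]`; the
  mitochondrial genome is treated as linear for placement. Origin-spanning
  fragments carry negligible probability mass (~fragment length / genome
  length) and would complicate coordinate arithmetic for no analytical
  gain. Draws longer than the genome are resampled, with a cap of 1,000
  attempts before a simulation error.
* **Capture** — a preparation is a logistic retention curve
  `p(L) = plateau / (1 + exp(−(L − midpoint)/scale))`, non-decreasing in
  length. Defaults: midpoint 45 bp, scale 6 (ssDNA — the 40–60 bp recovery
  floor set by DNA isolation) and midpoint 100 bp, scale 12 (dsDNA —
  size-selective cleanup). Only the qualitative contrast and the ssDNA
  floor are anchored; the logistic form and scales are the package's
  parameterization.
* **Pileups** — per-position coverage is Poisson(depth); errors substitute
  uniformly to the three other bases.
* **dPCR assays** — expected concentrations come from the fragmentation
  model below (mitochondrial: exponential, mean 80 bp; nuclear: gamma,
  mean 166 bp; amplitude ratio 56) with Poisson noise, over a panel of
  eight log-spaced amplicon lengths spanning 49–304 bp. Amplitudes are
  scaled so every panel point expects ≥ ~100 counts, keeping relative
  noise below ~10% everywhere.
* **Microbial community** — 25 bacterial taxa, genome lengths 1.5–8 Mb,
  true relative coverages log-spaced over `[0.02, 2]`, 5 × 10⁶ human reads
  per preparation, and a 74-fold ssDNA enrichment; read counts are
  multinomial across taxa. Coverages are set high enough that every taxon
  is detected in both preparations, so fold-change recovery is not
  distorted by detection conditioning.

What the generator does **not** emulate: read-level sequencing error on
fragments (only pileup substitution errors), PCR duplicates, quality
scores, alignment artefacts, mappability structure, real haplogroup
diversity, heteroplasmy, or the informative-fragment *rate* observed in
real data (which reflects quality filtering the generator does not model).
Passing recovery tests therefore demonstrates correctness of the
estimators under the stated generative model, not robustness to every
failure mode of real sequencing data.

## Fragment-length and GC analyses

Histograms are exact 1 bp integer bins with three normalizations: raw
counts, frequencies, or heights relative to the nuclear fragment count of
the same table (the convention for plotting minor compartments against
the nuclear profile). The sub-100 bp proportion uses a strict `< 100`
cut; length exactly 100 belongs to the super class. Modal lengths are
local maxima of the histogram after running-mean smoothing over a
centered 5-bin window; windows truncate at the edges (so the output
length equals the input length), adjacent ties resolve toward the smaller
length, and maxima below 5% of the global maximum are suppressed as
noise. GC is `(G + C) / length` per fragment, compared between classes
with a two-sided Mann–Whitney U test; complete ties leave the normal
approximation undefined and are reported as p = 1.

### The median-shift statistic

With few donor fragments against many recipient fragments, a direct
median comparison needs a reference distribution. The statistic subsamples
the recipient set without replacement at exactly the donor count, 10,000
times, and reports `median(donor) − median(recipient)` with the standard
deviation of subsample medians and a two-sided empirical p (add-one
correction, so p is never 0).

The p-value's null calibration is checked under the *exchangeable* null:
the donor set is itself drawn without replacement from the recipient set,
exactly like each resample, making the observed statistic one more draw
from the resampling distribution and the empirical p uniform by
construction. An independent donor sample compared against
without-replacement subsamples of a finite recipient sample is *not*
exchangeable — the observed difference has variance inflated by roughly
`(1 + f)/(1 − f)` at subsampling fraction `f` — so that design is mildly
anticonservative by construction and is not what the calibration suite
asserts. The calibration study uses the continuous (unrounded) length law
to avoid the heavy median ties that integer lengths induce, which would
otherwise make the empirical p conservative. The test is an extension of
the descriptive subsampling procedure; its p-value should be read with
the exchangeability caveat above.

## The dPCR fragmentation model

Only fragments that fully span an amplicon amplify: a fragment of length
`L` offers `max(L − a + 1, 0)` intact start positions for an amplicon of
length `a`. Under random fragmentation the measured genome-equivalent
concentration is

$$C(a) = C_0 \, \frac{E[(L - a + 1)_+]}{E[L]}$$

with `C0` the intact-locus concentration extrapolated to `a → 0`. The
kernel gives two invariants used as tests: `C(a)` is non-increasing in
`a`, and `C(1) = C0` for any finite-mean family. Expectations are
computed by numeric integration on 1–2000 bp (`rel.tol` 1e-9); 2000 bp is
far beyond any plasma cfDNA mass, so truncation error is negligible at
the panel's scale.

Three length families are offered — exponential (heavily fragmented,
mitochondrial/microbial-like), gamma (nucleosome-protected nuclear-like)
and lognormal — selected by the caller, never automatically. Fitting is
weighted least squares on log abundances (weights proportional to
measured counts), reflecting multiplicative noise across a six-fold
amplicon-length range; parameters are optimized on the log scale
(Nelder–Mead, then BFGS with a Hessian for covariance). A panel whose log
abundances span less than 5% or do not decrease with amplicon length is
rejected as non-identifiable with an explicit status — a flat panel is
incompatible with any finite-mean family — rather than silently returning
a boundary fit.

The genome-equivalent copy ratio between two targets is the ratio of
fitted `C0` values, with uncertainty propagated on the log scale from
both fits. Tying the ratio to `C0` (rather than to an integrated copy
number) is a declared convention: `C0` is precisely the concentration of
loci intact at vanishing amplicon length, which is what "genome
equivalents" measures. Partition-level dPCR occupancy statistics are out
of model; inputs are already concentrations.

## Microbial relative abundance

Hits are filtered at ≥ 90% identity across ≥ 90% of query bases (both
inclusive). Relative genomic coverage is the length-normalized read-count
ratio against the human genome (default length 3.1 × 10⁹ bp,
configurable); it is invariant to common scaling of read counts and
inversely proportional to taxon genome length. This direct estimator
replaces mixture-model EM read reassignment: for per-taxon aggregated hit
tables the coverage quantity is computable in closed form, at the cost of
ignoring read-level ambiguity between closely related genomes.

Preparations are compared per detection event (taxon × sample, each event
separate). "Detected" means any positive coverage after filtering — no
additional threshold is imposed. For shared events the headline fold
change is the geometric mean of per-event ratios, because such ratios
span orders of magnitude and an arithmetic mean would be dominated by the
upper tail; the arithmetic mean is reported alongside, as are the
Spearman correlation, a two-sided Mann–Whitney comparison of the coverage
sets, and the ss-only/ds-only/both overlap partition.

## Problem sizes and reproducibility

Every stochastic function takes an explicit `seed` and restores the
caller's RNG state (`withr::local_seed()`), so identical seeds give
byte-identical outputs and independent stages use independent sub-seeds.
The packaged studies run at desk scale, chosen so binomial/Poisson error
sits well inside each target's tolerance: 60,000 mitochondrial fragments
(≈ 26,000 informative) for donor-fraction recovery, 50,000 nuclear
fragments for length/GC structure, 265 vs 1,855 lengths with 10,000
resamples for the median shift, 500 simulations of 999 resamples for its
null calibration, 8-point panels with ≥ 100 expected counts per point for
dPCR recovery, and 20 replicate communities for fold-change recovery.

## Known limitations

* The chimerism model is consensus-based: sub-threshold heteroplasmy,
  indels and base-quality structure are invisible to it.
* The donor-fraction estimator conditions on unambiguous assignment;
  under base-calling error the ambiguous class grows and the inclusive
  and exclusive estimates diverge — both are reported.
* The capture curves are two-parameter logistics; real preparations can
  have non-monotone recovery (e.g. upper size cutoffs) that the model
  does not represent.
* The relative-coverage estimator attributes each read to one taxon;
  closely related genomes sharing reads will split coverage arbitrarily
  upstream of this package.
* The median-shift p-value assumes exchangeability between the donor set
  and recipient subsamples; for independent samples it is mildly
  anticonservative (see above).
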