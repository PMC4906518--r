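# Tabular readers/writers. All coordinates on disk and in memory are
# 0-based, half-open; every writer records that convention in a '#' header.

COORD_HEADER <- "# coordinates: 0-based, half-open"

#' Read cfDNA fragment records
#'
#' Reads fragment records either from a tab-separated table or from a
#' paired-end alignment file (BAM). For the alignment dialect one fragment is
#' emitted per properly paired read pair, with `start` the minimum leftmost
#' mapped coordinate of the two mates and `end` the maximum rightmost mapped
#' coordinate plus one, i.e. the insert implied by the outermost ends of the
#' pair. Secondary, supplementary, unpaired, duplicate and low-MAPQ records
#' are skipped and counted in the `skipped` attribute.
#'
#' @param path Path to a fragments TSV (columns `ref`, `start`, `end`,
#'   `sample`, `compartment`, optional `bases`; `#` lines are comments) or a
#'   coordinate-sorted BAM file.
#' @param dialect `"tsv"` or `"bam"`.
#' @param sample Sample id attached to every fragment (BAM dialect only;
#'   BAM files carry no sample column).
#' @param compartment_map Named character vector mapping reference names to
#'   compartment labels (BAM dialect). References named `chrM` or `MT`
#'   default to `"mito"`, everything else to `"nuclear"`.
#' @param mapq_min Minimum mapping quality for the BAM dialect (default 20).
#' @param drop_duplicates Drop records flagged as PCR/optical duplicates
#'   (BAM dialect, default `TRUE`).
#'
#' @return A fragment tibble with columns `ref`, `start`, `end`, `length`,
#'   `sample`, `compartment` (and `bases` when present), carrying attributes
#'   `coordinate_system` and `skipped` (named counts of rejected records).
#' @export
read_fragments <- function(path, dialect = c("tsv", "bam"), sample = "sample1",
                           compartment_map = NULL, mapq_min = 20,
                           drop_duplicates = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("fragment file not found: %s", path), class = "cfchimera_io_error")
  }
  out <- switch(dialect,
    tsv = read_fragments_tsv(path),
    bam = read_fragments_bam(path, sample, compartment_map, mapq_min,
                             drop_duplicates)
  )
  attr(out, "coordinate_system") <- "0-based, half-open"
  out
}

read_fragments_tsv <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           ref = readr::col_character(),
                           start = readr::col_double(),
                           end = readr::col_double(),
                           sample = readr::col_character(),
                           compartment = readr::col_character(),
                           .default = readr::col_character()
                         ))
  assert_columns(raw, c("ref", "start", "end", "sample", "compartment"),
                 "fragments TSV")
  bad <- raw$end <= raw$start
  rejected <- sum(bad)
  raw <- raw[!bad, , drop = FALSE]
  raw$length <- as.integer(raw$end - raw$start)
  keep <- c("ref", "start", "end", "length", "sample", "compartment",
            intersect("bases", names(raw)))
  out <- validate_fragments(raw[keep])
  attr(out, "skipped") <- c(bad_coordinates = rejected)
  out
}

read_fragments_bam <- function(path, sample, compartment_map, mapq_min,
                               drop_duplicates) {
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar")
  res <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(what = what))[[1]]
  n <- length(res$qname)
  if (n == 0L) {
    out <- tibble(ref = character(), start = double(), end = double(),
                  length = integer(), sample = character(),
                  compartment = character())
    attr(out, "skipped") <- c(unmapped = 0L, secondary_or_supplementary = 0L,
                              not_proper_pair = 0L, duplicate = 0L,
                              low_mapq = 0L, orphan = 0L)
    return(out)
  }
  flag <- res$flag
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- bitwAnd(flag, 256L) != 0L | bitwAnd(flag, 2048L) != 0L
  paired <- bitwAnd(flag, 1L) != 0L
  proper <- bitwAnd(flag, 2L) != 0L
  duplicate <- bitwAnd(flag, 1024L) != 0L
  low_mapq <- !is.na(res$mapq) & res$mapq < mapq_min
  drop_dup <- if (drop_duplicates) duplicate else rep(FALSE, n)
  keep <- !unmapped & !secondary & paired & proper & !drop_dup & !low_mapq

  skipped <- c(
    unmapped = sum(unmapped),
    secondary_or_supplementary = sum(secondary & !unmapped),
    not_proper_pair = sum((!paired | !proper) & !unmapped & !secondary),
    duplicate = sum(drop_dup & keep == FALSE & proper & paired & !unmapped & !secondary),
    low_mapq = sum(low_mapq & proper & paired & !unmapped & !secondary & !drop_dup)
  )

  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar[keep])
  df <- tibble(
    qname = res$qname[keep],
    ref = as.character(res$rname[keep]),
    left = res$pos[keep] - 1L,              # SAM POS is 1-based
    right = res$pos[keep] - 1L + width      # half-open end
  )
  pairs <- df %>%
    dplyr::group_by(.data$qname, .data$ref) %>%
    dplyr::summarise(start = min(.data$left), end = max(.data$right),
                     n_mates = dplyr::n(), .groups = "drop")
  orphans <- sum(pairs$n_mates != 2L)
  pairs <- pairs[pairs$n_mates == 2L, , drop = FALSE]
  skipped <- c(skipped, orphan = orphans)

  comp <- default_compartment(pairs$ref, compartment_map)
  out <- tibble(
    ref = pairs$ref,
    start = as.double(pairs$start),
    end = as.double(pairs$end),
    length = as.integer(pairs$end - pairs$start),
    sample = sample,
    compartment = comp
  )
  out <- out[order(out$ref, out$start, out$end), , drop = FALSE]
  out <- validate_fragments(out)
  attr(out, "skipped") <- skipped
  out
}

default_compartment <- function(ref, compartment_map = NULL) {
  comp <- ifelse(ref %in% c("chrM", "MT", "chrMT"), "mito", "nuclear")
  if (!is.null(compartment_map)) {
    hit <- ref %in% names(compartment_map)
    comp[hit] <- unname(compartment_map[ref[hit]])
  }
  comp
}

#' Write cfDNA fragment records to TSV
#'
#' @param fragments Fragment tibble (see [read_fragments()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  validate_fragments(fragments)
  cols <- c("ref", "start", "end", "sample", "compartment",
            intersect("bases", names(fragments)))
  writeLines(COORD_HEADER, path)
  readr::write_tsv(fragments[cols], path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read and write informative-SNP tables
#'
#' The on-disk format is a TSV with columns `pos` (0-based), `donor_allele`
#' and `recipient_allele`; the reference id is stored in a `# reference=`
#' comment. `read_snps(write_snps(x))` is the identity.
#'
#' @param snps SNP tibble with columns `ref`, `pos`, `donor_allele`,
#'   `recipient_allele`.
#' @param path File path.
#' @return `read_snps()` returns the SNP tibble sorted by position;
#'   `write_snps()` returns `path` invisibly.
#' @export
write_snps <- function(snps, path) {
  validate_snps(snps)
  ref <- if ("ref" %in% names(snps) && nrow(snps) > 0L) snps$ref[[1]] else "unknown"
  writeLines(c(COORD_HEADER, paste0("# reference=", ref)), path)
  readr::write_tsv(snps[c("pos", "donor_allele", "recipient_allele")], path,
                   append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_snps
#' @export
read_snps <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("SNP file not found: %s", path), class = "cfchimera_io_error")
  }
  ref <- scan_comment_field(path, "reference") %||% "unknown"
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = "icc")
  assert_columns(raw, c("pos", "donor_allele", "recipient_allele"), "SNP TSV")
  out <- tibble(ref = rep(ref, nrow(raw)), pos = as.integer(raw$pos),
                donor_allele = raw$donor_allele,
                recipient_allele = raw$recipient_allele)
  out <- out[order(out$pos), , drop = FALSE]
  validate_snps(out)
  out
}

scan_comment_field <- function(path, field) {
  lines <- readLines(path, n = 10L, warn = FALSE)
  pat <- paste0("^#\\s*", field, "=")
  hit <- grep(pat, lines, value = TRUE)
  if (length(hit) == 0L) return(NULL)
  sub(pat, "", hit[[1]])
}

#' Read and write per-position pileup base counts
#'
#' TSV with columns `pos` (0-based), `A`, `C`, `G`, `T`; the reference id is
#' stored in a `# reference=` comment.
#'
#' @param pileup Pileup tibble with columns `pos`, `A`, `C`, `G`, `T` and an
#'   optional `ref` column.
#' @param path File path.
#' @return `read_pileup()` returns the pileup tibble; `write_pileup()`
#'   returns `path` invisibly.
#' @export
read_pileup <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("pileup file not found: %s", path), class = "cfchimera_io_error")
  }
  ref <- scan_comment_field(path, "reference") %||% "unknown"
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = "iiiii")
  assert_columns(raw, c("pos", DNA_BASES), "pileup TSV")
  counts <- as.matrix(raw[DNA_BASES])
  if (any(counts < 0)) {
    abort("pileup counts must be non-negative", class = "cfchimera_validation_error")
  }
  if (anyDuplicated(raw$pos)) {
    abort("pileup positions must be unique", class = "cfchimera_validation_error")
  }
  out <- tibble(ref = rep(ref, nrow(raw)), pos = as.integer(raw$pos))
  out[DNA_BASES] <- raw[DNA_BASES]
  out
}

#' @rdname read_pileup
#' @export
write_pileup <- function(pileup, path) {
  assert_columns(pileup, c("pos", DNA_BASES), "pileup table")
  ref <- if ("ref" %in% names(pileup) && nrow(pileup) > 0L) pileup$ref[[1]] else "unknown"
  writeLines(c(COORD_HEADER, paste0("# reference=", ref)), path)
  readr::write_tsv(pileup[c("pos", DNA_BASES)], path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' Read and write microbial hit tables
#'
#' Per-taxon alignment summaries: taxon id, genome length (bp), read count,
#' mean percent identity and mean query-coverage fraction, with an optional
#' `sample` column.
#'
#' @param hits Hit tibble with columns `taxon`, `genome_length`,
#'   `read_count`, `identity`, `query_coverage` (optional `sample`).
#' @param path File path.
#' @return `read_hits()` returns the hit tibble; `write_hits()` returns
#'   `path` invisibly.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("hits file not found: %s", path), class = "cfchimera_io_error")
  }
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  validate_hits(raw)
}

#' @rdname read_hits
#' @export
write_hits <- function(hits, path) {
  validate_hits(hits)
  readr::write_tsv(hits, path)
  invisible(path)
}

validate_hits <- function(hits) {
  assert_columns(hits, c("taxon", "genome_length", "read_count", "identity",
                         "query_coverage"), "hit table")
  if (any(hits$genome_length <= 0)) {
    abort("genome_length must be > 0", class = "cfchimera_validation_error")
  }
  if (any(hits$read_count < 0)) {
    abort("read_count must be >= 0", class = "cfchimera_validation_error")
  }
  if (any(hits$identity < 0 | hits$identity > 100)) {
    abort("identity must be in [0, 100]", class = "cfchimera_validation_error")
  }
  if (any(hits$query_coverage < 0 | hits$query_coverage > 1)) {
    abort("query_coverage must be in [0, 1]", class = "cfchimera_validation_error")
  }
  as_tibble(hits)
}

#' Read and write dPCR amplicon-panel assays
#'
#' CSV with columns `target` (`mito` or `nuclear`), `amplicon_length_bp` and
#' `copies_per_ul`.
#'
#' @param assay Assay tibble with columns `target`, `amplicon_length` and
#'   `copies`.
#' @param path File path.
#' @return `read_dpcr()` returns the assay tibble; `write_dpcr()` returns
#'   `path` invisibly.
#' @export
read_dpcr <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("dPCR file not found: %s", path), class = "cfchimera_io_error")
  }
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  assert_columns(raw, c("target", "amplicon_length_bp", "copies_per_ul"),
                 "dPCR CSV")
  out <- tibble(target = raw$target,
                amplicon_length = as.double(raw$amplicon_length_bp),
                copies = as.double(raw$copies_per_ul))
  validate_assay(out)
  out
}

#' @rdname read_dpcr
#' @export
write_dpcr <- function(assay, path) {
  assert_columns(assay, c("target", "amplicon_length", "copies"), "dPCR assay")
  readr::write_csv(
    tibble(target = assay$target,
           amplicon_length_bp = assay$amplicon_length,
           copies_per_ul = assay$copies),
    path)
  invisible(path)
}

validate_assay <- function(assay) {
  if (any(assay$amplicon_length < 1)) {
    abort("amplicon lengths must be >= 1 bp", class = "cfchimera_validation_error")
  }
  dup <- assay %>% dplyr::count(.data$target, .data$amplicon_length) %>%
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort("amplicon lengths must be unique within a target",
          class = "cfchimera_validation_error")
  }
  if (any(assay$copies < 0)) {
    abort("measured copies must be >= 0", class = "cfchimera_validation_error")
  }
  invisible(assay)
}
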