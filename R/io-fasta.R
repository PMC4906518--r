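#' Read reference or consensus sequences from FASTA
#'
#' Reads a FASTA file into a genome table. Sequences are uppercased and must
#' use the alphabet A, C, G, T, N. A header token `circular=true` marks a
#' sequence (e.g. the mitochondrial genome) as circular.
#'
#' @param path Path to a FASTA file.
#'
#' @return A tibble with one row per sequence and columns `id` (first header
#'   token), `sequence`, `length` and `circular`.
#'
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrM circular=true", "ACGTACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path), class = "cfchimera_io_error")
  }
  validate_fasta_lines(path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(tibble(id = character(), sequence = character(),
                  length = integer(), circular = logical()))
  }
  headers <- names(set)
  seqs <- unname(toupper(as.character(set)))
  tibble(
    id = vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1L),
    sequence = unname(seqs),
    length = nchar(seqs),
    circular = grepl("circular=true", headers, fixed = TRUE)
  )
}

# Line-level validation so format errors can name the offending line, which
# Biostrings' parser does not report.
validate_fasta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  in_record <- FALSE
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (grepl("^\\s*$", line)) next
    if (startsWith(line, ">")) {
      if (grepl("^>\\s*$", line)) {
        abort(sprintf("malformed FASTA header at line %d: empty id", i),
              class = "cfchimera_format_error")
      }
      in_record <- TRUE
    } else {
      if (!in_record) {
        abort(sprintf("malformed FASTA at line %d: sequence before any header", i),
              class = "cfchimera_format_error")
      }
      if (grepl("[^ACGTNacgtn]", line)) {
        bad <- regmatches(line, regexpr("[^ACGTNacgtn]", line))
        abort(sprintf("illegal character '%s' in FASTA sequence at line %d (alphabet is A,C,G,T,N)",
                      bad, i),
              class = "cfchimera_format_error")
      }
    }
  }
  invisible(TRUE)
}

#' Write sequences to FASTA
#'
#' Inverse of [read_fasta()]: writes a genome table to FASTA, appending the
#' `circular=true` header token where the `circular` column is set.
#'
#' @param genomes Tibble with columns `id`, `sequence` and optionally
#'   `circular`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path) {
  assert_columns(genomes, c("id", "sequence"), "genome table")
  circular <- if ("circular" %in% names(genomes)) genomes$circular else FALSE
  headers <- ifelse(circular, paste0(genomes$id, " circular=true"), genomes$id)
  set <- Biostrings::BStringSet(genomes$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
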