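# Shared fixtures, all generated in code.

# Small subject pair for fast module tests.
make_test_pair <- function(seed = 11, L = 3000L, n_snps = 40L) {
  simulate_subject_pair(
    subject_pair_profile(mito_genome_length = L, n_mito_substitutions = n_snps),
    seed = seed)
}

# Independent brute-force oracle for fragment assignment: re-scans every SNP
# position for every fragment, no interval-join machinery.
brute_force_assign <- function(fragments, snps) {
  vapply(seq_len(nrow(fragments)), function(i) {
    start <- fragments$start[[i]]
    end <- fragments$end[[i]]
    bases <- fragments$bases[[i]]
    labels <- character(0)
    for (j in seq_len(nrow(snps))) {
      p <- snps$pos[[j]]
      if (p >= start && p < end) {
        allele <- substr(bases, p - start + 1, p - start + 1)
        labels <- c(labels,
                    if (allele == snps$donor_allele[[j]]) "donor"
                    else if (allele == snps$recipient_allele[[j]]) "recipient"
                    else "other")
      }
    }
    if (length(labels) == 0L) "uninformative"
    else if (all(labels == "donor")) "donor"
    else if (all(labels == "recipient")) "recipient"
    else "ambiguous"
  }, character(1))
}

# Inject random base substitutions into fragment sequences so that mixed and
# third-allele cases occur.
corrupt_bases <- function(fragments, rate = 0.02) {
  bases <- strsplit(fragments$bases, "", fixed = TRUE)
  fragments$bases <- vapply(bases, function(b) {
    hit <- runif(length(b)) < rate
    b[hit] <- sample(c("A", "C", "G", "T", "N"), sum(hit), replace = TRUE)
    paste(b, collapse = "")
  }, character(1))
  fragments
}

# A coordinate-sorted SAM file with two proper pairs, one orphan read and
# one duplicate-flagged pair; converted to BAM by Rsamtools for the BAM
# dialect tests.
write_test_sam <- function(path) {
  sam_line <- function(qname, flag, pos, cigar, mpos, isize, seqlen) {
    paste(qname, flag, "chrM", pos, 60, cigar, "=", mpos, isize,
          strrep("A", seqlen), "*", sep = "\t")
  }
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chrM\tLN:16569",
    # fragment [100, 266): mates [100,175) and [150,266)
    sam_line("pair1", 99, 101, "75M", 151, 166, 75),
    sam_line("pair1", 147, 151, "116M", 101, -166, 116),
    # fragment [400, 450)
    sam_line("pair2", 99, 401, "30M", 421, 50, 30),
    sam_line("pair2", 147, 421, "30M", 401, -50, 30),
    # unpaired read: skipped
    paste("orphan", 0, "chrM", 501, 60, "50M", "*", 0, 0,
          strrep("A", 50), "*", sep = "\t"),
    # duplicate-flagged proper pair: skipped by default
    sam_line("dup1", 99 + 1024, 601, "40M", 641, 80, 40),
    sam_line("dup1", 147 + 1024, 641, "40M", 601, -80, 40)
  )
  writeLines(lines, path)
  path
}
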