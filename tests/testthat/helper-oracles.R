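# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid Biostrings and any package code path they verify.

# all k-mers of a sequence as a character vector (1 per start offset)
bf_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- 1:(n - k + 1)
  substring(seq, starts, starts + k - 1)
}

bf_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# sliding-window NGG count over both strands
bf_count_ngg <- function(seq) {
  tri <- bf_kmers(seq, 3)
  fwd <- sum(substr(tri, 2, 3) == "GG")
  rc <- bf_kmers(bf_revcomp(seq), 3)
  fwd + sum(substr(rc, 2, 3) == "GG")
}

# 0-based start offsets where pattern matches subject within max_mm
# substitutions (quadratic Hamming scan)
bf_hamming_starts <- function(pattern, subject, max_mm = 0) {
  k <- nchar(pattern)
  kmers <- bf_kmers(subject, k)
  if (length(kmers) == 0) return(integer(0))
  p <- strsplit(pattern, "")[[1]]
  mm <- vapply(kmers, function(s) {
    sum(strsplit(s, "")[[1]] != p)
  }, numeric(1), USE.NAMES = FALSE)
  which(mm <= max_mm) - 1L
}

# exact-match hit counts of many spacers against both genome strands,
# via a k-mer tally (enumeration, no pattern matching library)
bf_hit_counts <- function(spacers, genome_seq) {
  k <- nchar(spacers[1])
  stopifnot(all(nchar(spacers) == k))
  tab <- table(bf_kmers(genome_seq, k))
  fwd <- as.integer(tab[spacers]); fwd[is.na(fwd)] <- 0L
  rev <- as.integer(tab[bf_revcomp(spacers)]); rev[is.na(rev)] <- 0L
  fwd + rev
}

# closed-form OLS slope/intercept from the normal equations
bf_ols <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  c(slope = slope, intercept = (sy - slope * sx) / n)
}

# small shared fixtures
fixture_barcodes <- function() {
  barcode_spec(c("S1", "S2", "S3"), c("ACG", "TCAG", "GATCA"))
}
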