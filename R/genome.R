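#' Simulate a phage genome
#'
#' Generates a random double-stranded DNA genome that stands in for the phage
#' whose protospacers seed new CRISPR spacers. Bases are drawn i.i.d. with the
#' requested GC content.
#'
#' @param length Genome length in bp (>= 100).
#' @param gc Target GC fraction, strictly between 0 and 1.
#' @param seed Integer seed; the same (parameters, seed) pair always yields
#'   the same genome.
#' @param id Sequence identifier used in FASTA output.
#' @return An object of class `genome`: a list with `id` and `sequence`.
#' @examples
#' g <- make_phage_genome(1000, gc = 0.35, seed = 1)
#' nchar(g$sequence)
#' @export
make_phage_genome <- function(length, gc = 0.5, seed = 1L, id = "phage_sim") {
  if (!is.numeric(length) || length < 100) {
    stop("genome length must be >= 100 bp", call. = FALSE)
  }
  if (!is.numeric(gc) || gc <= 0 || gc >= 1) {
    stop("gc must lie strictly between 0 and 1", call. = FALSE)
  }
  seq <- with_seed(seed, random_dna(as.integer(length), gc))
  structure(list(id = id, sequence = seq), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d bp, GC %.1f%%\n", x$id, nchar(x$sequence),
              100 * mean(strsplit(x$sequence, "")[[1]] %in% c("G", "C"))))
  invisible(x)
}

as_genome <- function(x, id = "genome") {
  if (inherits(x, "genome")) return(x)
  assert_dna(x, "genome sequence")
  structure(list(id = id, sequence = x), class = "genome")
}

# Enumerate all protospacer placements of `len` bp whose 3' flank (on the
# match strand) fits NGG. Returns a data.frame of 0-based half-open intervals
# on the forward coordinate system.
enumerate_pam_sites <- function(genome, len, require_pam = TRUE) {
  genome <- as_genome(genome)
  seq <- genome$sequence
  L <- nchar(seq)
  out <- list()
  # forward strand: protospacer [s, s+len), PAM at [s+len, s+len+3)
  if (L >= len + 3) {
    starts <- 0:(L - len - 3L)
    pam2 <- substring(seq, starts + len + 2L, starts + len + 3L)
    keep <- if (require_pam) pam2 == "GG" else rep(TRUE, length(starts))
    if (any(keep)) {
      out[[1]] <- data.frame(start = starts[keep], end = starts[keep] + len,
                             strand = "+", stringsAsFactors = FALSE)
    }
    # reverse strand: protospacer occupies forward [s, s+len); its 3' flank on
    # the minus strand is forward [s-3, s), valid when that revcomps to NGG,
    # i.e. forward bases at [s-3, s-1) are CC.
    starts <- 3:(L - len)
    cc <- substring(seq, starts - 2L, starts - 1L)
    keep <- if (require_pam) cc == "CC" else rep(TRUE, length(starts))
    if (any(keep)) {
      out[[2]] <- data.frame(start = starts[keep], end = starts[keep] + len,
                             strand = "-", stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Sample a protospacer from a genome
#'
#' Draws a protospacer of the requested length uniformly from all eligible
#' placements on either strand. With `require_pam = TRUE` only placements
#' whose 3 nt immediately 3' of the match (on the match strand) fit NGG are
#' eligible, emulating PAM-adjacent spacer sampling by SpyCas9 systems.
#'
#' @param genome A `genome` object or plain DNA string.
#' @param length Protospacer length in bp.
#' @param require_pam Require an NGG immediately 3' of the site.
#' @param seed Integer seed.
#' @return A list with `sequence` (spacer-sense sequence), `start`, `end`
#'   (0-based half-open forward coordinates), `strand` and `pam`.
#' @export
sample_protospacer <- function(genome, length, require_pam = TRUE, seed = NULL) {
  genome <- as_genome(genome)
  if (length > nchar(genome$sequence)) {
    stop("no site available: requested length exceeds genome length",
         call. = FALSE)
  }
  sites <- enumerate_pam_sites(genome, length, require_pam)
  if (nrow(sites) == 0) {
    stop("no ", if (require_pam) "PAM-adjacent " else "",
         "site of the requested length in genome", call. = FALSE)
  }
  i <- with_seed(seed, sample.int(nrow(sites), 1L))
  site <- sites[i, ]
  seq <- substr0(genome$sequence, site$start, site$end)
  if (site$strand == "-") seq <- revcomp(seq)
  pam <- protospacer_pam(genome, site$start, site$end, site$strand)
  list(sequence = seq, start = site$start, end = site$end,
       strand = site$strand, pam = pam)
}

# 3 nt immediately 3' of a protospacer on its match strand; NA when the
# genome end leaves fewer than 3 nt of flank.
protospacer_pam <- function(genome, start, end, strand) {
  genome <- as_genome(genome)
  L <- nchar(genome$sequence)
  if (strand == "+") {
    if (end + 3 > L) return(NA_character_)
    substr0(genome$sequence, end, end + 3L)
  } else {
    if (start - 3 < 0) return(NA_character_)
    revcomp(substr0(genome$sequence, start - 3L, start))
  }
}

#' Count NGG PAM occurrences on both strands
#'
#' @param genome A `genome` object or DNA string.
#' @return Integer count of NGG trinucleotides over the two strands.
#' @export
count_pam_sites <- function(genome) {
  genome <- as_genome(genome)
  s <- Biostrings::DNAString(genome$sequence)
  fwd <- Biostrings::countPattern("NGG", s, fixed = FALSE)
  rev <- Biostrings::countPattern("CCN", s, fixed = FALSE)
  fwd + rev
}
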