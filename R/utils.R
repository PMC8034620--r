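#' @importFrom stats rbinom rgeom rnorm runif lm coef sd setNames aggregate
#' @importFrom utils write.table read.delim modifyList
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All stochastic generators route through this so
# results are bit-reproducible given (parameters, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Draw independent sub-seeds from a master seed so sibling generators do not
# share an RNG stream. Kept below 2^31 - 1.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

assert_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  if (nchar(x) > 0 && grepl("[^ACGT]", x)) {
    stop(what, " contains non-ACGT characters", call. = FALSE)
  }
  invisible(x)
}

# Apply per-base substitution errors at rate `rate`; substitutions are drawn
# uniformly from the three non-identical bases.
mutate_sequence <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- runif(length(bases)) < rate
  if (any(hit)) {
    bases[hit] <- vapply(bases[hit], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1))
  }
  paste(bases, collapse = "")
}

# Phred+33 encoding helpers for Sanger-style quality strings.
phred_to_string <- function(q) {
  intToUtf8(pmin(pmax(round(q), 0L), 60L) + 33L)
}

string_to_phred <- function(s) {
  if (nchar(s) == 0) return(numeric(0))
  utf8ToInt(s) - 33
}

mean_quality <- function(qual_string) {
  q <- string_to_phred(qual_string)
  if (length(q) == 0) return(NA_real_)
  mean(q)
}

# 0-based substring: seq[start, end) in half-open coordinates.
substr0 <- function(seq, start, end) {
  if (end <= start) return("")
  substr(seq, start + 1L, end)
}
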