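#' Map a spacer to the phage genome by perfect matching
#'
#' Exact-substring search of the spacer against the forward strand and of
#' its reverse complement against the forward strand (equivalently, against
#' the minus strand). All hits are enumerated; a unique hit yields the
#' protospacer interval, strand and PAM. Spacers matching at more than one
#' site are flagged ambiguous and carry no unique interval.
#'
#' @param spacer DNA string (A/C/G/T only), at least `min_length` bp.
#' @param genome A `genome` object or DNA string.
#' @param min_length Minimum spacer length accepted for mapping (default 15).
#' @param circular Treat the genome as circular (wrap-around matches and
#'   PAM flanks).
#' @return A list of class `mapping_result`: `spacer`, `hit_count`,
#'   `ambiguous`, and (for unique hits) `start`, `end` (0-based half-open
#'   forward coordinates), `strand`, `pam`, `pam_valid`.
#' @examples
#' g <- make_phage_genome(2000, seed = 5)
#' sp <- substr(g$sequence, 101, 130)
#' map_spacer(sp, g)$start  # 100
#' @export
map_spacer <- function(spacer, genome, min_length = 15L, circular = FALSE) {
  assert_dna(spacer, "spacer")
  genome <- as_genome(genome)
  if (nchar(spacer) < min_length) {
    stop("spacer shorter than the ", min_length, " bp mapping floor",
         call. = FALSE)
  }
  L <- nchar(genome$sequence)
  k <- nchar(spacer)
  subject_seq <- genome$sequence
  if (circular && k + 3 <= L) {
    # append a prefix so matches and PAM flanks can wrap the origin
    subject_seq <- paste0(subject_seq, substr(genome$sequence, 1L, k + 2L))
  }
  subject <- Biostrings::DNAString(subject_seq)
  fwd <- BiocGenerics::start(Biostrings::matchPattern(spacer, subject)) - 1L
  rev <- BiocGenerics::start(
    Biostrings::matchPattern(revcomp(spacer), subject)) - 1L
  if (circular) {
    # matches starting in the appended prefix duplicate their linear twin
    fwd <- sort(unique(ifelse(fwd >= L, fwd - L, fwd)))
    rev <- sort(unique(ifelse(rev >= L, rev - L, rev)))
  }
  hits <- rbind(
    if (length(fwd)) data.frame(start = fwd, strand = "+") else NULL,
    if (length(rev)) data.frame(start = rev, strand = "-") else NULL)
  hit_count <- if (is.null(hits)) 0L else nrow(hits)
  out <- list(spacer = spacer, hit_count = hit_count,
              ambiguous = hit_count > 1L,
              start = NA_integer_, end = NA_integer_,
              strand = NA_character_, pam = NA_character_, pam_valid = NA)
  if (hit_count == 1L) {
    out$start <- hits$start[1]
    out$end <- hits$start[1] + k
    out$strand <- hits$strand[1]
    pam <- classify_pam(out$start, out$end, out$strand, genome,
                        circular = circular)
    out$pam <- pam$pam
    out$pam_valid <- pam$pam_valid
  }
  structure(out, class = "mapping_result")
}

#' Classify the PAM of a mapped protospacer
#'
#' Reads the 3 nt immediately 3' of the protospacer on the match strand
#' (the canonical SpyCas9 convention) and tests them against NGG.
#'
#' @param start,end 0-based half-open interval on the forward strand.
#' @param strand `"+"` or `"-"`.
#' @param genome A `genome` object or DNA string.
#' @param circular Wrap PAM flanks around the genome origin.
#' @return List with `pam` (3-nt string, or NA when the match abuts the
#'   genome end) and `pam_valid` (TRUE iff positions 2-3 are GG; FALSE when
#'   unavailable).
#' @export
classify_pam <- function(start, end, strand, genome, circular = FALSE) {
  genome <- as_genome(genome)
  L <- nchar(genome$sequence)
  seq <- genome$sequence
  grab <- function(i0, i1) {  # 0-based half-open with optional wrap
    if (i0 >= 0 && i1 <= L) return(substr0(seq, i0, i1))
    if (!circular) return(NA_character_)
    idx <- ((i0:(i1 - 1L)) %% L) + 1L
    paste(strsplit(seq, "")[[1]][idx], collapse = "")
  }
  pam <- if (strand == "+") grab(end, end + 3L) else {
    flank <- grab(start - 3L, start)
    if (is.na(flank)) NA_character_ else revcomp(flank)
  }
  list(pam = pam,
       pam_valid = !is.na(pam) && substr(pam, 2L, 3L) == "GG")
}

#' Map a table of spacer calls to the genome
#'
#' Maps each unique spacer sequence once and joins results back to the call
#' table.
#'
#' @param calls data.frame with a `spacer` column (e.g. from
#'   [call_spacers()]).
#' @inheritParams map_spacer
#' @return data.frame: one row per input row with appended columns
#'   `hit_count`, `ambiguous`, `start`, `end`, `strand`, `pam`, `pam_valid`.
#' @export
map_spacers <- function(calls, genome, min_length = 15L, circular = FALSE) {
  stopifnot(is.data.frame(calls), "spacer" %in% names(calls))
  uniq <- unique(calls$spacer)
  res <- lapply(uniq, function(s) {
    m <- map_spacer(s, genome, min_length = min_length, circular = circular)
    data.frame(spacer = s, hit_count = m$hit_count, ambiguous = m$ambiguous,
               start = m$start, end = m$end, strand = m$strand,
               pam = m$pam, pam_valid = m$pam_valid,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res_cols <- c("hit_count", "ambiguous", "start", "end", "strand", "pam",
                "pam_valid")
  clash <- intersect(names(calls), res_cols)
  names(calls)[match(clash, names(calls))] <- paste0(clash, ".input")
  merge(calls, res, by = "spacer", sort = FALSE)[
    , c(setdiff(names(calls), "spacer"), "spacer", res_cols)]
}
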