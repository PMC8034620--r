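#' Demultiplex barcoded amplicon reads
#'
#' Assigns each read to a sample by exact match of the 3-5 bp barcode found
#' at positions 6..(5+barcode length), immediately after the 5-nt random tag
#' (UMI). Because the barcode set is prefix-free, a read matches at most one
#' sample. Unassigned or too-short reads are logged with a reason.
#'
#' @param reads data.frame with columns `read_id`, `sequence` and optionally
#'   `quality` (as written by [simulate_acquisition_reads()] or read with
#'   [read_fastq()]).
#' @param barcodes A [barcode_spec()] or data.frame with `sample_id`,
#'   `barcode`.
#' @param min_payload Minimum payload length (bases after tag + barcode)
#'   for a read to be kept; shorter reads are rejected as `too_short`.
#' @return A list with `assigned` (data.frame: `read_id`, `sample_id`, `umi`,
#'   `payload`) and `rejected` (data.frame: `read_id`, `reason`).
#' @export
demultiplex <- function(reads, barcodes, min_payload = 0L) {
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  barcodes <- as_barcode_spec(barcodes)
  umi_len <- 5L
  seqs <- toupper(reads$sequence)
  n <- length(seqs)
  sample_id <- rep(NA_character_, n)
  bc_len <- rep(NA_integer_, n)
  reason <- rep(NA_character_, n)

  too_short <- nchar(seqs) < umi_len + min(nchar(barcodes$barcode)) + min_payload
  reason[too_short] <- "too_short"
  for (j in seq_len(nrow(barcodes))) {
    b <- barcodes$barcode[j]
    hit <- !too_short & is.na(sample_id) &
      substr(seqs, umi_len + 1L, umi_len + nchar(b)) == b
    sample_id[hit] <- barcodes$sample_id[j]
    bc_len[hit] <- nchar(b)
  }
  reason[is.na(sample_id) & is.na(reason)] <- "unknown_barcode"
  # re-check payload length against this sample's own barcode length
  assigned <- !is.na(sample_id)
  short2 <- assigned & nchar(seqs) < umi_len + bc_len + min_payload
  reason[short2] <- "too_short"
  sample_id[short2] <- NA_character_
  assigned <- !is.na(sample_id)

  list(
    assigned = data.frame(
      read_id = reads$read_id[assigned],
      sample_id = sample_id[assigned],
      umi = substr(seqs[assigned], 1L, umi_len),
      payload = substring(seqs[assigned], umi_len + bc_len[assigned] + 1L),
      stringsAsFactors = FALSE),
    rejected = data.frame(
      read_id = reads$read_id[!assigned],
      reason = reason[!assigned],
      stringsAsFactors = FALSE)
  )
}

# All occurrences of the repeat in `payload` within `max_mismatch`
# substitutions, as 0-based half-open start/end positions. Overlapping
# occurrences are resolved greedily left-to-right so tandem repeats in an
# expanded array are each reported once.
find_repeats <- function(payload, repeat_seq, max_mismatch = 0L) {
  m <- Biostrings::matchPattern(repeat_seq, Biostrings::DNAString(payload),
                                max.mismatch = max_mismatch,
                                with.indels = FALSE)
  starts <- BiocGenerics::start(m) - 1L
  if (length(starts) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  rlen <- nchar(repeat_seq)
  keep <- integer(0)
  last_end <- -1L
  for (s in sort(starts)) {
    if (s >= last_end) {
      keep <- c(keep, s)
      last_end <- s + rlen
    }
  }
  data.frame(start = keep, end = keep + rlen)
}

#' Call a newly acquired spacer from one demultiplexed read
#'
#' Scans the read payload for direct-repeat copies (allowing up to
#' `max_repeat_mismatches` substitutions per copy). An expanded array shows
#' at least two repeats; the sequence between the leader-proximal repeat and
#' the next repeat is the candidate new spacer. When the parent array
#' already carries spacers, a call is made only if the candidate differs
#' from the original spacer 1 (an unexpanded parent read).
#'
#' @param payload Locus portion of a demultiplexed read (DNA string).
#' @param model The parent [crispr_array_model()].
#' @param max_repeat_mismatches Substitutions tolerated per repeat copy.
#' @param min_spacer_length Minimum callable spacer length in bp.
#' @return A list with `status` (`"call"`, `"no_expansion"`, or
#'   `"malformed"`), and for calls: `spacer`, `length`,
#'   `multi_acquisition` (TRUE when more than one new spacer is present).
#' @export
call_expanded_array <- function(payload, model, max_repeat_mismatches = 2L,
                                min_spacer_length = 10L) {
  stopifnot(inherits(model, "crispr_array_model"))
  reps <- find_repeats(payload, model$repeat_seq, max_repeat_mismatches)
  if (nrow(reps) == 0) {
    return(list(status = "malformed", reason = "no_repeat_found"))
  }
  n_orig <- length(model$spacers)
  # number of repeats expected in an unexpanded read: n_orig + 1
  if (nrow(reps) < 2) {
    return(list(status = "no_expansion"))
  }
  candidate <- substr0(payload, reps$end[1], reps$start[2])
  if (n_orig > 0 && candidate == model$spacers[1]) {
    return(list(status = "no_expansion"))
  }
  if (nchar(candidate) < min_spacer_length) {
    return(list(status = "malformed", reason = "spacer_too_short"))
  }
  if (nrow(find_repeats(candidate, model$repeat_seq,
                        max_repeat_mismatches)) > 0) {
    return(list(status = "malformed", reason = "repeat_within_spacer"))
  }
  multi <- nrow(reps) > n_orig + 2L
  list(status = "call", spacer = candidate, length = nchar(candidate),
       multi_acquisition = multi)
}

#' Call spacers across a demultiplexed read set
#'
#' Vectorised driver for [call_expanded_array()].
#'
#' @param demuxed `assigned` data.frame from [demultiplex()].
#' @param model The parent [crispr_array_model()].
#' @inheritParams call_expanded_array
#' @return A list with `calls` (data.frame: `read_id`, `sample_id`, `umi`,
#'   `spacer`, `length`, `multi_acquisition`) and `rejected` (data.frame:
#'   `read_id`, `reason`).
#' @export
call_spacers <- function(demuxed, model, max_repeat_mismatches = 2L,
                         min_spacer_length = 10L) {
  stopifnot(is.data.frame(demuxed),
            all(c("read_id", "sample_id", "umi", "payload") %in% names(demuxed)))
  res <- lapply(demuxed$payload, call_expanded_array, model = model,
                max_repeat_mismatches = max_repeat_mismatches,
                min_spacer_length = min_spacer_length)
  status <- vapply(res, `[[`, character(1), "status")
  is_call <- status == "call"
  calls <- data.frame(
    read_id = demuxed$read_id[is_call],
    sample_id = demuxed$sample_id[is_call],
    umi = demuxed$umi[is_call],
    spacer = vapply(res[is_call], `[[`, character(1), "spacer"),
    length = vapply(res[is_call], `[[`, integer(1), "length"),
    multi_acquisition = vapply(res[is_call], `[[`, logical(1),
                               "multi_acquisition"),
    stringsAsFactors = FALSE)
  bad <- status == "malformed"
  rejected <- data.frame(
    read_id = demuxed$read_id[bad],
    reason = vapply(res[bad], `[[`, character(1), "reason"),
    stringsAsFactors = FALSE)
  list(calls = calls, rejected = rejected,
       n_no_expansion = sum(status == "no_expansion"))
}
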