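#' Collapse PCR duplicates by distinct-tag counting
#'
#' PCR-bias normalisation: the 5-nt random tag attached before amplification
#' marks each original molecule, so the number of distinct tags per unique
#' spacer sequence (per sample) estimates the number of independent
#' acquisition events, independent of per-event duplication depth.
#'
#' @param calls data.frame of spacer calls with columns `sample_id`,
#'   `spacer`, `length`, `umi`.
#' @return data.frame: one row per (sample, spacer) with `raw_reads`,
#'   `distinct_umis` (the normalised abundance) and `length`.
#' @export
normalize_counts <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("sample_id", "spacer", "length", "umi") %in% names(calls)))
  if (nrow(calls) == 0) {
    return(data.frame(sample_id = character(0), spacer = character(0),
                      length = integer(0), raw_reads = integer(0),
                      distinct_umis = integer(0), stringsAsFactors = FALSE))
  }
  if (any(nchar(calls$umi) != 5L)) {
    stop("all tags must be 5 nt", call. = FALSE)
  }
  key <- paste(calls$sample_id, calls$spacer, sep = "\r")
  raw <- tapply(calls$umi, key, length)
  umis <- tapply(calls$umi, key, function(u) length(unique(u)))
  lens <- tapply(calls$length, key, `[`, 1L)
  samp <- tapply(calls$sample_id, key, `[`, 1L)
  spac <- tapply(calls$spacer, key, `[`, 1L)
  out <- data.frame(sample_id = as.character(samp),
                    spacer = as.character(spac),
                    length = as.integer(lens),
                    raw_reads = as.integer(raw),
                    distinct_umis = as.integer(umis),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$sample_id, out$spacer), , drop = FALSE]
}

#' Expected number of tag collisions (birthday bound)
#'
#' Expected number of events sharing a 5-nt random tag with an earlier
#' event of the same spacer, under uniform tag draws:
#' `n - K * (1 - (1 - 1/K)^n)` with `K = 4^umi_length`.
#'
#' @param n_events Number of events drawing tags.
#' @param umi_length Tag length in nt (default 5).
#' @return Expected collision count (numeric).
#' @export
expected_umi_collisions <- function(n_events, umi_length = 5L) {
  K <- 4^umi_length
  n_events - K * (1 - (1 - 1 / K)^n_events)
}

#' Spacer-length distribution over unique sequences
#'
#' Each unique spacer sequence contributes once, regardless of read or tag
#' abundance; per-length percentages are taken over the number of unique
#' sequences in the sample. With `abundance_weighted = TRUE`, sequences are
#' weighted by their distinct-tag counts instead.
#'
#' @param tab Per-spacer table from [normalize_counts()] (columns
#'   `sample_id`, `spacer`, `length`, `distinct_umis`).
#' @param abundance_weighted Weight by `distinct_umis` instead of counting
#'   unique sequences once (off by default).
#' @return data.frame: `sample_id`, `length`, `percent`, `n_unique`;
#'   percentages sum to 100 within each sample. Empty input yields an empty
#'   distribution.
#' @export
length_distribution <- function(tab, abundance_weighted = FALSE) {
  stopifnot(is.data.frame(tab))
  if (nrow(tab) == 0) {
    return(data.frame(sample_id = character(0), length = integer(0),
                      percent = numeric(0), n_unique = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(split(tab, tab$sample_id), function(d) {
    w <- if (abundance_weighted) d$distinct_umis else rep(1L, nrow(d))
    tot <- sum(w)
    agg <- tapply(w, d$length, sum)
    data.frame(sample_id = d$sample_id[1],
               length = as.integer(names(agg)),
               percent = 100 * as.numeric(agg) / tot,
               n_unique = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$sample_id, out$length), , drop = FALSE]
}

#' Summarise protospacer mapping results
#'
#' Deterministic aggregation of a mapping table: the fraction of spacers
#' mapping uniquely, and PAM validity and strand balance among unique
#' mappers (ambiguous multi-hit spacers are excluded from PAM/orientation
#' summaries).
#'
#' @param mapping data.frame from [map_spacers()].
#' @return List: `n_spacers`, `percent_unique`, `percent_pam_valid`,
#'   `percent_plus_strand` (all zero for an empty table).
#' @export
summarize_mapping <- function(mapping) {
  stopifnot(is.data.frame(mapping))
  if (nrow(mapping) == 0) {
    return(list(n_spacers = 0L, percent_unique = 0,
                percent_pam_valid = 0, percent_plus_strand = 0))
  }
  uniq <- mapping[mapping$hit_count == 1L, , drop = FALSE]
  list(
    n_spacers = nrow(mapping),
    percent_unique = 100 * nrow(uniq) / nrow(mapping),
    percent_pam_valid = if (nrow(uniq)) {
      100 * mean(uniq$pam_valid %in% TRUE)
    } else 0,
    percent_plus_strand = if (nrow(uniq)) {
      100 * mean(uniq$strand == "+")
    } else 0)
}

#' Fit processing rates from a kinetics time course
#'
#' Ordinary least-squares regression of fraction processed against time,
#' fitted per replicate; the reported rate is the mean slope across
#' replicates with its SD (the assay design uses three replicates).
#'
#' @param series data.frame with columns `time` (minutes), `fraction`
#'   (in `[0, 1]`) and optionally `replicate`.
#' @return List: `slope` (mean across replicates, fraction per minute),
#'   `slope_sd`, `intercept`, and `fits` (per-replicate data.frame with
#'   `replicate`, `slope`, `intercept`).
#' @export
fit_processing_rate <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("time", "fraction") %in% names(series)))
  if (is.null(series$replicate)) series$replicate <- 1L
  if (any(series$fraction < 0 | series$fraction > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  fits <- lapply(split(series, series$replicate), function(d) {
    if (length(unique(d$time)) < 2) {
      stop("at least 2 timepoints are required per replicate", call. = FALSE)
    }
    fit <- lm(fraction ~ time, data = d)
    data.frame(replicate = d$replicate[1],
               slope = unname(coef(fit)[["time"]]),
               intercept = unname(coef(fit)[["(Intercept)"]]))
  })
  fits <- do.call(rbind, fits)
  rownames(fits) <- NULL
  list(slope = mean(fits$slope),
       slope_sd = if (nrow(fits) > 1) sd(fits$slope) else NA_real_,
       intercept = mean(fits$intercept),
       fits = fits)
}
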