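#' Simulate barcoded amplicon reads of expanded CRISPR arrays
#'
#' Emulates the acquisition deep-sequencing assay: each acquisition event
#' draws a PAM-adjacent protospacer from the phage genome (length sampled
#' from `length_weights`), inserts it with a duplicated repeat at the
#' leader-proximal edge of the parent array, and is amplified into `k`
#' duplicate reads with `k` drawn from the PCR duplication-factor
#' distribution. Every read carries the assay's 5' structure:
#' `[5-nt random tag][sample barcode][constant primer anchor][locus]`.
#'
#' @param model A [crispr_array_model()] describing the parent locus.
#' @param genome A `genome` (see [make_phage_genome()]).
#' @param barcodes A [barcode_spec()]; events are assigned to samples
#'   uniformly.
#' @param n_events Number of independent acquisition events.
#' @param length_weights Named numeric vector mapping spacer length (bp) to
#'   probability; must sum to 1. Default concentrates on 30-31 bp, the
#'   lengths dominating in vivo acquisition.
#' @param pcr_bias PCR duplication-factor distribution: either a single
#'   positive integer (constant factor) or a function `n -> integer vector`
#'   of per-event duplication factors. Default is geometric with mean 3.
#' @param error_rate Per-base substitution probability applied independently
#'   to every emitted read copy.
#' @param require_pam Sample only PAM-adjacent protospacers (default TRUE).
#' @param anchor Constant 20-nt primer anchor between barcode and locus.
#' @param downstream_bases Backbone bases retained 3' of the array in the
#'   amplicon.
#' @param seed Integer seed; output is bit-reproducible.
#' @return An object of class `acquisition_sim`: list with `reads` (data.frame
#'   `read_id`, `sequence`, `quality`), `truth` (one row per event:
#'   `event_id`, `sample_id`, `umi`, `spacer`, `length`, `strand`, `start`,
#'   `end`, `pam`, `n_reads`), and `tag_collisions` (events sharing
#'   sample, spacer and tag with an earlier event).
#' @export
simulate_acquisition_reads <- function(model, genome, barcodes,
                                       n_events,
                                       length_weights = c("30" = 0.7, "31" = 0.2, "32" = 0.1),
                                       pcr_bias = NULL,
                                       error_rate = 0,
                                       require_pam = TRUE,
                                       anchor = "ACACGACGCTCTTCCGATCT",
                                       downstream_bases = 60L,
                                       seed = 1L) {
  stopifnot(inherits(model, "crispr_array_model"))
  genome <- as_genome(genome)
  barcodes <- as_barcode_spec(barcodes)
  if (n_events < 1) stop("n_events must be >= 1", call. = FALSE)
  w <- as.numeric(length_weights)
  lens <- as.integer(names(length_weights))
  if (anyNA(lens) || any(w < 0) || abs(sum(w) - 1) > 1e-6) {
    stop("length_weights must be named by integer lengths and sum to 1",
         call. = FALSE)
  }
  if (error_rate < 0 || error_rate > 1) {
    stop("error_rate must lie in [0, 1]", call. = FALSE)
  }
  assert_dna(anchor, "anchor")
  dup_fun <- pcr_bias_function(pcr_bias)

  down <- substr(model$backbone_down, 1L,
                 min(nchar(model$backbone_down), downstream_bases))
  locus_tail <- if (length(model$spacers)) {
    paste0(paste0(model$spacers, model$repeat_seq, collapse = ""), down)
  } else down

  with_seed(seed, {
    ev_len <- lens[sample.int(length(lens), n_events, replace = TRUE,
                              prob = w)]
    ev_sample <- sample(barcodes$sample_id, n_events, replace = TRUE)
    ev_umi <- vapply(seq_len(n_events), function(i) random_dna(5L),
                     character(1))
    dup <- dup_fun(n_events)
    if (any(dup < 1) || anyNA(dup)) {
      stop("pcr_bias must yield duplication factors >= 1", call. = FALSE)
    }
    site_cache <- lapply(setNames(nm = as.character(sort(unique(ev_len)))),
                         function(l) {
      tab <- enumerate_pam_sites(genome, as.integer(l), require_pam)
      if (nrow(tab) == 0) {
        stop("no ", if (require_pam) "PAM-adjacent " else "",
             "protospacer of length ", l, " in genome", call. = FALSE)
      }
      tab
    })
    sites <- lapply(ev_len, function(len) {
      tab <- site_cache[[as.character(len)]]
      tab[sample.int(nrow(tab), 1L), ]
    })
    truth <- do.call(rbind, sites)
    truth$spacer <- vapply(seq_len(n_events), function(i) {
      s <- substr0(genome$sequence, truth$start[i], truth$end[i])
      if (truth$strand[i] == "-") revcomp(s) else s
    }, character(1))
    truth$pam <- vapply(seq_len(n_events), function(i) {
      protospacer_pam(genome, truth$start[i], truth$end[i], truth$strand[i])
    }, character(1))
    truth <- data.frame(event_id = sprintf("ev%05d", seq_len(n_events)),
                        sample_id = ev_sample, umi = ev_umi,
                        spacer = truth$spacer, length = ev_len,
                        strand = truth$strand, start = truth$start,
                        end = truth$end, pam = truth$pam,
                        n_reads = as.integer(dup),
                        stringsAsFactors = FALSE)

    bc <- barcodes$barcode[match(ev_sample, barcodes$sample_id)]
    amplicon <- paste0(ev_umi, bc, anchor, model$leader, model$repeat_seq,
                       truth$spacer, model$repeat_seq, locus_tail)
    idx <- rep.int(seq_len(n_events), dup)
    copy <- sequence(dup)
    seqs <- amplicon[idx]
    if (error_rate > 0) {
      seqs <- vapply(seqs, mutate_sequence, character(1), rate = error_rate,
                     USE.NAMES = FALSE)
    }
    reads <- data.frame(
      read_id = sprintf("%s_c%02d", truth$event_id[idx], copy),
      sequence = seqs,
      quality = vapply(nchar(seqs), function(n) strrep("I", n), character(1)),
      stringsAsFactors = FALSE)

    collisions <- as.integer(n_events) -
      nrow(unique(truth[, c("sample_id", "spacer", "umi")]))
    structure(list(reads = reads, truth = truth,
                   tag_collisions = collisions,
                   anchor = anchor),
              class = "acquisition_sim")
  })
}

pcr_bias_function <- function(pcr_bias) {
  if (is.null(pcr_bias)) {
    # geometric duplication-factor model, mean 3
    function(n) 1L + rgeom(n, prob = 1 / 3)
  } else if (is.function(pcr_bias)) {
    pcr_bias
  } else if (is.numeric(pcr_bias) && length(pcr_bias) == 1L && pcr_bias >= 1) {
    k <- as.integer(pcr_bias)
    function(n) rep.int(k, n)
  } else {
    stop("pcr_bias must be NULL, a constant >= 1 or a function(n)",
         call. = FALSE)
  }
}

as_barcode_spec <- function(x) {
  if (inherits(x, "barcode_spec")) return(x)
  if (is.data.frame(x) && all(c("sample_id", "barcode") %in% names(x))) {
    return(barcode_spec(x$sample_id, x$barcode))
  }
  stop("barcodes must be a barcode_spec or data.frame with sample_id, barcode",
       call. = FALSE)
}

#' @export
print.acquisition_sim <- function(x, ...) {
  cat(sprintf("<acquisition_sim> %d events, %d reads, %d tag collision(s)\n",
              nrow(x$truth), nrow(x$reads), x$tag_collisions))
  invisible(x)
}
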