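#' Describe a parent CRISPR array
#'
#' The model captures the leader/repeat/spacer architecture of the parent
#' plasmid locus used for acquisition assays: a leader, `n + 1` identical
#' direct repeat copies interleaved with `n` pre-existing spacers (indexed
#' 1..n from the leader), and backbone flanks on either side. The default in
#' vivo construct carries a single repeat and no spacer.
#'
#' @param leader Leader DNA string (upstream of the first repeat).
#' @param repeat_seq Direct repeat DNA string; all copies are identical.
#'   Type II-A repeats are 36 bp.
#' @param spacers Character vector of pre-existing spacer sequences, ordered
#'   from the leader; may be empty.
#' @param backbone_up,backbone_down Backbone DNA flanking the locus.
#' @return An object of class `crispr_array_model`.
#' @examples
#' m <- random_array_model(n_spacers = 0, seed = 7)
#' m$repeat_seq
#' @export
crispr_array_model <- function(leader, repeat_seq, spacers = character(0),
                               backbone_up = "", backbone_down = "") {
  assert_dna(leader, "leader")
  assert_dna(repeat_seq, "repeat")
  if (nchar(repeat_seq) < 8) stop("repeat must be at least 8 bp", call. = FALSE)
  if (length(spacers)) {
    for (s in spacers) assert_dna(s, "spacer")
    if (anyDuplicated(spacers)) {
      stop("pre-existing spacers must be pairwise distinct", call. = FALSE)
    }
  }
  if (nchar(backbone_up) > 0) assert_dna(backbone_up, "backbone_up")
  if (nchar(backbone_down) > 0) assert_dna(backbone_down, "backbone_down")
  structure(list(leader = leader, repeat_seq = repeat_seq,
                 spacers = as.character(spacers),
                 backbone_up = backbone_up, backbone_down = backbone_down),
            class = "crispr_array_model")
}

#' @export
print.crispr_array_model <- function(x, ...) {
  cat(sprintf(
    "<crispr_array_model> leader %d bp, repeat %d bp x %d, %d spacer(s)\n",
    nchar(x$leader), nchar(x$repeat_seq), length(x$spacers) + 1L,
    length(x$spacers)))
  invisible(x)
}

#' Generate a random parent array model
#'
#' Convenience constructor for simulations: random leader, repeat and
#' backbone flanks with `n_spacers` distinct random spacers.
#'
#' @param n_spacers Number of pre-existing spacers (0 for the single-repeat
#'   construct used in phage-challenge acquisition assays).
#' @param repeat_length Direct repeat length in bp (36 for type II-A).
#' @param spacer_length Length of pre-existing spacers in bp.
#' @param leader_length,flank_length Lengths of the leader and backbone
#'   flanks in bp.
#' @param seed Integer seed.
#' @return A `crispr_array_model`.
#' @export
random_array_model <- function(n_spacers = 0L, repeat_length = 36L,
                               spacer_length = 30L, leader_length = 80L,
                               flank_length = 300L, seed = 1L) {
  with_seed(seed, {
    spacers <- character(0)
    while (length(unique(spacers)) < n_spacers) {
      spacers <- unique(c(spacers, random_dna(spacer_length)))
    }
    crispr_array_model(
      leader = random_dna(leader_length),
      repeat_seq = random_dna(repeat_length),
      spacers = spacers,
      backbone_up = random_dna(flank_length),
      backbone_down = random_dna(flank_length)
    )
  })
}

# Locus sequence from leader through the array into the downstream backbone,
# optionally with a new spacer (plus duplicated repeat) at the leader-proximal
# edge. Used both by the read simulator and by callers building references.
array_locus_sequence <- function(model, new_spacer = NULL) {
  stopifnot(inherits(model, "crispr_array_model"))
  r <- model$repeat_seq
  arr <- r
  if (!is.null(new_spacer)) arr <- paste0(arr, new_spacer, r)
  if (length(model$spacers)) {
    arr <- paste0(arr, paste0(model$spacers, r, collapse = ""))
  }
  paste0(model$leader, arr, model$backbone_down)
}

# Full parent plasmid sequence (linearised): upstream backbone + locus.
parent_plasmid_sequence <- function(model) {
  paste0(model$backbone_up, array_locus_sequence(model))
}

#' Define sample barcodes for demultiplexing
#'
#' Amplicon reads carry a 5-nt random tag (UMI) followed by a per-sample
#' barcode of 3-5 bp at their 5' end. The barcode set must be prefix-free so
#' each read matches at most one sample.
#'
#' @param sample_id Character vector of sample names.
#' @param barcode Character vector of 3-5 bp barcodes, one per sample.
#' @param umi_length UMI length in nt (fixed at 5 in this assay).
#' @return A data.frame of class `barcode_spec`.
#' @export
barcode_spec <- function(sample_id, barcode, umi_length = 5L) {
  if (length(sample_id) != length(barcode)) {
    stop("sample_id and barcode must have equal length", call. = FALSE)
  }
  if (anyDuplicated(sample_id)) stop("duplicate sample_id", call. = FALSE)
  for (b in barcode) assert_dna(b, "barcode")
  nb <- nchar(barcode)
  if (any(nb < 3 | nb > 5)) {
    stop("barcodes must be 3-5 bp long", call. = FALSE)
  }
  check_prefix_free(barcode)
  if (umi_length != 5L) stop("umi_length must be 5", call. = FALSE)
  structure(data.frame(sample_id = as.character(sample_id),
                       barcode = toupper(barcode),
                       stringsAsFactors = FALSE),
            umi_length = 5L, class = c("barcode_spec", "data.frame"))
}

check_prefix_free <- function(barcodes) {
  if (anyDuplicated(barcodes)) {
    stop("barcode set is not prefix-free (duplicates present)", call. = FALSE)
  }
  n <- length(barcodes)
  if (n < 2) return(invisible(TRUE))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && startsWith(barcodes[j], barcodes[i])) {
        stop("barcode set is not prefix-free: '", barcodes[i],
             "' is a prefix of '", barcodes[j], "'", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}
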