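CASSETTE_ANCHOR <- 30L  # Sanger primers sit this far inside each cassette end

COLONY_CLASSES <- c("full_site_repeat_edge", "ectopic_site",
                    "nonconsecutive_flank", "prespacer_end_indel",
                    "low_quality_trace")

#' Generate a selection cassette sequence
#'
#' Random stand-in for the chloramphenicol selection cassette that Golden
#' Gate assembly swaps into the central BbsI region of an integrated spacer.
#' The cassette carries two internal Sanger primer sites, 10 nt inside each
#' end, oriented outward toward the flanking array.
#'
#' @param length Cassette length in bp (>= 80).
#' @param seed Integer seed.
#' @return A single DNA string.
#' @export
make_selection_cassette <- function(length = 200L, seed = 11L) {
  if (length < 80) stop("cassette must be >= 80 bp", call. = FALSE)
  with_seed(seed, random_dna(length))
}

# Symmetric, centre-anchored trim of the substrate duplex to length L,
# preserving the central 24-bp region: returns the flank lengths (l, r)
# such that l + 24 + r == L.
centred_flanks <- function(substrate, L) {
  D <- substrate$duplex_length
  c0 <- if (!is.null(substrate$bbsi_interval)) substrate$bbsi_interval[1] else
    (D - BBSI_CASSETTE_SPAN) %/% 2L
  l <- ceiling((L - BBSI_CASSETTE_SPAN) / 2)
  r <- (L - BBSI_CASSETTE_SPAN) - l
  l <- min(l, c0)
  r <- min(r, D - (c0 + BBSI_CASSETTE_SPAN))
  c(l = as.integer(l), r = as.integer(r), c0 = as.integer(c0))
}

#' Simulate colonies from a full-site integration screen
#'
#' Builds one plasmid per colony according to its (sampled) event class,
#' then emits the pair of outward-facing Sanger reads from the two
#' cassette-internal primer sites. Full-site events insert the (possibly
#' trimmed) spacer with a duplicated repeat at a repeat edge, with the
#' selection cassette replacing the central 24-bp BbsI region; defect
#' classes model ectopic insertion, recombination that leaves nonconsecutive
#' flanking spacers, indels/substitutions at the prespacer ends, and
#' low-quality traces. Spacer orientation is drawn uniformly.
#'
#' @param model A [crispr_array_model()]. `nonconsecutive_flank` events need
#'   at least 2 pre-existing spacers.
#' @param substrate A `prespacer_substrate` with a central BbsI cassette.
#' @param class_probs Named probabilities over the five event classes;
#'   must sum to 1.
#' @param n_colonies Number of colonies.
#' @param read_len Sanger read length in nt.
#' @param error_rate Per-base substitution probability for read emission.
#' @param cassette Selection cassette sequence; default
#'   [make_selection_cassette()].
#' @param trim Logical: apply the stochastic trimming model to set each
#'   event's spacer length (default TRUE); when FALSE the full duplex is
#'   integrated.
#' @param trim_target,trim_noise_sd,trim_efficiency Trimming model
#'   parameters as in [simulate_trimming()].
#' @param seed Integer seed.
#' @return An object of class `colony_sim`: list with `pairs` (data.frame:
#'   `colony_id`, `fwd_read`, `fwd_qual`, `rev_read`, `rev_qual`), `truth`
#'   (per-colony ground truth, withheld from the annotator), `cassette`.
#' @export
simulate_integration_colonies <- function(model, substrate,
                                          class_probs = c(
                                            full_site_repeat_edge = 0.7,
                                            ectopic_site = 0.1,
                                            nonconsecutive_flank = 0.1,
                                            prespacer_end_indel = 0.05,
                                            low_quality_trace = 0.05),
                                          n_colonies = 100L,
                                          read_len = 400L,
                                          error_rate = 0,
                                          cassette = NULL,
                                          trim = TRUE,
                                          trim_target = 30L,
                                          trim_noise_sd = 1,
                                          trim_efficiency = default_trim_efficiency,
                                          seed = 1L) {
  stopifnot(inherits(model, "crispr_array_model"),
            inherits(substrate, "prespacer_substrate"))
  if (is.null(substrate$bbsi_interval)) {
    stop("substrate must carry the central BbsI cassette (with_bbsi = TRUE)",
         call. = FALSE)
  }
  probs <- class_probs[COLONY_CLASSES]
  names(probs) <- COLONY_CLASSES
  probs[is.na(probs)] <- 0
  if (abs(sum(probs) - 1) > 1e-6) {
    stop("class_probs must sum to 1 over the five event classes",
         call. = FALSE)
  }
  if (probs[["nonconsecutive_flank"]] > 0 && length(model$spacers) < 2) {
    stop("nonconsecutive_flank events need a model with >= 2 spacers",
         call. = FALSE)
  }
  if (is.null(cassette)) cassette <- make_selection_cassette()
  assert_dna(cassette, "cassette")
  D <- substrate$duplex_length
  if (D < 26) stop("substrate duplex must be >= 26 bp", call. = FALSE)
  Tdup <- substrate_duplex(substrate)
  n_rep <- length(model$spacers) + 1L

  with_seed(seed, {
    classes <- sample(COLONY_CLASSES, n_colonies, replace = TRUE,
                      prob = probs)
    orientations <- sample(c("forward", "reverse"), n_colonies,
                           replace = TRUE)
    eff <- trim_efficiency(max(substrate$overhang_3p_left,
                               substrate$overhang_3p_right))
    truth <- vector("list", n_colonies)
    pairs <- vector("list", n_colonies)
    for (i in seq_len(n_colonies)) {
      cls <- classes[i]
      # spacer length for this event: trimmed (centre-preserving) or full
      if (trim && runif(1) < eff) {
        L <- round(rnorm(1, trim_target, trim_noise_sd))
      } else {
        L <- D
      }
      L <- min(max(L, BBSI_CASSETTE_SPAN + 2L), D)
      fl <- centred_flanks(substrate, L)
      left_flank <- substr0(Tdup, fl["c0"] - fl["l"], fl["c0"])
      right_flank <- substr0(Tdup, fl["c0"] + BBSI_CASSETTE_SPAN,
                             fl["c0"] + BBSI_CASSETTE_SPAN + fl["r"])
      indel_side <- NA_character_
      indel_type <- NA_character_
      if (cls == "prespacer_end_indel") {
        indel_side <- sample(c("left", "right"), 1L)
        indel_type <- sample(c("substitution", "deletion"), 1L)
        if (indel_side == "left") {
          left_flank <- corrupt_flank(left_flank, indel_type, outer = "left")
        } else {
          right_flank <- corrupt_flank(right_flank, indel_type,
                                       outer = "right")
        }
      }
      insert <- paste0(left_flank, cassette, right_flank)
      if (orientations[i] == "reverse") insert <- revcomp(insert)

      rep_index <- NA_integer_
      if (cls == "ectopic_site") {
        offset <- sample(50:min(150, nchar(model$backbone_down) - 1L), 1L)
        plasmid <- paste0(model$backbone_up,
                          array_locus_sequence_until_backbone(model),
                          substr(model$backbone_down, 1L, offset),
                          insert,
                          substr(model$backbone_down, offset + 1L,
                                 nchar(model$backbone_down)))
      } else if (cls == "nonconsecutive_flank") {
        # recombination: integration at the leader edge with loss of the
        # first original spacer + repeat, leaving spacer 2 as the flank
        rep_index <- 1L
        r <- model$repeat_seq
        tail_arr <- paste0(
          paste0(model$spacers[-1], r, collapse = ""), model$backbone_down)
        plasmid <- paste0(model$backbone_up, model$leader, r, insert, r,
                          tail_arr)
      } else {
        # full-site insertion (also the construct behind end-indel and
        # low-quality colonies): duplicated repeat at a repeat edge
        rep_index <- sample.int(n_rep, 1L)
        plasmid <- insert_full_site(model, insert, rep_index)
      }

      reads <- emit_colony_reads(plasmid, cassette, read_len,
                                 low_quality = cls == "low_quality_trace",
                                 error_rate = error_rate)
      pairs[[i]] <- data.frame(colony_id = sprintf("col%04d", i),
                               fwd_read = reads$fwd, fwd_qual = reads$fwd_q,
                               rev_read = reads$rev, rev_qual = reads$rev_q,
                               stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(
        colony_id = sprintf("col%04d", i),
        class = cls,
        orientation = orientations[i],
        site_class = if (cls == "ectopic_site") "ectopic" else "repeat_edge",
        repeat_index = rep_index,
        leader_proximal = !is.na(rep_index) && rep_index == 1L,
        spacer_length = fl[["l"]] + BBSI_CASSETTE_SPAN + fl[["r"]],
        flank_left = fl[["l"]], flank_right = fl[["r"]],
        indel_side = indel_side, indel_type = indel_type,
        stringsAsFactors = FALSE)
    }
    structure(list(pairs = do.call(rbind, pairs),
                   truth = do.call(rbind, truth),
                   cassette = cassette),
              class = "colony_sim")
  })
}

# locus sequence without the downstream backbone (used to place ectopic
# inserts inside the backbone itself)
array_locus_sequence_until_backbone <- function(model) {
  r <- model$repeat_seq
  arr <- r
  if (length(model$spacers)) {
    arr <- paste0(arr, paste0(model$spacers, r, collapse = ""))
  }
  paste0(model$leader, arr)
}

# Full-site insertion at the leader-side edge of repeat `k`: the repeat is
# duplicated, giving ... [context] R insert R S_k ...
insert_full_site <- function(model, insert, k) {
  r <- model$repeat_seq
  n <- length(model$spacers)
  stopifnot(k >= 1, k <= n + 1)
  pre_spacers <- if (k > 1) {
    paste0(paste0(model$spacers[seq_len(k - 1L)], r, collapse = ""))
  } else ""
  post <- if (k <= n) {
    paste0(paste0(model$spacers[k:n], r, collapse = ""), model$backbone_down)
  } else model$backbone_down
  paste0(model$backbone_up, model$leader, r, pre_spacers, insert, r, post)
}

# Plant a detectable end defect in a prespacer flank: a substitution at the
# outermost base, or an internal deletion. Deletions inside a homopolymer
# run touching the outer end are sequence-identical to one extra base of
# trimming, so the deleted position is chosen just past that run (falling
# back to a substitution if the whole flank is one run).
corrupt_flank <- function(flank, type, outer = c("left", "right")) {
  outer <- match.arg(outer)
  n <- nchar(flank)
  if (n < 2) stop("flank too short to corrupt", call. = FALSE)
  bases <- strsplit(flank, "")[[1]]
  if (type == "deletion") {
    pos <- if (outer == "left") {
      which(bases != bases[1])[1]
    } else {
      n + 1L - which(rev(bases) != bases[n])[1]
    }
    if (is.na(pos)) type <- "substitution" else {
      return(paste0(substr(flank, 1L, pos - 1L),
                    substr(flank, pos + 1L, n)))
    }
  }
  pos <- if (outer == "left") 1L else n
  b <- substr(flank, pos, pos)
  substr(flank, pos, pos) <- sample(setdiff(DNA_BASES, b), 1L)
  flank
}

# Emit the outward-facing read pair for one colony plasmid. The cassette is
# located on either strand; reads are defined in the cassette frame so the
# same primer geometry applies regardless of insert orientation:
#   rev read: ends at cassette offset 30, reads leftward (bottom strand)
#   fwd read: starts at cassette offset M-30, reads rightward (top strand)
emit_colony_reads <- function(plasmid, cassette, read_len, low_quality,
                              error_rate) {
  M <- nchar(cassette)
  a <- as.integer(regexpr(cassette, plasmid, fixed = TRUE)) - 1L
  if (a < 0) {
    plasmid <- revcomp(plasmid)
    a <- as.integer(regexpr(cassette, plasmid, fixed = TRUE)) - 1L
  }
  if (a < 0) stop("internal error: cassette not found in colony plasmid")
  Lp <- nchar(plasmid)
  rev_seq <- revcomp(substr0(plasmid, max(0L, a + CASSETTE_ANCHOR - read_len),
                             a + CASSETTE_ANCHOR))
  fwd_start <- a + M - CASSETTE_ANCHOR
  fwd_seq <- substr0(plasmid, fwd_start, min(Lp, fwd_start + read_len))
  if (error_rate > 0) {
    rev_seq <- mutate_sequence(rev_seq, error_rate)
    fwd_seq <- mutate_sequence(fwd_seq, error_rate)
  }
  list(fwd = fwd_seq, fwd_q = sanger_quality(nchar(fwd_seq), low_quality),
       rev = rev_seq, rev_q = sanger_quality(nchar(rev_seq), low_quality))
}

# Phred-like Sanger quality profile: high-quality traces centre near Q38
# with a mild degradation tail; low-quality traces centre near Q12.
sanger_quality <- function(n, low_quality = FALSE) {
  if (n == 0) return("")
  base <- if (low_quality) 12 else 38
  tail_drop <- pmax(0, seq_len(n) - 300) * 0.02
  phred_to_string(rnorm(n, base, 2) - tail_drop)
}

#' @export
print.colony_sim <- function(x, ...) {
  cat(sprintf("<colony_sim> %d colonies: %s\n", nrow(x$truth),
              paste(names(table(x$truth$class)), table(x$truth$class),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
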