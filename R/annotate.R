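EXCLUSION_REASONS <- c("low_quality", "non_repeat_edge",
                       "nonconsecutive_flank", "end_mutation_indel")

#' Build a plasmid feature database
#'
#' Derives from the parent array model and the selection cassette the
#' reference features the annotator matches against: leader/repeat/spacer
#' coordinates on the parent plasmid, the repeat edge octamers used to test
#' "edge of a direct repeat", cassette-internal primer anchors and backbone
#' landmarks used to orient composites.
#'
#' @param model A [crispr_array_model()].
#' @param cassette Selection cassette sequence (see
#'   [make_selection_cassette()]).
#' @return An object of class `plasmid_feature_db`.
#' @export
plasmid_feature_db <- function(model, cassette) {
  stopifnot(inherits(model, "crispr_array_model"))
  assert_dna(cassette, "cassette")
  M <- nchar(cassette)
  if (M < 2 * CASSETTE_ANCHOR + 20) {
    stop("cassette too short for primer anchors", call. = FALSE)
  }
  r <- model$repeat_seq
  # parent plasmid coordinate table (0-based half-open)
  feats <- list()
  pos <- 0L
  add <- function(label, seq) {
    feats[[length(feats) + 1L]] <<- data.frame(
      feature = label, start = pos, end = pos + nchar(seq),
      stringsAsFactors = FALSE)
    pos <<- pos + nchar(seq)
  }
  add("backbone_up", model$backbone_up)
  add("leader", model$leader)
  add("repeat_1", r)
  if (length(model$spacers)) {
    for (j in seq_along(model$spacers)) {
      add(paste0("spacer_", j), model$spacers[j])
      add(paste0("repeat_", j + 1L), r)
    }
  }
  add("backbone_down", model$backbone_down)

  lead_n <- nchar(model$leader)
  structure(list(
    model = model,
    cassette = cassette,
    anchor_left = substr(cassette, 11L, 30L),
    anchor_right = substr(cassette, M - 29L, M - 10L),
    repeat_head8 = substr(r, 1L, 8L),
    repeat_tail8 = substr(r, nchar(r) - 7L, nchar(r)),
    leader_tail = substr(model$leader, max(1L, lead_n - 24L), lead_n),
    landmarks = c(
      leader = substr(model$leader, max(1L, lead_n - 24L), lead_n),
      backbone_up = if (nchar(model$backbone_up) >= 25) {
        substr(model$backbone_up, nchar(model$backbone_up) - 24L,
               nchar(model$backbone_up))
      } else NULL,
      backbone_down = if (nchar(model$backbone_down) >= 25) {
        substr(model$backbone_down, 1L, 25L)
      } else NULL),
    features = do.call(rbind, feats)),
    class = "plasmid_feature_db")
}

find_all <- function(pattern, x) {
  hits <- gregexpr(pattern, x, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

# longest run of equal characters comparing a's suffix with b's suffix
common_suffix_length <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- utf8ToInt(substr(a, nchar(a) - n + 1L, nchar(a)))
  bv <- utf8ToInt(substr(b, nchar(b) - n + 1L, nchar(b)))
  neq <- which(rev(av) != rev(bv))
  if (length(neq) == 0) n else neq[1] - 1L
}

common_prefix_length <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- utf8ToInt(substr(a, 1L, n))
  bv <- utf8ToInt(substr(b, 1L, n))
  neq <- which(av != bv)
  if (length(neq) == 0) n else neq[1] - 1L
}

#' Merge a colony's outward-facing read pair
#'
#' Reverse-complements the leftward (rev) read and concatenates it with the
#' rightward (fwd) read around an explicit gap sentinel, yielding a
#' composite in the cassette frame. Each read is independently anchored to
#' its cassette-internal primer site; failure to anchor marks the colony
#' uninterpretable. Reads whose mean Phred quality falls below
#' `quality_threshold` pre-mark the colony low-quality (annotation is still
#' attempted).
#'
#' @param pair One-row data.frame (or list) with `colony_id`, `fwd_read`,
#'   `fwd_qual`, `rev_read`, `rev_qual`.
#' @param db A [plasmid_feature_db()].
#' @param quality_threshold Mean-Phred floor below which a read is low
#'   quality (default 20).
#' @param sentinel Gap sentinel placed between the two reads.
#' @return List of class `colony_composite`: `colony_id`, `composite`,
#'   `left` (reverse-complemented rev read), `right` (fwd read), flank
#'   windows `w_left`/`w_right` adjacent to the cassette, `low_quality`,
#'   `anchored`, `mean_quality` (per read).
#' @export
merge_colony_reads <- function(pair, db, quality_threshold = 20,
                               sentinel = strrep("N", 10L)) {
  stopifnot(inherits(db, "plasmid_feature_db"))
  fwd <- toupper(pair$fwd_read)
  rev <- toupper(pair$rev_read)
  mq <- c(fwd = mean_quality(pair$fwd_qual), rev = mean_quality(pair$rev_qual))
  low_quality <- any(is.na(mq)) || any(mq < quality_threshold)
  left <- revcomp(rev)
  composite <- paste0(left, sentinel, fwd)

  # left read must end inside the cassette: its primer anchor covers
  # cassette offsets 11..30, so the cassette starts 10 bases before the
  # anchor; bases before that are the flank window
  pa <- find_all(db$anchor_left, left)
  pb <- find_all(db$anchor_right, fwd)
  anchored <- length(pa) > 0 && length(pb) > 0
  w_left <- w_right <- NA_character_
  if (length(pa) > 0) {
    p <- max(pa)
    w_left <- substr(left, 1L, p - 11L)
  }
  if (length(pb) > 0) {
    q <- min(pb)
    w_right <- substring(fwd, q + 30L)
  }
  structure(list(colony_id = pair$colony_id, composite = composite,
                 left = left, right = fwd,
                 w_left = w_left, w_right = w_right,
                 low_quality = low_quality, anchored = anchored,
                 mean_quality = mq),
            class = "colony_composite")
}

#' Annotate one integration event
#'
#' Classifies a merged colony composite against the feature database and the
#' designed prespacer substrate: reconstructs the integrated spacer (left
#' flank + 24-bp cassette-replaced centre + right flank), tests whether the
#' insertion sits at a direct-repeat edge (exact identity of the repeat's
#' terminal 8 nt immediately abutting the spacer), derives orientation and
#' repeat index, checks that the flanking original spacers are consecutive,
#' and compares the prespacer ends base-by-base to the designed substrate.
#' Exclusion reasons are assigned in priority order
#' low_quality > non_repeat_edge > nonconsecutive_flank > end_mutation_indel.
#'
#' @param merged A `colony_composite` from [merge_colony_reads()].
#' @param db A [plasmid_feature_db()].
#' @param substrate The designed `prespacer_substrate` (must carry the
#'   central BbsI cassette).
#' @return One-row data.frame of class `integration_event` columns:
#'   `colony_id`, `site_class`, `repeat_index`, `leader_proximal`,
#'   `orientation`, `spacer_length`, `flanking_spacers_consecutive`,
#'   `prespacer_ends_intact`, `excluded`, `exclusion_reason`.
#' @export
annotate_event <- function(merged, db, substrate) {
  stopifnot(inherits(merged, "colony_composite"),
            inherits(db, "plasmid_feature_db"),
            inherits(substrate, "prespacer_substrate"))
  if (is.null(substrate$bbsi_interval)) {
    stop("substrate must carry the central BbsI cassette", call. = FALSE)
  }
  out <- data.frame(colony_id = merged$colony_id,
                    site_class = NA_character_,
                    repeat_index = NA_integer_,
                    leader_proximal = NA,
                    orientation = NA_character_,
                    spacer_length = NA_integer_,
                    flanking_spacers_consecutive = NA,
                    prespacer_ends_intact = NA,
                    excluded = TRUE,
                    exclusion_reason = NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("integration_event", "data.frame")

  exclude <- function(reason) {
    out$excluded <- TRUE
    out$exclusion_reason <- reason
    out
  }
  if (!merged$anchored) return(exclude("low_quality"))

  # plasmid orientation from model landmarks: found forward means the
  # cassette frame equals the plasmid frame (spacer in forward orientation
  # relative to the prespacer top strand)
  fwd_hit <- any(vapply(db$landmarks, function(l) {
    length(find_all(l, merged$composite)) > 0
  }, logical(1)))
  rev_hit <- any(vapply(db$landmarks, function(l) {
    length(find_all(revcomp(l), merged$composite)) > 0
  }, logical(1)))
  if (fwd_hit == rev_hit) return(exclude("low_quality"))
  orientation <- if (fwd_hit) "forward" else "reverse"
  out$orientation <- orientation

  # flank match lengths in the cassette frame against the substrate duplex
  Tdup <- substrate_duplex(substrate)
  c0 <- substrate$bbsi_interval[1]
  EL <- substr0(Tdup, 0L, c0)
  ER <- substr0(Tdup, c0 + BBSI_CASSETTE_SPAN, substrate$duplex_length)
  l <- common_suffix_length(merged$w_left, EL)
  r <- common_prefix_length(merged$w_right, ER)

  # plasmid-frame windows and flank lengths
  if (orientation == "forward") {
    PL <- merged$w_left; PR <- merged$w_right
    l_p <- l; r_p <- r
  } else {
    PL <- revcomp(merged$w_right); PR <- revcomp(merged$w_left)
    l_p <- r; r_p <- l
  }

  rep_len <- nchar(db$model$repeat_seq)
  e_hits <- find_all(db$repeat_tail8, PL)
  s_hits <- find_all(db$repeat_head8, PR)
  left_edge <- length(e_hits) > 0
  right_edge <- length(s_hits) > 0
  out$site_class <- if (left_edge && right_edge) "repeat_edge" else "ectopic"

  if (out$site_class == "ectopic") {
    out$spacer_length <- l_p + BBSI_CASSETTE_SPAN + r_p
    return(exclude("non_repeat_edge"))
  }

  e <- max(e_hits) + 7L          # 1-based end of the left repeat
  s <- min(s_hits)               # 1-based start of the right repeat
  gap_l <- nchar(PL) - e
  gap_r <- s - 1L
  # ends intact iff the full windows between repeat edges and cassette match
  # the designed substrate base-by-base (orientation-aware)
  EL_p <- if (orientation == "forward") EL else revcomp(ER)
  ER_p <- if (orientation == "forward") ER else revcomp(EL)
  win_l <- substring(PL, e + 1L)
  win_r <- substr(PR, 1L, gap_r)
  out$prespacer_ends_intact <-
    gap_l <= nchar(EL_p) && gap_r <= nchar(ER_p) &&
    common_suffix_length(win_l, EL_p) == gap_l &&
    common_prefix_length(win_r, ER_p) == gap_r
  out$spacer_length <- gap_l + BBSI_CASSETTE_SPAN + gap_r

  # array context beyond the flanking repeats
  ctx_l <- substr(PL, 1L, e - rep_len)
  ctx_r <- substring(PR, s + rep_len)
  left_ctx <- classify_left_context(ctx_l, db)
  right_ctx <- classify_right_context(ctx_r, db)
  n <- length(db$model$spacers)
  expected_right <- if (identical(left_ctx, "leader")) {
    if (n >= 1) 1L else "backbone"
  } else if (is.numeric(left_ctx)) {
    if (left_ctx < n) left_ctx + 1L else "backbone"
  } else NA
  consec <- if (is.null(right_ctx) || identical(expected_right, NA)) {
    NA
  } else identical(right_ctx, expected_right)
  out$flanking_spacers_consecutive <- consec
  out$repeat_index <- if (identical(left_ctx, "leader")) 1L else
    if (is.numeric(left_ctx)) as.integer(left_ctx + 1L) else NA_integer_
  out$leader_proximal <- identical(left_ctx, "leader")

  if (isFALSE(consec)) return(exclude("nonconsecutive_flank"))
  if (!out$prespacer_ends_intact) return(exclude("end_mutation_indel"))
  out$excluded <- FALSE
  out
}

# what lies upstream of the left flanking repeat: "leader", an original
# spacer index, or NULL when undecidable
classify_left_context <- function(ctx, db) {
  if (nchar(ctx) >= 8) {
    k <- min(nchar(ctx), nchar(db$leader_tail))
    if (substr(ctx, nchar(ctx) - k + 1L, nchar(ctx)) ==
        substr(db$leader_tail, nchar(db$leader_tail) - k + 1L,
               nchar(db$leader_tail))) {
      return("leader")
    }
    for (j in seq_along(db$model$spacers)) {
      if (endsWith(ctx, db$model$spacers[j])) return(j)
    }
  }
  NULL
}

# what lies downstream of the right flanking repeat: a spacer index or
# "backbone" (end of array), or NULL when undecidable
classify_right_context <- function(ctx, db) {
  if (nchar(ctx) >= 8) {
    for (j in seq_along(db$model$spacers)) {
      if (startsWith(ctx, db$model$spacers[j])) return(j)
    }
    bb <- db$model$backbone_down
    k <- min(nchar(ctx), nchar(bb), 20L)
    if (k >= 8 && substr(ctx, 1L, k) == substr(bb, 1L, k)) return("backbone")
  }
  NULL
}

#' Annotate all colonies of a simulated or observed screen
#'
#' @param pairs data.frame of read pairs (`colony_id`, `fwd_read`,
#'   `fwd_qual`, `rev_read`, `rev_qual`) or a `colony_sim`.
#' @param db A [plasmid_feature_db()].
#' @param substrate The designed `prespacer_substrate`.
#' @param quality_threshold Mean-Phred floor for [merge_colony_reads()].
#' @return data.frame with one `integration_event` row per colony.
#' @export
annotate_colonies <- function(pairs, db, substrate, quality_threshold = 20) {
  if (inherits(pairs, "colony_sim")) pairs <- pairs$pairs
  stopifnot(is.data.frame(pairs))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    merged <- merge_colony_reads(pairs[i, ], db,
                                 quality_threshold = quality_threshold)
    ev <- annotate_event(merged, db, substrate)
    if (merged$low_quality) {  # priority: low quality first
      ev$excluded <- TRUE
      ev$exclusion_reason <- "low_quality"
    }
    ev
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise annotated integration events
#'
#' @param events data.frame from [annotate_colonies()].
#' @return List: `n_total`, `n_kept`, `length_histogram` (data.frame
#'   `length`, `n` over kept events), `percent_forward`,
#'   `percent_leader_proximal` (over kept events), `exclusions` (named
#'   tally by reason).
#' @export
summarize_events <- function(events) {
  stopifnot(is.data.frame(events), nrow(events) >= 1)
  kept <- events[!events$excluded, , drop = FALSE]
  hist <- if (nrow(kept)) {
    tab <- table(kept$spacer_length)
    data.frame(length = as.integer(names(tab)), n = as.integer(tab))
  } else data.frame(length = integer(0), n = integer(0))
  excl <- table(factor(events$exclusion_reason[events$excluded],
                       levels = EXCLUSION_REASONS))
  list(n_total = nrow(events),
       n_kept = nrow(kept),
       length_histogram = hist,
       percent_forward = if (nrow(kept)) {
         100 * mean(kept$orientation == "forward")
       } else NA_real_,
       percent_leader_proximal = if (nrow(kept)) {
         100 * mean(kept$leader_proximal %in% TRUE)
       } else NA_real_,
       exclusions = setNames(as.integer(excl), names(excl)))
}
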