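BBSI_SITE <- "GAAGAC"  # BbsI recognition; cuts 2 nt (top) / 6 nt (bottom)
                       # downstream leaving 4-nt 5' overhangs
BBSI_CASSETTE_SPAN <- 24L

#' Design a prespacer substrate
#'
#' Builds a DNA duplex with optional single-stranded 3' overhangs on both
#' ends, mimicking the resection intermediates captured for CRISPR
#' integration. With `with_bbsi = TRUE` the central 24 bp of the duplex
#' carry two abutted, inverted BbsI sites whose outward-facing cuts leave
#' 4-nt overhangs inside the central region, so Golden Gate assembly can
#' swap the centre for a selection cassette after full-site integration.
#'
#' Layout of the 24-bp centre on the top strand:
#' `[4-nt overhang][2 nt][GTCTTC][GAAGAC][2 nt][4-nt overhang]`
#' (4 + 2 + 6 + 6 + 2 + 4 = 24); `GTCTTC` is `GAAGAC` read on the bottom
#' strand, so the two recognition sites are inverted and abutted.
#'
#' @param duplex_length Double-stranded core length in bp (>= 24 when
#'   `with_bbsi`).
#' @param overhang_left,overhang_right Lengths (nt) of the 3' single-stranded
#'   extensions: `overhang_right` extends the top strand 3' end,
#'   `overhang_left` extends the bottom strand 3' end.
#' @param with_pam Place a `TGG` at the 3' end of the top-strand duplex so
#'   the substrate carries a PAM; recorded as `has_pam`.
#' @param with_bbsi Encode the central inverted BbsI cassette.
#' @param seed Integer seed for the random sequence fill.
#' @return An object of class `prespacer_substrate` with fields
#'   `top_strand`, `bottom_strand` (both 5'->3'), `duplex_length`,
#'   `overhang_3p_left`, `overhang_3p_right`, `has_pam`,
#'   `bbsi_interval` (0-based half-open on the top strand, or NULL).
#' @examples
#' s <- design_prespacer(30, 6, 6, with_bbsi = TRUE, seed = 2)
#' diff(s$bbsi_interval)  # 24
#' @export
design_prespacer <- function(duplex_length, overhang_left = 0L,
                             overhang_right = 0L, with_pam = FALSE,
                             with_bbsi = FALSE, seed = 1L) {
  if (overhang_left < 0 || overhang_right < 0) {
    stop("overhangs must be >= 0", call. = FALSE)
  }
  if (with_bbsi && duplex_length < BBSI_CASSETTE_SPAN) {
    stop("duplex_length must be >= 24 bp to hold the BbsI cassette",
         call. = FALSE)
  }
  if (duplex_length < 1) stop("duplex_length must be >= 1", call. = FALSE)
  with_seed(seed, {
    duplex <- random_dna(duplex_length)
    bbsi_interval <- NULL
    if (with_bbsi) {
      c0 <- (duplex_length - BBSI_CASSETTE_SPAN) %/% 2L
      centre <- paste0(random_dna(4L), random_dna(2L), revcomp(BBSI_SITE),
                       BBSI_SITE, random_dna(2L), random_dna(4L))
      duplex <- paste0(substr0(duplex, 0L, c0), centre,
                       substr0(duplex, c0 + BBSI_CASSETTE_SPAN, duplex_length))
      bbsi_interval <- c(c0, c0 + BBSI_CASSETTE_SPAN)
    }
    if (with_pam) {
      # NGG at the top-strand 3' duplex edge
      duplex <- paste0(substr0(duplex, 0L, duplex_length - 2L), "GG")
    }
    top <- paste0(duplex, random_dna(overhang_right))
    bottom <- paste0(revcomp(duplex), random_dna(overhang_left))
    structure(list(top_strand = top, bottom_strand = bottom,
                   duplex_length = as.integer(duplex_length),
                   overhang_3p_left = as.integer(overhang_left),
                   overhang_3p_right = as.integer(overhang_right),
                   has_pam = isTRUE(with_pam),
                   bbsi_interval = bbsi_interval),
              class = "prespacer_substrate")
  })
}

#' @export
print.prespacer_substrate <- function(x, ...) {
  cat(sprintf(
    "<prespacer_substrate> %d-bp duplex, 3' overhangs %d/%d nt%s%s\n",
    x$duplex_length, x$overhang_3p_left, x$overhang_3p_right,
    if (!is.null(x$bbsi_interval)) ", central BbsI cassette" else "",
    if (x$has_pam) ", PAM" else ""))
  invisible(x)
}

# Duplex region of the top strand (excludes the right 3' overhang).
substrate_duplex <- function(substrate) {
  substr0(substrate$top_strand, 0L, substrate$duplex_length)
}

#' Default trimming efficiency as a function of 3'-overhang length
#'
#' Probability that the supercomplex fully processes a substrate, given its
#' longest 3' overhang: near-zero for blunt/very short overhangs, rising to
#' complete processing for 6-12 nt, then decaying for longer overhangs
#' (0.2 at 25 nt). Values between the knots are linearly interpolated.
#'
#' @param overhang Integer vector of overhang lengths (nt).
#' @return Numeric vector of processing probabilities in `[0, 1]`.
#' @export
default_trim_efficiency <- function(overhang) {
  knots <- c(0, 2, 3, 6, 12, 25)
  eff <- c(0.05, 0.05, 0.6, 1.0, 1.0, 0.2)
  pmin(pmax(stats::approx(knots, eff, xout = pmin(overhang, 25),
                          rule = 2)$y, 0), 1)
}

#' Simulate exonucleolytic prespacer trimming
#'
#' Stochastic model of 3'-end trimming by the Cas9-integrase supercomplex:
#' each molecule is processed with a probability given by
#' `efficiency_by_overhang` evaluated at the substrate's longest 3' overhang;
#' processed molecules acquire a duplex length drawn from a discretised
#' normal centred at `target_length` (the canonical ~30-bp product),
#' truncated at the input duplex length; unprocessed molecules keep their
#' input duplex length.
#'
#' @param substrate A `prespacer_substrate`.
#' @param target_length Canonical product duplex length in bp (default 30).
#' @param efficiency_by_overhang Function mapping overhang length (nt) to
#'   processing probability; default [default_trim_efficiency()].
#' @param noise_sd Standard deviation (bp) of the product-length spread.
#' @param n_molecules Number of molecules to simulate.
#' @param seed Integer seed.
#' @return An object of class `trim_product_set`: list with `substrate`,
#'   `product_lengths` (integer vector, one per molecule), `processed`
#'   (logical vector) and `fraction_processed`.
#' @examples
#' s <- design_prespacer(45, 8, 8, seed = 3)
#' tp <- simulate_trimming(s, n_molecules = 1000, seed = 4)
#' table(tp$product_lengths)
#' @export
simulate_trimming <- function(substrate, target_length = 30L,
                              efficiency_by_overhang = default_trim_efficiency,
                              noise_sd = 1, n_molecules = 1000L,
                              seed = 1L) {
  stopifnot(inherits(substrate, "prespacer_substrate"))
  if (n_molecules < 1) stop("n_molecules must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  eff <- efficiency_by_overhang(max(substrate$overhang_3p_left,
                                    substrate$overhang_3p_right))
  if (length(eff) != 1L || is.na(eff) || eff < 0 || eff > 1) {
    stop("efficiency_by_overhang must return one probability in [0, 1]",
         call. = FALSE)
  }
  with_seed(seed, {
    processed <- runif(n_molecules) < eff
    lengths <- rep.int(substrate$duplex_length, n_molecules)
    n_proc <- sum(processed)
    if (n_proc > 0) {
      drawn <- round(rnorm(n_proc, mean = target_length, sd = noise_sd))
      drawn <- pmin(pmax(drawn, 1L), substrate$duplex_length)
      lengths[processed] <- drawn
    }
    structure(list(substrate = substrate,
                   product_lengths = as.integer(lengths),
                   processed = processed,
                   fraction_processed = n_proc / n_molecules),
              class = "trim_product_set")
  })
}

#' @export
print.trim_product_set <- function(x, ...) {
  cat(sprintf(
    "<trim_product_set> %d molecules, %.1f%% processed, modal length %d bp\n",
    length(x$product_lengths), 100 * x$fraction_processed,
    modal_length(x$product_lengths)))
  invisible(x)
}

#' Modal value of a length distribution
#'
#' @param lengths Integer vector of product lengths.
#' @return The most frequent length (smallest on ties).
#' @export
modal_length <- function(lengths) {
  tab <- table(lengths)
  as.integer(names(tab)[which.max(tab)])
}

#' Simulate a processing kinetics time course
#'
#' Generates per-replicate fraction-processed measurements on the assay's
#' standard time grid, following linear accumulation `rate * t` (clamped to
#' `[0, 1]`) with Gaussian measurement noise — the regime in which processing
#' rates are estimated by linear regression.
#'
#' @param rate Processing rate in fraction per minute.
#' @param timepoints Sampling times in minutes (default the assay grid
#'   5, 10, 20, 40, 60, 120).
#' @param n_replicates Number of replicates (default 3).
#' @param noise_sd SD of measurement noise on the fraction scale.
#' @param seed Integer seed.
#' @return A data.frame with columns `time`, `replicate`, `fraction`.
#' @export
simulate_kinetics <- function(rate, timepoints = c(5, 10, 20, 40, 60, 120),
                              n_replicates = 3L, noise_sd = 0.02,
                              seed = 1L) {
  if (any(diff(timepoints) <= 0)) {
    stop("timepoints must be strictly increasing", call. = FALSE)
  }
  with_seed(seed, {
    grid <- expand.grid(time = timepoints, replicate = seq_len(n_replicates))
    grid$fraction <- pmin(pmax(
      rate * grid$time + rnorm(nrow(grid), sd = noise_sd), 0), 1)
    grid[order(grid$replicate, grid$time), c("time", "replicate", "fraction")]
  })
}
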