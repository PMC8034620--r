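fixture_screen <- function(n_colonies, class_probs = NULL, seed = 1,
                           n_spacers = 3) {
  m <- random_array_model(n_spacers = n_spacers, seed = 3)
  s <- design_prespacer(45, 8, 8, with_bbsi = TRUE, seed = 5)
  args <- list(model = m, substrate = s, n_colonies = n_colonies, seed = seed)
  if (!is.null(class_probs)) args$class_probs <- class_probs
  sim <- do.call(simulate_integration_colonies, args)
  list(model = m, substrate = s, sim = sim,
       db = plasmid_feature_db(m, sim$cassette))
}

test_that("degenerate class distribution yields only full-site colonies", {
  fx <- fixture_screen(30, class_probs = c(full_site_repeat_edge = 1),
                       seed = 2)
  expect_true(all(fx$sim$truth$class == "full_site_repeat_edge"))
  ev <- annotate_colonies(fx$sim$pairs, fx$db, fx$substrate)
  expect_true(all(!ev$excluded))
})

test_that("a full-site plasmid carries exactly one extra repeat copy", {
  m <- random_array_model(n_spacers = 2, seed = 4)
  s <- design_prespacer(45, 8, 8, with_bbsi = TRUE, seed = 5)
  sim <- simulate_integration_colonies(
    m, s, class_probs = c(full_site_repeat_edge = 1), n_colonies = 10,
    seed = 6)
  parent <- spacerseq:::parent_plasmid_sequence(m)
  n_parent <- length(bf_hamming_starts(m$repeat_seq, parent, 0))
  for (i in 1:10) {
    # reconstruct the colony plasmid from its read pair composite span:
    # count repeats in both reads (they tile the insert neighbourhood)
    comp <- paste0(bf_revcomp(sim$pairs$rev_read[i]), strrep("N", 10),
                   sim$pairs$fwd_read[i])
    n_reads <- length(bf_hamming_starts(m$repeat_seq, comp, 0)) +
      length(bf_hamming_starts(bf_revcomp(m$repeat_seq), comp, 0))
    expect_gte(n_reads, 2)  # the duplicated repeat flanks the insert
  }
  expect_equal(n_parent, length(m$spacers) + 1)
})

test_that("merging anchors both reads and is additive in length", {
  fx <- fixture_screen(5, class_probs = c(full_site_repeat_edge = 1),
                       seed = 7)
  pair <- fx$sim$pairs[1, ]
  mg <- merge_colony_reads(pair, fx$db)
  expect_true(mg$anchored)
  expect_false(mg$low_quality)
  expect_equal(nchar(mg$composite),
               nchar(pair$fwd_read) + nchar(pair$rev_read) + 10)
  # scrambled reverse read loses its anchor
  pair2 <- pair
  pair2$rev_read <- paste(rev(strsplit(pair$rev_read, "")[[1]]),
                          collapse = "")
  mg2 <- merge_colony_reads(pair2, fx$db)
  expect_false(mg2$anchored)
  ev2 <- annotate_event(mg2, fx$db, fx$substrate)
  expect_true(ev2$excluded)
  expect_equal(ev2$exclusion_reason, "low_quality")
})

test_that("each defect class is excluded for its own reason", {
  fx <- fixture_screen(120, seed = 8)
  ev <- annotate_colonies(fx$sim$pairs, fx$db, fx$substrate)
  truth <- fx$sim$truth
  expected <- c(full_site_repeat_edge = "kept",
                ectopic_site = "non_repeat_edge",
                nonconsecutive_flank = "nonconsecutive_flank",
                prespacer_end_indel = "end_mutation_indel",
                low_quality_trace = "low_quality")
  observed <- ifelse(ev$excluded, ev$exclusion_reason, "kept")
  expect_identical(observed, unname(expected[truth$class]))
  # exclusion tally equals the simulator's defect counts
  summ <- summarize_events(ev)
  for (cls in names(expected)[-1]) {
    expect_equal(unname(summ$exclusions[expected[[cls]]]),
                 sum(truth$class == cls))
  }
})

test_that("kept events recover truth length, orientation and site exactly", {
  for (seed in 1:3) {
    fx <- fixture_screen(80, seed = seed)
    ev <- annotate_colonies(fx$sim$pairs, fx$db, fx$substrate)
    kept <- !ev$excluded
    truth <- fx$sim$truth
    expect_identical(ev$spacer_length[kept], truth$spacer_length[kept])
    expect_identical(ev$orientation[kept], truth$orientation[kept])
    expect_identical(ev$repeat_index[kept], truth$repeat_index[kept])
    expect_identical(ev$leader_proximal[kept], truth$leader_proximal[kept])
    expect_true(all(ev$flanking_spacers_consecutive[kept]))
    expect_true(all(ev$prespacer_ends_intact[kept]))
  }
})

test_that("orientation is drawn uniformly (binomial 3-SE bound)", {
  fx <- fixture_screen(600, class_probs = c(full_site_repeat_edge = 1),
                       seed = 9)
  p_fwd <- mean(fx$sim$truth$orientation == "forward")
  expect_lt(abs(p_fwd - 0.5), 3 * sqrt(0.25 / 600))
  ev <- annotate_colonies(fx$sim$pairs, fx$db, fx$substrate)
  summ <- summarize_events(ev)
  expect_lt(abs(summ$percent_forward / 100 - 0.5), 3 * sqrt(0.25 / 600))
})

test_that("class probabilities must sum to one", {
  m <- random_array_model(n_spacers = 3, seed = 3)
  s <- design_prespacer(45, 8, 8, with_bbsi = TRUE, seed = 5)
  expect_error(
    simulate_integration_colonies(m, s, class_probs = c(
      full_site_repeat_edge = 0.5), n_colonies = 5),
    "sum to 1")
})

test_that("single-repeat parents support leader-edge full-site annotation", {
  fx <- fixture_screen(40, class_probs = c(full_site_repeat_edge = 1),
                       seed = 10, n_spacers = 0)
  ev <- annotate_colonies(fx$sim$pairs, fx$db, fx$substrate)
  expect_true(all(!ev$excluded))
  expect_true(all(ev$leader_proximal))
  expect_true(all(ev$repeat_index == 1))
})
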