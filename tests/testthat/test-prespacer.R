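test_that("BbsI cassette spans exactly 24 bp with inverted abutted sites", {
  s <- design_prespacer(30, 0, 0, with_bbsi = TRUE, seed = 2)
  expect_equal(diff(s$bbsi_interval), 24)
  centre <- substr(s$top_strand, s$bbsi_interval[1] + 1, s$bbsi_interval[2])
  # top strand carries GAAGAC on the right half and its reverse complement
  # (= GAAGAC on the bottom strand) abutted on the left half
  expect_identical(substr(centre, 13, 18), "GAAGAC")
  expect_identical(substr(centre, 7, 12), bf_revcomp("GAAGAC"))
  # cut offsets 2 (top) / 6 (bottom) place the two 4-nt overhang positions
  # at the outermost 4 bp of the centre, inside the 24-bp region
  expect_equal(s$bbsi_interval[1] + 4 + 2 + 6, s$bbsi_interval[1] + 12)
  expect_error(design_prespacer(20, with_bbsi = TRUE), "24")
})

test_that("strand lengths are additive in duplex and overhangs", {
  s <- design_prespacer(30, overhang_left = 6, overhang_right = 6, seed = 1)
  expect_equal(nchar(s$top_strand), 36)
  expect_equal(nchar(s$bottom_strand), 36)
  expect_error(design_prespacer(30, overhang_left = -1), "overhang")
})

test_that("the overhang sweep substrates all anneal over the duplex", {
  for (oh in 3:25) {
    s <- design_prespacer(45, oh, oh, with_bbsi = TRUE, seed = oh)
    duplex_top <- substr(s$top_strand, 1, s$duplex_length)
    duplex_bottom <- substr(s$bottom_strand, 1, s$duplex_length)
    expect_identical(duplex_bottom, bf_revcomp(duplex_top))
    expect_equal(nchar(s$top_strand), 45 + oh)
  }
})

test_that("degenerate trimming settings behave deterministically", {
  s <- design_prespacer(45, 8, 8, with_bbsi = TRUE, seed = 5)
  all_on <- simulate_trimming(s, noise_sd = 0, n_molecules = 50,
                              efficiency_by_overhang = function(o) 1,
                              seed = 1)
  expect_true(all(all_on$product_lengths == 30))
  expect_equal(all_on$fraction_processed, 1)
  all_off <- simulate_trimming(s, n_molecules = 50,
                               efficiency_by_overhang = function(o) 0,
                               seed = 1)
  expect_equal(all_off$fraction_processed, 0)
  expect_true(all(all_off$product_lengths == s$duplex_length))
})

test_that("fraction processed matches the configured efficiency within 3 SE", {
  s <- design_prespacer(45, 20, 20, with_bbsi = TRUE, seed = 5)
  eff <- default_trim_efficiency(20)
  tp <- simulate_trimming(s, n_molecules = 10000, seed = 3)
  se <- sqrt(eff * (1 - eff) / 10000)
  expect_lt(abs(tp$fraction_processed - eff), 3 * se)
})

test_that("trimming conserves molecule count and never lengthens products", {
  for (seed in 1:3) {
    s <- design_prespacer(40, 6, 12, with_bbsi = TRUE, seed = seed)
    tp <- simulate_trimming(s, n_molecules = 500, seed = seed)
    expect_length(tp$product_lengths, 500)
    expect_true(all(tp$product_lengths <= nchar(s$top_strand)))
    expect_true(all(tp$product_lengths[!tp$processed] == s$duplex_length))
  }
})

test_that("default efficiency is complete for 6-12 nt overhangs and decays", {
  expect_equal(default_trim_efficiency(6), 1)
  expect_equal(default_trim_efficiency(12), 1)
  expect_equal(default_trim_efficiency(3), 0.6)
  expect_equal(default_trim_efficiency(25), 0.2)
  sweep <- default_trim_efficiency(12:25)
  expect_true(all(diff(sweep) <= 0))
})

test_that("simulated kinetics recover their configured linear rate", {
  k <- simulate_kinetics(0.005, noise_sd = 0, seed = 1)
  expect_identical(sort(unique(k$time)), c(5, 10, 20, 40, 60, 120))
  fit <- fit_processing_rate(k)
  expect_equal(fit$slope, 0.005, tolerance = 1e-10)
})
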