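test_that("distinct-tag counting collapses PCR duplicates", {
  calls <- data.frame(sample_id = "S1", spacer = "ACGTACGTACGTACG",
                      length = 15L,
                      umi = rep("AAAAA", 5), stringsAsFactors = FALSE)
  tab <- normalize_counts(calls)
  expect_equal(tab$raw_reads, 5)
  expect_equal(tab$distinct_umis, 1)
  calls$umi <- c("AAAAA", "CCCCC", "GGGGG", "TTTTT", "ACGTA")
  tab <- normalize_counts(calls)
  expect_equal(tab$raw_reads, 5)
  expect_equal(tab$distinct_umis, 5)
})

test_that("normalisation is invariant to uniform PCR duplication", {
  g <- make_phage_genome(20000, gc = 0.4, seed = 1)
  m <- random_array_model(n_spacers = 0, seed = 2)
  bcs <- fixture_barcodes()
  res <- lapply(c(1, 4), function(k) {
    sim <- simulate_acquisition_reads(m, g, bcs, 150, pcr_bias = k, seed = 11)
    dmx <- demultiplex(sim$reads, bcs)
    normalize_counts(call_spacers(dmx$assigned, m)$calls)
  })
  # same events (seed shared up to the duplication draw order); distinct-tag
  # counts identical while raw reads scale by the duplication factor
  expect_identical(res[[1]][, c("sample_id", "spacer", "distinct_umis")],
                   res[[2]][, c("sample_id", "spacer", "distinct_umis")])
  expect_identical(res[[2]]$raw_reads, 4L * res[[1]]$raw_reads)
})

test_that("distinct tags equal truth event counts up to enumerable collisions", {
  g <- make_phage_genome(20000, gc = 0.4, seed = 1)
  m <- random_array_model(n_spacers = 0, seed = 2)
  bcs <- fixture_barcodes()
  sim <- simulate_acquisition_reads(m, g, bcs, 400, seed = 12)
  dmx <- demultiplex(sim$reads, bcs)
  tab <- normalize_counts(call_spacers(dmx$assigned, m)$calls)
  truth_umis <- aggregate(umi ~ sample_id + spacer, data = sim$truth,
                          FUN = function(u) length(unique(u)))
  mrg <- merge(tab, truth_umis, by = c("sample_id", "spacer"))
  expect_equal(nrow(mrg), nrow(tab))
  expect_identical(mrg$distinct_umis, as.integer(mrg$umi))
  # total shortfall vs events is exactly the simulator's collision count
  expect_equal(sum(sim$truth$n_reads >= 1) - sum(tab$distinct_umis),
               sim$tag_collisions)
})

test_that("length distributions are percentages over unique sequences", {
  tab <- data.frame(sample_id = "S1",
                    spacer = replicate(10, paste(sample(c("A", "C", "G", "T"),
                                                        30, replace = TRUE),
                                                 collapse = "")),
                    length = 30L, distinct_umis = c(100L, rep(1L, 9)),
                    stringsAsFactors = FALSE)
  d <- length_distribution(tab)
  expect_equal(d$percent, 100)
  tab$length <- rep(c(30L, 31L), each = 5)
  d <- length_distribution(tab)
  expect_equal(d$percent, c(50, 50))
  expect_equal(unique(d$n_unique), 10)
  expect_equal(sum(d$percent), 100, tolerance = 1e-6)
  empty <- length_distribution(normalize_counts(
    data.frame(sample_id = character(0), spacer = character(0),
               length = integer(0), umi = character(0))))
  expect_equal(nrow(empty), 0)
})

test_that("configured length weights are recovered within 3 binomial SEs", {
  g <- make_phage_genome(50000, gc = 0.4, seed = 21)
  m <- random_array_model(n_spacers = 0, seed = 22)
  bcs <- fixture_barcodes()
  w <- c("30" = 0.6, "31" = 0.3, "32" = 0.1)
  sim <- simulate_acquisition_reads(m, g, bcs, 2000, length_weights = w,
                                    pcr_bias = 1, seed = 23)
  dmx <- demultiplex(sim$reads, bcs)
  tab <- normalize_counts(call_spacers(dmx$assigned, m)$calls)
  # pool samples: unique spacers per length across the run
  pooled <- length_distribution(within(tab, sample_id <- "all"))
  for (len in names(w)) {
    p <- w[[len]]
    se <- sqrt(p * (1 - p) / 2000)
    obs <- pooled$percent[pooled$length == as.integer(len)] / 100
    expect_lt(abs(obs - p), 3 * se + 0.01)
  }
})

test_that("mapping summaries aggregate deterministically", {
  empty <- summarize_mapping(data.frame())
  expect_equal(empty$n_spacers, 0)
  expect_equal(empty$percent_pam_valid, 0)
  mp <- data.frame(hit_count = c(1L, 1L, 2L, 0L),
                   strand = c("+", "-", NA, NA),
                   pam_valid = c(TRUE, TRUE, NA, NA))
  s <- summarize_mapping(mp)
  expect_equal(s$percent_unique, 50)
  expect_equal(s$percent_pam_valid, 100)
  expect_equal(s$percent_plus_strand, 50)
})

test_that("kinetics slopes equal the closed-form normal-equations solution", {
  # exact line through the assay time grid
  k0 <- data.frame(time = c(5, 10, 20, 40, 60, 120),
                   fraction = 0.01 * c(5, 10, 20, 40, 60, 120) * 0.5)
  f0 <- fit_processing_rate(k0)
  expect_equal(f0$slope, 0.005, tolerance = 1e-12)
  expect_equal(f0$intercept, 0, tolerance = 1e-12)
  # flat series
  kf <- data.frame(time = c(5, 10, 20), fraction = rep(0.4, 3))
  expect_equal(fit_processing_rate(kf)$slope, 0)
  # noisy replicates vs the oracle, per replicate
  k <- simulate_kinetics(0.006, noise_sd = 0.03, seed = 31)
  fit <- fit_processing_rate(k)
  for (rep_i in unique(k$replicate)) {
    d <- k[k$replicate == rep_i, ]
    oracle <- bf_ols(d$time, d$fraction)
    expect_equal(fit$fits$slope[fit$fits$replicate == rep_i],
                 unname(oracle["slope"]), tolerance = 1e-10)
  }
  expect_equal(fit$slope, mean(fit$fits$slope))
  expect_error(fit_processing_rate(data.frame(time = 5, fraction = 0.1)),
               "2 timepoints")
})

test_that("expected tag-collision counts follow the birthday bound", {
  expect_equal(expected_umi_collisions(1), 0)
  # for n << 4^5 the bound is close to n(n-1)/2 / 4^5
  n <- 100
  expect_equal(expected_umi_collisions(n), n^2 / 2 / 4^5, tolerance = 0.05)
})
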