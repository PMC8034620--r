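test_that("demultiplexing assigns by exact barcode after the 5-nt tag", {
  bcs <- barcode_spec(c("S1", "S2"), c("ACG", "TCAG"))
  reads <- data.frame(
    read_id = c("r1", "r2", "r3"),
    sequence = c(paste0("GGGTT", "ACG", strrep("A", 60)),
                 paste0("CCCAA", "TCAG", strrep("A", 60)),
                 paste0("AAAAA", "TTT", strrep("A", 60))),
    quality = strrep("I", 68), stringsAsFactors = FALSE)
  dmx <- demultiplex(reads, bcs)
  expect_equal(dmx$assigned$sample_id, c("S1", "S2"))
  expect_equal(dmx$assigned$umi, c("GGGTT", "CCCAA"))
  expect_equal(dmx$assigned$payload[1], strrep("A", 60))
  expect_equal(dmx$rejected$read_id, "r3")
  expect_equal(dmx$rejected$reason, "unknown_barcode")
})

test_that("short reads are rejected with reason too_short", {
  bcs <- barcode_spec("S1", "ACG")
  reads <- data.frame(read_id = "r1", sequence = "GGGTTACGAA",
                      quality = "IIIIIIIIII", stringsAsFactors = FALSE)
  dmx <- demultiplex(reads, bcs, min_payload = 50)
  expect_equal(dmx$rejected$reason, "too_short")
})

test_that("non-prefix-free barcode tables are refused at load time", {
  expect_error(barcode_spec(c("A", "B"), c("ACG", "ACGT")), "prefix-free")
  expect_error(barcode_spec(c("A", "B"), c("ACG", "ACG")), "prefix")
})

test_that("a constructed expanded read yields the planted spacer call", {
  m <- random_array_model(n_spacers = 0, seed = 1)
  new_spacer <- strrep("ACGTA", 6)  # 30 bp
  payload <- paste0(m$leader, m$repeat_seq, new_spacer, m$repeat_seq,
                    substr(m$backbone_down, 1, 50))
  call <- call_expanded_array(payload, m)
  expect_equal(call$status, "call")
  expect_identical(call$spacer, new_spacer)
  expect_equal(call$length, 30)
  expect_false(call$multi_acquisition)
})

test_that("unexpanded and repeat-free payloads are not called", {
  m <- random_array_model(n_spacers = 0, seed = 1)
  unexpanded <- paste0(m$leader, m$repeat_seq, substr(m$backbone_down, 1, 50))
  expect_equal(call_expanded_array(unexpanded, m)$status, "no_expansion")
  expect_equal(call_expanded_array(strrep("ACGT", 40), m)$status, "malformed")
  # parent array with an original spacer: seeing spacer 1 is no expansion
  m1 <- random_array_model(n_spacers = 1, seed = 2)
  parent <- paste0(m1$leader, m1$repeat_seq, m1$spacers[1], m1$repeat_seq,
                   substr(m1$backbone_down, 1, 50))
  expect_equal(call_expanded_array(parent, m1)$status, "no_expansion")
})

test_that("repeat scanning agrees with a brute-force Hamming scan", {
  m <- random_array_model(n_spacers = 0, seed = 3)
  payload <- paste0(m$leader, m$repeat_seq, strrep("ACGTG", 6), m$repeat_seq,
                    substr(m$backbone_down, 1, 40))
  # plant one mismatched copy
  mutated <- m$repeat_seq
  substr(mutated, 5, 5) <- if (substr(mutated, 5, 5) == "A") "C" else "A"
  payload2 <- paste0(payload, "TTTT", mutated)
  for (mm in 0:2) {
    found <- spacerseq:::find_repeats(payload2, m$repeat_seq, mm)
    oracle <- bf_hamming_starts(m$repeat_seq, payload2, mm)
    # greedy non-overlap resolution on the oracle side
    keep <- integer(0); last_end <- -1
    for (s in oracle) {
      if (s >= last_end) { keep <- c(keep, s); last_end <- s + nchar(m$repeat_seq) }
    }
    expect_identical(found$start, as.integer(keep))
  }
})

test_that("calls never contain a full repeat copy", {
  g <- make_phage_genome(20000, gc = 0.4, seed = 1)
  m <- random_array_model(n_spacers = 0, seed = 2)
  sim <- simulate_acquisition_reads(m, g, fixture_barcodes(), 100,
                                    pcr_bias = 1, seed = 9)
  dmx <- demultiplex(sim$reads, fixture_barcodes())
  calls <- call_spacers(dmx$assigned, m)$calls
  expect_gt(nrow(calls), 0)
  expect_false(any(grepl(m$repeat_seq, calls$spacer, fixed = TRUE)))
})

test_that("caller round-trips simulator output exactly when error-free", {
  g <- make_phage_genome(20000, gc = 0.4, seed = 1)
  m <- random_array_model(n_spacers = 0, seed = 2)
  bcs <- fixture_barcodes()
  sim <- simulate_acquisition_reads(m, g, bcs, 200, error_rate = 0, seed = 10)
  dmx <- demultiplex(sim$reads, bcs, min_payload = nchar(m$repeat_seq) + 20)
  expect_equal(nrow(dmx$rejected), 0)
  # demux assignment agrees with truth for every read
  truth_sample <- sim$truth$sample_id[
    match(sub("_c\\d+$", "", dmx$assigned$read_id), sim$truth$event_id)]
  expect_identical(dmx$assigned$sample_id, truth_sample)
  res <- call_spacers(dmx$assigned, m, max_repeat_mismatches = 0)
  # precision and recall of (sample, spacer) pairs are both 1
  truth_set <- unique(paste(sim$truth$sample_id, sim$truth$spacer))
  call_set <- unique(paste(res$calls$sample_id, res$calls$spacer))
  expect_setequal(call_set, truth_set)
  expect_equal(nrow(res$calls), nrow(dmx$assigned))
})
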