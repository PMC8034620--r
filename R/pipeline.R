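#' Default configuration for the acquisition pipeline
#'
#' Returns the full parameter block consumed by
#' [run_acquisition_pipeline()]; user-supplied configs override these
#' defaults field by field.
#'
#' @return A nested list of parameter blocks.
#' @export
acquisition_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    genome = list(length = 50000L, gc = 0.35),
    model = list(n_spacers = 0L, repeat_length = 36L, spacer_length = 30L,
                 leader_length = 80L, flank_length = 300L),
    barcodes = list(sample_id = c("S1", "S2", "S3"),
                    barcode = c("ACG", "TCAG", "GATCA")),
    acquisition = list(n_events = 500L,
                       length_weights = c("30" = 0.7, "31" = 0.2, "32" = 0.1),
                       pcr_bias = NULL, error_rate = 0),
    caller = list(max_repeat_mismatches = 2L, min_spacer_length = 10L)
  )
}

#' Default configuration for the integration pipeline
#'
#' @return A nested list of parameter blocks for
#'   [run_integration_pipeline()].
#' @export
integration_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    model = list(n_spacers = 3L, repeat_length = 36L, spacer_length = 30L,
                 leader_length = 80L, flank_length = 300L),
    substrate = list(duplex_length = 45L, overhang_left = 8L,
                     overhang_right = 8L, with_pam = FALSE, with_bbsi = TRUE),
    colonies = list(n_colonies = 100L,
                    class_probs = c(full_site_repeat_edge = 0.7,
                                    ectopic_site = 0.1,
                                    nonconsecutive_flank = 0.1,
                                    prespacer_end_indel = 0.05,
                                    low_quality_trace = 0.05),
                    read_len = 400L, error_rate = 0, trim = TRUE,
                    trim_target = 30L, trim_noise_sd = 1),
    annotate = list(quality_threshold = 20)
  )
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Config file; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return A configuration list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json", call. = FALSE)
  }
}

merge_config <- function(defaults, config) {
  if (is.null(config)) return(defaults)
  modifyList(defaults, config)
}

require_config <- function(config, keys) {
  for (k in keys) {
    v <- config
    for (part in strsplit(k, ".", fixed = TRUE)[[1]]) {
      v <- v[[part]]
      if (is.null(v)) stop("missing configuration key: ", k, call. = FALSE)
    }
  }
  invisible(TRUE)
}

write_manifest <- function(config, stages, out_dir) {
  # out_dir is dropped so the manifest depends only on the run parameters
  config$out_dir <- NULL
  write_json(list(package = "spacerseq",
                  version = as.character(utils::packageVersion("spacerseq")),
                  config = config, stages = stages),
             file.path(out_dir, "manifest.json"))
}

#' Run the acquisition pipeline end to end
#'
#' simulate reads -> demultiplex -> call expanded arrays -> map to the phage
#' genome -> normalise by distinct tags -> length distribution and mapping
#' summary. All randomness derives from `config$seed`; a fixed config
#' reproduces byte-identical outputs.
#'
#' @param config Configuration list (see [acquisition_config()] for the
#'   defaults it is merged over). `out_dir` is required.
#' @return Invisibly, a report list: `truth`, `calls`, `mapping`,
#'   `per_spacer`, `length_distribution`, `summary`.
#' @export
run_acquisition_pipeline <- function(config = list()) {
  config <- merge_config(acquisition_config(), config)
  require_config(config, c("out_dir", "seed", "genome.length",
                           "acquisition.n_events"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 2L)
  stages <- list()

  genome <- make_phage_genome(config$genome$length, config$genome$gc,
                              seed = seeds[1])
  model <- do.call(random_array_model,
                   c(config$model, list(seed = seeds[1])))
  bcs <- if (is.character(config$barcodes)) {
    read_barcodes_tsv(config$barcodes)
  } else {
    barcode_spec(config$barcodes$sample_id, config$barcodes$barcode)
  }
  lw <- config$acquisition$length_weights
  if (is.list(lw)) lw <- unlist(lw)
  sim <- simulate_acquisition_reads(
    model, genome, bcs,
    n_events = config$acquisition$n_events,
    length_weights = lw,
    pcr_bias = config$acquisition$pcr_bias,
    error_rate = config$acquisition$error_rate,
    seed = seeds[2])
  write_genome_fasta(genome, file.path(config$out_dir, "genome.fasta"))
  write_fastq(sim$reads, file.path(config$out_dir, "reads.fastq"))
  write_tsv(sim$truth, file.path(config$out_dir, "truth.tsv"))
  stages$simulate <- list(n_events = nrow(sim$truth),
                          n_reads = nrow(sim$reads),
                          tag_collisions = sim$tag_collisions)

  dmx <- demultiplex(sim$reads, bcs,
                     min_payload = nchar(model$repeat_seq) + 20L)
  stages$demultiplex <- list(n_assigned = nrow(dmx$assigned),
                             n_rejected = nrow(dmx$rejected))

  called <- call_spacers(dmx$assigned, model,
                         max_repeat_mismatches = config$caller$max_repeat_mismatches,
                         min_spacer_length = config$caller$min_spacer_length)
  write_tsv(called$calls, file.path(config$out_dir, "spacer_calls.tsv"))
  write_tsv(rbind(dmx$rejected, called$rejected),
            file.path(config$out_dir, "rejected_reads.tsv"))
  stages$call <- list(n_calls = nrow(called$calls),
                      n_no_expansion = called$n_no_expansion,
                      n_rejected = nrow(called$rejected))

  per_spacer <- normalize_counts(called$calls)
  mapping <- if (nrow(per_spacer)) {
    map_spacers(per_spacer, genome)
  } else {
    cbind(per_spacer, hit_count = integer(0), ambiguous = logical(0),
          start = integer(0), end = integer(0), strand = character(0),
          pam = character(0), pam_valid = logical(0))
  }
  write_tsv(mapping, file.path(config$out_dir, "mapping.tsv"))
  dist <- length_distribution(per_spacer)
  write_tsv(dist, file.path(config$out_dir, "length_distribution.tsv"))
  map_sum <- summarize_mapping(mapping)
  stages$map <- map_sum

  summary <- list(n_events = nrow(sim$truth),
                  n_reads = nrow(sim$reads),
                  n_calls = nrow(called$calls),
                  n_unique_spacers = nrow(per_spacer),
                  tag_collisions = sim$tag_collisions,
                  mapping = map_sum,
                  length_distribution = split(
                    setNames(dist$percent, dist$length), dist$sample_id))
  write_json(summary, file.path(config$out_dir, "summary.json"))
  write_manifest(config, stages, config$out_dir)
  invisible(list(genome = genome, model = model, truth = sim$truth,
                 calls = called$calls, per_spacer = per_spacer,
                 mapping = mapping, length_distribution = dist,
                 summary = summary))
}

#' Run the integration-screen pipeline end to end
#'
#' design substrate -> simulate colonies -> merge and annotate read pairs ->
#' cohort summary. Deterministic for a fixed config.
#'
#' @param config Configuration list merged over [integration_config()].
#'   `out_dir` is required.
#' @return Invisibly, a report list: `substrate`, `truth`, `events`,
#'   `summary`.
#' @export
run_integration_pipeline <- function(config = list()) {
  config <- merge_config(integration_config(), config)
  require_config(config, c("out_dir", "seed", "substrate.duplex_length",
                           "colonies.n_colonies"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 3L)
  stages <- list()

  model <- do.call(random_array_model,
                   c(config$model, list(seed = seeds[1])))
  substrate <- design_prespacer(
    config$substrate$duplex_length,
    overhang_left = config$substrate$overhang_left,
    overhang_right = config$substrate$overhang_right,
    with_pam = isTRUE(config$substrate$with_pam),
    with_bbsi = isTRUE(config$substrate$with_bbsi),
    seed = seeds[2])
  cp <- config$colonies$class_probs
  if (is.list(cp)) cp <- unlist(cp)
  sim <- simulate_integration_colonies(
    model, substrate,
    class_probs = cp,
    n_colonies = config$colonies$n_colonies,
    read_len = config$colonies$read_len,
    error_rate = config$colonies$error_rate,
    trim = isTRUE(config$colonies$trim),
    trim_target = config$colonies$trim_target,
    trim_noise_sd = config$colonies$trim_noise_sd,
    seed = seeds[3])
  write_tsv(sim$truth, file.path(config$out_dir, "colony_truth.tsv"))
  write_tsv(sim$pairs, file.path(config$out_dir, "colony_reads.tsv"))
  stages$simulate <- list(n_colonies = nrow(sim$truth))

  db <- plasmid_feature_db(model, sim$cassette)
  events <- annotate_colonies(sim$pairs, db, substrate,
                              quality_threshold = config$annotate$quality_threshold)
  write_tsv(events, file.path(config$out_dir, "integration_events.tsv"))
  summ <- summarize_events(events)
  stages$annotate <- list(n_kept = summ$n_kept,
                          exclusions = as.list(summ$exclusions))
  write_json(list(n_total = summ$n_total, n_kept = summ$n_kept,
                  percent_forward = summ$percent_forward,
                  percent_leader_proximal = summ$percent_leader_proximal,
                  exclusions = as.list(summ$exclusions),
                  length_histogram = summ$length_histogram),
             file.path(config$out_dir, "summary.json"))
  write_manifest(config, stages, config$out_dir)
  invisible(list(model = model, substrate = substrate, truth = sim$truth,
                 events = events, summary = summ))
}
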