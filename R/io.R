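#' Write reads to FASTQ
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sequence", "quality") %in% names(reads)))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id)),
    Biostrings::PhredQuality(reads$quality))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file into a reads data.frame
#'
#' @param path FASTQ path.
#' @return data.frame with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping (empty) metadata columns on FASTQ input
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(read_id = names(x),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a genome (or any named sequence) to FASTA
#'
#' @param genome A `genome` object.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(genome$sequence, genome$id)), path)
  invisible(path)
}

#' Read the first record of a FASTA file as a genome
#'
#' @param path FASTA path.
#' @return A `genome` object.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  as_genome(as.character(x[[1]]), id = names(x)[1])
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a barcode table from TSV
#'
#' @param path TSV with columns `sample_id`, `barcode`.
#' @return A [barcode_spec()].
#' @export
read_barcodes_tsv <- function(path) {
  tab <- read_tsv(path)
  barcode_spec(tab$sample_id, tab$barcode)
}

#' Read a kinetics table from TSV
#'
#' @param path TSV with columns `time`, `fraction` and optionally
#'   `replicate`.
#' @return data.frame suitable for [fit_processing_rate()].
#' @export
read_kinetics_tsv <- function(path) {
  read_tsv(path)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
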