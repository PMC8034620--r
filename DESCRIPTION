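Package: spacerseq
Title: Simulation and Analysis of Type II-A CRISPR Spacer Acquisition Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse sequencing assays that measure new
    spacer acquisition by the Streptococcus pyogenes type II-A CRISPR-Cas
    system. Includes a synthetic-data generator (phage genome, barcoded
    UMI-tagged amplicon reads of expanded repeat-spacer arrays with PCR
    duplication bias, prespacer substrates with 3'-overhangs and a central
    inverted BbsI cassette, a stochastic prespacer-trimming simulator, and
    colony Sanger read pairs of plasmid integration products), an amplicon
    spacer caller with sample demultiplexing and UMI-based PCR-bias
    normalisation, perfect-match protospacer mapping with NGG PAM
    classification, spacer-length distribution and processing-kinetics
    summaries, and an annotator that classifies full-site integration events
    from paired outward-facing Sanger reads with explicit exclusion rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
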