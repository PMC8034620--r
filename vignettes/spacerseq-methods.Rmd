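---
title: "Models and methods behind spacerseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spacerseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacerseq)
```

# The biology being measured

In the *Streptococcus pyogenes* type II-A CRISPR-Cas system, new immunity is
acquired when a fragment of invader DNA (a prespacer) is trimmed to the
canonical ~30-bp spacer length and integrated by the Cas1-Cas2 integrase at
the leader-proximal edge of the CRISPR array, duplicating one direct repeat.
Two assay families quantify this process:

1. **Acquisition deep sequencing.** After phage challenge, the CRISPR locus
   is PCR-amplified with a primer carrying a 5-nt random tag (a minimal UMI)
   and a 3–5 bp sample barcode at its 5' end. Reads showing an expanded
   array (two repeat copies around a new insert) yield spacer sequences,
   which are mapped by *perfect* matching to the phage genome on both
   strands, and summarised as the percentage of *unique* spacer sequences
   per length.
2. **Full-site integration screen.** Synthetic prespacer duplexes carry two
   abutted, inverted BbsI sites occupying their central 24 bp. After an in
   vitro integration reaction, Golden Gate assembly swaps that centre for a
   selection cassette, so only full-site integration products give doubly
   resistant colonies. Each colony is Sanger-sequenced with two
   cassette-internal, outward-facing primers, and the read pair is annotated
   against the known plasmid features to recover integration site,
   orientation and spacer length, with explicit exclusion rules.

spacerseq implements both analysis paths and, because the assays' raw data
are external, a first-class synthetic-data generator for every input, with
machine-readable ground truth that the analysis code never reads.

# Synthetic-data models

## Phage genome and protospacer sampling

`make_phage_genome()` draws i.i.d. bases at a chosen GC content (default
0.35, typical of staphylococcal phage). `sample_protospacer()` enumerates
*all* placements of the requested length whose 3-nt 3' flank on the match
strand fits NGG and samples uniformly among them, so truth PAMs are valid by
construction. Protospacers are drawn i.i.d.; no phage population genetics is
modelled.

## Amplicon reads

Each read is `[5-nt tag][barcode][20-nt constant anchor][leader + R +
new spacer + R + downstream locus]`. The real amplicon primer cocktail is
assay-specific, so a configurable constant anchor stands in for it; it gives
demultiplexing a deterministic register and plays no further role. PCR bias
is modelled as duplicate reads sharing one tag, with per-event duplication
factors drawn from a geometric distribution with mean 3 by default (a
long-tailed family consistent with amplification jackpots); any
`function(n)` can be substituted. Substitution errors are applied per read
copy. Default length weights concentrate on 30–31 bp, the lengths dominating
in vivo acquisition.

## Prespacer substrates and the BbsI centre

`design_prespacer()` builds a duplex with 3' single-stranded extensions on
both ends. The 24-bp centre is laid out on the top strand as
`[4][2][GTCTTC][GAAGAC][2][4]`: two abutted recognition sites in inverted
orientation, each cutting outward with the standard Type IIS offsets (2 nt
top / 6 nt bottom), which places both 4-nt overhang positions inside the
central region and reproduces the printed 24-bp span analytically
(2 × (6 + 2 + 4) = 24). `with_pam` writes an NGG at the top strand's 3'
duplex edge and records the flag.

## Trimming model

`simulate_trimming()` treats processing as all-or-none per molecule: a
molecule is processed with probability `efficiency_by_overhang(max
overhang)`, and processed molecules take a duplex length drawn from a
discretised normal centred at the 30-bp canonical product
(`noise_sd = 1` bp), truncated at the input duplex length; unprocessed
molecules keep their input length. The default efficiency map is complete
(1.0) for 6–12-nt overhangs, 0.6 at 3 nt, decaying linearly to 0.2 at 25 nt,
and near zero (0.05) for blunt/very short ends — the knots reflect the
qualitative substrate-preference trend; the interpolation between them is a
modelling choice, not a measured curve. Trimming is exonucleolytic from the
3' ends only; products never exceed the input.

## Colony simulation

`simulate_integration_colonies()` draws an event class per colony:
full-site at a repeat edge (repeat duplicated, cassette replacing the
spacer's central 24 bp), ectopic insertion (no repeat duplication, placed in
the backbone), recombination leaving nonconsecutive flanking spacers
(modelled as loss of spacer 1 + repeat during leader-edge integration),
prespacer end defects (substitution at the outermost flank base or an
internal deletion), and low-quality traces (full-site construct, read
qualities centred near Q12). Orientation is uniform — the simulator default
is "no preferential orientation". The repeat edge used by full-site events
is uniform over the array's leader-side edges; physiological leader
preference can be emulated by reducing the model to a single repeat.

One identifiability limit is built in deliberately: a deletion at the very
end of a trimmed prespacer is sequence-identical to one extra base of
trimming and cannot be detected by any annotator; the simulator therefore
plants end defects just past any terminal homopolymer run, which keeps the
defect observable while remaining biologically plausible (synthesis errors
occur anywhere in the oligo).

# Analysis methods and numerical choices

* **Demultiplexing** is exact (no 1-mismatch rescue); the prefix-free
  barcode check runs at load time. Reads shorter than tag + barcode +
  repeat + 20 nt are rejected as `too_short`.
* **Expansion calling** locates repeat copies with up to
  `max_repeat_mismatches` substitutions (default 2, accommodating
  sequencing errors; set 0 for error-free simulations). Overlapping repeat
  hits are resolved greedily left-to-right. The new spacer is the segment
  between the first two repeats; when the parent array has spacers, a
  candidate equal to original spacer 1 is an unexpanded read. Calls never
  contain a full repeat copy, and only the leader-proximal acquisition is
  called (multi-acquisition reads are flagged). Coordinates are 0-based,
  half-open throughout.
* **Mapping** is perfect-match only — by design, not limitation: spacers
  with errors simply fail to map, and the mapped fraction decreases with
  error rate. Multi-hit spacers stay in length statistics but are excluded
  from PAM/orientation summaries. A `circular` flag enables wrap-around
  matching. PAM is the 3 nt immediately 3' of the protospacer on the match
  strand (canonical SpyCas9 convention).
* **PCR-bias normalisation** is distinct-tag counting per unique
  (sample, spacer): with 5 random nucleotides as a degenerate tag this is
  the standard UMI collapse. Tag collisions are not rescued; their expected
  count is available from the birthday bound
  (`expected_umi_collisions()`) so they can be accounted for exactly in
  truth comparisons.
* **Length distributions** count each unique spacer sequence once (the
  assay's explicit choice); abundance weighting exists but is off by
  default. Percentages always sum to 100 within 1e-6.
* **Kinetics** are fit by ordinary least squares of fraction processed
  vs time per replicate (default grid 5, 10, 20, 40, 60, 120 min, three
  replicates), reporting mean ± SD of slopes.
* **Colony annotation** anchors each read to its cassette-internal primer
  site, reverse-complements the leftward read and joins the pair around an
  `N` sentinel; plasmid orientation comes from leader/backbone landmarks, so
  spacer orientation relative to the prespacer top strand is the cassette's
  orientation in the plasmid. "Edge of a direct repeat" is operationalised
  as exact identity of the repeat's terminal 8 nt immediately abutting the
  reconstructed spacer. Spacer length is left flank + 24 + right flank,
  assuming the cassette precisely replaced the central BbsI region;
  deviations between the repeat edge and the matched substrate flank are
  end mutations/indels. Exclusion reasons are assigned with the fixed
  priority `low_quality > non_repeat_edge > nonconsecutive_flank >
  end_mutation_indel` (the source assay lists the rules without precedence;
  a deterministic order keeps reasons mutually exclusive). "Low quality"
  is mean Phred < 20 on either read — no numeric threshold is stated for
  the original traces, and 20 cleanly separates the simulator's two quality
  regimes.

# What passing tests do and do not show

The simulators generate reads with ideal structure: fixed anchors, exact
repeats (at `error_rate = 0`), no chimeras, no indel sequencing errors, no
mixed-template traces. Perfect precision/recall on such data validates the
*logic* of the callers and annotator — coordinates, exclusion rules,
orientation algebra, normalisation — not their robustness to the full error
spectrum of real amplicon or Sanger data. Conversely, the perfect-match
mapping criterion means real error-bearing reads are dropped rather than
rescued, exactly as in the original analysis.

Problem sizes used by the test suite were chosen to make binomial bounds
tight while keeping runs quick: 1,000–2,000 events across 5 seeds for
caller round-trips and length-weight recovery, 1,000 random 30-mers against
a 50-kb genome for mapping equivalence, and 200 colonies across 5 seeds for
the five-class confusion matrix.

# Known limitations

* No chromatogram emulation; Sanger reads are sequence + quality only, and
  polyclonal traces are outside the quality-gate model.
* The annotator requires both cassette anchors; swapped read roles are not
  auto-detected in this version.
* Terminal prespacer deletions are absorbed into trimming (see above).
* The deep-sequencing assay is treated as non-quantitative across
  conditions; no differential-acquisition statistics are provided.
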