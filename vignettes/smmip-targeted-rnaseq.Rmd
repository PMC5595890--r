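---
title: "Targeted RNA sequencing with smMIPs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted RNA sequencing with smMIPs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smmipseq)
```

## The assay in one paragraph

A single-molecule molecular inversion probe (smMIP) is a single-stranded
oligonucleotide whose two ends — the extension probe and the ligation
probe — are complementary to two sites on the antisense strand of a target
cDNA, placed so that exactly 112 nt of target separate them. Hybridisation,
gap-fill polymerisation and ligation circularise the probe around a copy of
those 112 nt; exonucleases remove everything linear; PCR with primers in
the probe's constant 40-nt backbone (one of them carrying a per-sample
barcode) produces the sequencing library. An 8-nt random unique molecule
identifier (UMI) adjacent to the ligation probe marks each captured
molecule, so all PCR amplicons deriving from one capture event can later be
collapsed into one *unique read*. Unique-read counts per probe measure
expression; the gap-fill sequence itself carries any variants in the
captured window.

This vignette documents the models behind each module, the tunable
parameters with their defaults, the conventions ("dialects") the package
had to fix where the assay leaves freedom, and what the built-in simulator
does and does not emulate.

## Probe design

`enumerate_candidates()` slides the 112-nt gap window along the spliced
transcript at a configurable stride (default 10 nt; 1 nt in full-coverage
mode) and for each window picks arm lengths:

* extension arm: 16–30 nt; ligation arm: 18–30 nt. The minima are the
  assay's structural constants; the maxima are a design choice.
* among admissible lengths the *shortest* whose target GC content falls in
  [0.2, 0.8] is used, falling back to the minimum length when no length
  reaches the window. Short arms keep synthesis cheap and melting
  temperatures moderate; the GC window is a coarse, transparent proxy for
  capture behaviour.

`score_candidate()` is a deliberately simple, fully documented score in
[0, 1]: per arm, a GC penalty (1 inside the window, decaying linearly to 0
over 0.2 GC units outside) times a homopolymer penalty (halved per base a
run extends beyond 5); arms containing N score 0; the arm scores multiply.
It replaces trained capture-efficiency models with something a reviewer can
recompute by hand; it makes no claim to predict absolute efficiency.

`select_panel()` picks `n_per_transcript` probes (default 5, at most 10)
per transcript by greedy assignment of candidates to the ideal
evenly-spaced grid of gap midpoints across the CDS; ties are broken by
higher score, then lower gap start, then candidate id, which makes
selection deterministic. Placing arms on *adjacent exons* is preferred
whenever any admissible window allows it (a junction-spanning probe cannot
capture contaminating genomic DNA, where the intron breaks the arm
spacing): the preference is soft during scoring but the final selection
guarantees at least one junction-spanning probe per transcript when one
exists. Full-coverage mode instead solves the classic interval-covering
problem over the CDS with stride-1 candidates. Transcripts that end up
with fewer than `n_per_transcript` probes, or an incompletely covered CDS,
are reported in the `under_covered` attribute rather than silently
accepted.

Coordinates are 0-based half-open everywhere inside the package; 1-based
numbering appears only in HGVS strings.

## The read dialect

The wet assay does not dictate where in the sequenced insert the UMI,
backbone and barcode images fall; the package therefore fixes one explicit
convention shared by the simulator and the processor:

```
amplicon = ext_arm_target (16-30) | gap (112) | lig_arm_target (18-30)
           | UMI (8) | backbone (40) | barcode (8)
read 1 = first 151 nt of the amplicon
read 2 = reverse complement of the last 151 nt
```

Consequences worth knowing:

* read 1 always covers the entire gap (arm maxima keep 16–30 + 112 within
  151 nt);
* read 2 spends 56 nt on the barcode, backbone and UMI images plus the
  ligation arm, and therefore reaches only the 3'-most `95 − lig_len` nt
  of the gap (77 nt at the minimum 18-nt arm). Positions in the 5' part of
  a gap consequently have *no reverse-orientation support* from that probe;
  a variant there can only satisfy the orientation filter through an
  overlapping probe. This asymmetry is intrinsic to any 2×151 layout that
  sequences a 112-nt gap plus a 56-nt tail through the same mate, and the
  pileup tracks per-mate coverage explicitly rather than pretending both
  mates see everything.

Primer tails are not emitted; only the sequenced insert is modelled.

## The simulator

`simulate_reads()` is the package's fixture generator and ground-truth
oracle. Its model, stage by stage:

* **capture**: `n_molecules` capture events are distributed over the
  panel by a multinomial with weights `abundance(transcript) ×
  efficiency(smMIP)`. Efficiencies are drawn once per panel as
  LogNormal(0, σ) with σ = 1.5 by default — probes on the same transcript
  routinely differ by two orders of magnitude in practice, and this
  heavy-tailed dispersion reproduces that phenomenon (it is a
  phenomenological choice, not a mechanistic claim).
* **abundance defaults**: simulation studies in this package draw
  transcript abundances log-uniformly over four orders of magnitude,
  the dynamic range a targeted expression panel typically spans; this is
  the one generator condition neither structural nor externally fixed,
  chosen once for realism.
* **variants**: spiked SNVs and deletions (1–20 nt) are held per molecule
  with probability `allele_fraction`, independently per variant. A variant
  is only *observable* — and only simulated — through probes whose gap
  fully contains it: a variant under a probe's arm would in reality
  disrupt capture of the mutant allele, so detection genuinely depends on
  which probes cover the site, and the package makes that rule explicit
  rather than modelling arm-disruption kinetics.
* **PCR and sequencing**: each molecule receives a uniform-random 8-nt UMI
  and `1 + Poisson(dup_mean)` read pairs (default `dup_mean = 1`);
  substitution errors hit each base independently at `error_rate`
  (default 0.001, a typical Illumina scale); qualities are constant
  Phred 30. The error model is substitution-only by design — spiked
  *template* deletions exercise the deletion machinery, while keeping the
  consensus oracle exact. Quality decay along the read, indel sequencing
  errors, fragmentation and index hopping are deliberately not modelled.
* **determinism**: everything derives from the plan's seed; two runs with
  the same plan produce byte-identical FASTQ.

Because UMIs are finite (4^8 = 65,536), two molecules of one probe can
collide on a UMI; at the depths used in the shipped tests (tens of
molecules per probe) this is negligible, and the exact truth-recovery
property is asserted in that regime on purpose.

## Processing and UMI consensus

`demultiplex()` matches the barcode image at the start of read 2 within a
Hamming tolerance (default 1) and refuses barcode maps whose pairwise
distance does not exceed twice that tolerance. `match_smmip()` requires
*both* arm images at their fixed positions, each within one substitution by
default; exact matches resolve through a dictionary, inexact ones through a
full panel scan; two equally good probes leave the pair unassigned (ties
are data, not guesses). `collapse_umis()` groups by `(sample, smMIP, UMI)`
— exact 8-mer match, no directional clustering; the simplest faithful
reading of UMI deduplication, documented as swappable — and takes a
per-position majority vote per mate among observations of the modal
length, breaking ties by summed base quality and then alphabetically.
Singleton families pass: no minimum family size is imposed. Collapse is
idempotent and invariant under PCR duplication depth.

Template deletions make an observation shorter than 112 nt; the deletion
is localised by maximal-prefix comparison against the reference gap and
normalised to its 3'-most placement (the HGVS convention), at transcript
scope so overlapping probes agree on the event.

## Quantification

FPM divides each probe's unique-read count by the sample's **total
assigned unique reads** and multiplies by 10^6; unassigned reads are
excluded from the denominator. No housekeeping-gene normalisation is
applied anywhere. Per-transcript expression aggregates probe FPM by
`mean` (default; zero-FPM probes included so non-performing probes count),
`median`, or `best` (maximum). TPM from whole-transcriptome gene counts is
the standard length-normalised transform. FPM–TPM concordance uses Pearson
correlation on `log10(x + 0.01)` by default: expression spans orders of
magnitude, and the pseudocount keeps non-performing panels (FPM near
10^-2) finite; the raw scale is available via `log_transform = FALSE`.
Transcripts present on only one side are reported, never silently dropped.

At the default desk-scale simulation (50 transcripts × 5 probes, 20,000
molecules) the limiting factor for abundance recovery is not the estimator
but sampling depth: transcripts at the bottom of a four-order abundance
range expect fewer than one captured molecule, their mean FPM collapses to
zero, and the log-scale floor inflates the apparent noise. The acceptance
script computes the resulting correlation at exactly these conditions;
deeper simulations (more molecules per probe) move the correlation up
towards the efficiency-dispersion-limited ceiling.

## Variant calling

The pileup records, per transcript position, base and deletion
observations split by orientation: forward = mate-1, reverse = mate-2,
each unique read contributing at most one observation per mate per
position. The VAF denominator is this orientation-split observation count
(a molecule whose position both mates cover contributes two observations)
— one explicit choice among several defensible ones, documented here
because coverage strings like `9% (22) [11 / 11]` only make sense relative
to it.

The filter: VAF ≥ 5 % and ≥ 5 supporting unique-read observations *in
total*, with both orientations represented (≥ 1 each). The stricter
reading — ≥ 5 per orientation — is available as `strict_orientation =
TRUE`. Sub-threshold alleles down to half the VAF floor are emitted with a
fail reason for audit; weaker signals are dropped. Overlapping probes pool
their counts; there is no per-probe reporting, because detection power is
a property of the covered position, not of a single probe.

Annotation maps calls into c. numbering and derives protein consequences:
SNVs by codon substitution under the standard genetic code; deletions of
length divisible by 3 as in-frame deletions (`p.…del`, `p.…delins…`;
classification `inframe_deletion`, an extension of the classic
synonymous/missense/nonsense/frameshift quartet which cannot express
them); other deletions by translating the shifted frame to its first new
stop (`p.Val83Argfs*48`), with `fs*?` when translation runs off the
transcript without meeting a stop. Two conventions for rare cases: any
variant disrupting the initiation codon is annotated `p.Met1?`
(downstream effect unknowable from sequence alone), and a stop-loss SNV is
annotated with `ext*` notation and classified as missense, the nearest
available class. Variants not fully inside the CDS are reported in n.
notation without classification.

## Synthetic reference transcripts

The package ships no third-party sequence data. Two hotspot-bearing
transcripts are *constructed in code* and documented as synthetic:

* `synthetic_vhl_transcript()` reverse-translates a VHL-like 213-residue
  protein with fixed codons at residues 82–83 and 130–132. Under that
  context the annotation engine derives — from first principles, nothing
  hard-coded — the classic consequences: `c.246_247delCG` →
  `p.Val83Argfs*48` and `c.394C>T` → `p.Gln132*`. The default codon table
  used for reverse translation avoids third-position T, so frameshifts
  through unconstrained regions cannot hit spurious stops; only the
  deliberately planted context creates them.
* `synthetic_idh1_transcript()` plants Arg codons at residues 132 (CGT)
  and 314, giving `c.395G>A` → `p.Arg132His` and `c.940C>T` →
  `p.Arg314Cys`.

These stand-ins reproduce the hotspots' *local* codon arithmetic exactly
while making no claim to be the RefSeq sequences; anything depending on
the true global sequence (e.g. genome-space coordinates) is out of scope.

## Problem sizes and numerical choices

The shipped test-suite and acceptance script run, per invocation: panel
design on ~50 synthetic transcripts (~250 probes); simulations of 100–
20,000 molecules (up to ~40,000 read pairs); a 1,000-case random-variant
annotation comparison against a brute-force translate-and-diff oracle; and
a brute-force subset-enumeration check of the even-spacing selector on a
20-candidate instance. These sizes were chosen so the whole suite runs in
about a minute on one core while still exercising every code path at
realistic per-probe depths.

Degenerate inputs are handled explicitly rather than by crashing:
transcripts too short for any probe yield an empty candidate set; a sample
with zero assigned reads yields all-zero FPM with a warning; unmatchable
read pairs and sub-threshold alleles are data with a recorded status, not
errors.

## Known limitations

* The capture-efficiency model is phenomenological; the design score is
  transparent but untrained. Neither predicts wet-lab efficiency of a
  specific probe.
* UMI grouping is exact-match; at depths approaching the 4^8 UMI space,
  collisions deflate unique counts and a directional-clustering grouper
  would be the next step.
* Read 2 never reaches the 5' third of a gap (see the dialect above), so
  single-probe coverage cannot PASS the orientation filter there.
* Variant support is transcript-space only; there is no genomic liftover,
  no fusion or splice-variant caller, and no insertion support.
* Passing simulation-based tests demonstrates internal consistency of the
  pipeline under the documented generative model — substitution-only
  errors, independent molecules, in-read barcodes — not performance on
  real libraries, where chemistry artifacts the simulator omits (primer
  carry-over, chimeras, quality decay) will add noise.
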