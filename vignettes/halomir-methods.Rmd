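---
title: "halomir: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{halomir: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halomir)
```

# The problem

Halophytes such as the common ice plant tolerate soil salinities that stop
glycophyte growth, and part of that tolerance is exerted post-
transcriptionally through microRNAs. A standard experimental design
sequences small RNA libraries from control and salt-treated seedlings,
assembles a reference transcriptome from the matched poly(A)+ libraries, and
then asks four computational questions:

1. Which known plant miRNA families are expressed, and at what abundance in
   each condition?
2. Which small RNA tags derive from genuine hairpin precursors encoded in
   the transcriptome — including novel, species-specific miRNAs?
3. Which transcripts do those miRNAs target, and is targeting by cleavage
   corroborated by degradome (PARE) sequencing?
4. How does expression shift under stress, for miRNAs and their targets,
   by qPCR?

halomir implements this workflow end to end as composable R functions with
a synthetic-data generator so that every stage is testable without any
external download.

# Read cleaning and tag collapsing

Raw reads carry a 3' sequencing adapter. `trim_adapter()` truncates each
read at the leftmost position where an adapter *prefix* of at least
`min_overlap` bases (default 6) matches exactly. Trimming is deliberately
exact-match: no published error rate is available for the data this mirrors,
and an exact trimmer is reproducible and dependency-free. Mismatch-tolerant
trimming, quality trimming and paired-end handling are out of scope.

`filter_reads()` then keeps exactly the reads that are 18–25 nt long,
contain no ambiguous base, and do not match a user-supplied contaminant
(t/rRNA) set by exact full-sequence membership. The filter is idempotent and
order-preserving. `collapse_tags()` produces one tag per distinct sequence
with per-library counts (the count conservation `sum(counts) == clean
reads` is enforced by construction and asserted in the tests), plus a
per-library profile: redundant and unique size histograms over 18–25 nt and
the 5'-nucleotide composition. The 5' composition is computed over *unique*
tags per length class, which is the convention used when reporting that 21–
22-nt small RNAs tend to begin with U; each occupied row sums to 1.

All sequences are normalized to the uppercase DNA alphabet (U→T) at ingest;
mature miRNAs can be printed back as RNA with `as_rna()`.

# Conserved family assignment and RPM

`match_tag()` assigns 20–22-nt tags to mature reference entries by
equal-length Hamming matching with at most 2 substitutions. Indel-tolerant
matching is deliberately excluded: "two mismatches" is only reproducible as
substitution-only distance, and restricting the conserved search to 20–22 nt
matches the mature length range of conserved plant miRNAs. Family labels
are parsed from miRBase-style names (species prefix and member suffix
stripped), with an explicit merge table for families conventionally reported
jointly (miR156/157, miR165/166).

Abundance is reported in reads per million: the summed redundant counts of
the tags assigned to a family, divided by the library's full 18–25-nt clean
total, times 10^6 (`compute_rpm()`). The denominator is always the clean
total, not the 20–22-nt subset searched. A tag matching several families
counts once per family; this double-counting is documented behaviour (the
alternative — fractional assignment — is not reconstructible from published
tables). RPM is therefore scale-invariant (doubling all counts changes
nothing) and a library's family total cannot exceed 10^6 except through the
multi-family rule.

# Precursor discovery

`anchor_tags()` finds every perfect occurrence of a tag on either strand of
the transcriptome contigs (minus-strand hits via reverse complement,
coordinates reported on the forward strand). `extract_window()` cuts the
candidate precursor: up to 200 nt upstream and downstream of the anchor,
clipped at contig ends, in 0-based half-open coordinates; minus-strand
windows are returned reverse-complemented with forward coordinates
recorded. Windows shorter than 30 nt or longer than 500 nt are rejected as
candidates (not errors).

## The folding engine

`fold_rna()` computes a minimum-free-energy nested secondary structure with
a self-contained nearest-neighbour model — self-contained because the
pipeline must be reproducible from this package alone, and because the
acceptance surface is not bit-compatibility with any particular folding
server (whose versions drift) but the behaviour of the −35 kcal/mol
threshold on hairpin-versus-background discrimination.

The model is the minimal published parameter set:

* Watson–Crick and G:U wobble pairs; the ten unique Watson–Crick stacking
  energies (Turner values, kcal/mol at 37 °C) completed by the symmetry
  `stack(p, q) = stack(rev(q), rev(p))`;
* G:U-containing stacks at a coarse three-level scheme (−1.5 against
  C-G/G-C, −0.8 against A-U/U-A, −0.5 for tandem wobbles, +0.47 for the
  destabilising 5'GG/3'UU motif and its symmetric mate);
* size-dependent hairpin (≥ 3 unpaired bases), bulge and internal-loop
  penalties with logarithmic extrapolation `E(last) + 1.08·log(n/last)`
  beyond tabulated sizes, and an internal-loop asymmetry penalty
  0.6·|n1 − n2| capped at 3.0;
* an affine multibranch term (3.4 init + 0.4 per branch, unpaired free);
* no pseudoknots, no dangling ends, no coaxial stacking, no special
  tetraloops, interior loops capped at 30 unpaired nucleotides.

The dynamic programme is the standard Zuker O(n³) recursion; the empty
structure has energy 0, so the reported MFE is never positive. Traceback is
deterministic with a fixed preference order (hairpin, stack, interior loop
by increasing 5' extent, multibranch), so identical inputs always give
identical structures. `fold_params()` exposes the full parameter set; the
test suite re-derives structure energies by independent loop decomposition
from those tables and checks the engine against exhaustive enumeration of
all nested structures on random sequences up to 14 nt, where enumeration is
tractable.

What this does and does not show: the engine provably minimises *its own*
energy model; it is not a re-implementation of full Turner-2004
thermodynamics, and its MFE values will differ from mfold/ViennaRNA by a
few percent on long hairpins. All thresholds that consume MFE (notably the
−35 kcal/mol criterion) operate at margins far wider than that difference
for genuine precursors (planted perfect stems score below −80; unstructured
sequence scores near 0).

## Duplex location and the five validity criteria

The miRNA arm is the anchored tag. The star arm is inferred from the fold
by the Dicer 2-nt 3'-overhang rule: the star runs from the pairing partner
of miRNA position L−2 to the partner of miRNA position 1, plus 2 nt — a
formula that is symmetric for 5'- and 3'-arm miRNAs and is an involution
(the star of the star is the miRNA). If a boundary position is unpaired the
partner is extrapolated from the nearest paired position so the candidate
can still be reported, but the overhang criterion is then failed.

`evaluate_criteria()` computes five independent verdicts:

1. hairpin MFE ≤ −35 kcal/mol;
2. at most 4 mismatches in the miRNA/miRNA* duplex — a mismatch is a miRNA
   duplex position (excluding the 2-nt 3' overhang) not paired into the
   star span; G:U wobbles count as pairs, following standard plant-miRNA
   annotation practice (configurable);
3. at most one asymmetric bulge in the duplex, of at most 2 nt — bulge
   asymmetry is measured between consecutive paired duplex positions;
4. miRNA : miRNA* read ratio ≥ 5, with star support looked up as the counts
   of any sequenced tag equal to the inferred star sequence (summed over
   libraries);
5. clean 2-nt 3' overhangs, i.e. both duplex boundary positions are
   actually base-paired.

`valid` is the conjunction. When no star read exists, criterion 4 is
recorded as `NA` ("not evaluable") and the candidate is reported with
`star_evaluable = FALSE` but not counted valid — mirroring the practice of
retaining well-supported precursors whose star strand was never sequenced,
while keeping the strict reading of the criteria for automated calls. A
structure with no stem under the miRNA fails all duplex criteria rather
than erroring.

A note on criteria counts: the source workflow's results section speaks of
"ten criteria" while its methods enumerate five; the five enumerated
criteria are normative here.

## Thermodynamic statistics

`thermo_stats()` computes AMFE = MFE / hairpin length × 100 (kcal/mol per
100 nt), GC% from the precursor sequence, and MFEI = |AMFE| / GC%. The MFEI
is reported as a magnitude (conventionally printed positive while AMFE is
negative). Values are kept at full precision and rounded to 2 decimals only
in report writers. A GC% of zero leaves the MFEI undefined and flagged
rather than infinite.

The packaged precursor tables (19 conserved, 24 novel records) carry
per-row consistency flags computed at load time: several printed rows do
not satisfy AMFE = MFE/length×100 under any rounding (the printed hairpin
length is evidently not always the length the AMFE was computed from), so
identity checks run only on rows flagged consistent, and the flags are part
of the loader contract rather than a hand-maintained list.

# Target prediction

`score_duplex()` scores a miRNA/site alignment read from the miRNA 5' end:
match 0, G:U 0.5, mismatch 1.0, gap 2.0, with penalties multiplied by 1.5
at miRNA positions 2–13. This is the documented default scheme of the
psRNATarget lineage of plant target predictors; every constant is a
function argument. `scan_targets()` slides the miRNA over every transcript
position (ungapped, antiparallel) and reports sites with expectation ≤ 3.0
best-first; gapped sites are reachable only through an explicit manual
alignment, and curated above-cutoff pairs can be carried with a `manual`
flag (the packaged target table contains one such pair, at expectation 4).
Site regions (5' UTR / ORF / 3' UTR) are labelled from a user-supplied ORF
interval table; no ORF prediction is performed. `classify_inhibition()`
calls translation repression if and only if a mismatch or gap covers miRNA
position 10 or 11, cleavage otherwise.

# Degradome confirmation

`build_tplot()` accumulates degradome 5'-end tag counts per transcript
position. `categorize_peak()` follows the CleaveLand-lineage category
scheme — 0 unique maximum, 1 tied maximum, 2 above the median of nonzero
counts, 3 at/below it, 4 singleton — chosen because the cited software
version names no explicit rules; categories 0–1 are invariant under uniform
count scaling. `confirm_cleavage()` accepts a predicted site when a peak of
category ≤ 2 lies within ±1 nt of the base paired to miRNA position 10
(cleavage falls between positions 10 and 11; the degradome tag marks the 5'
end of the 3' fragment). Transcripts without degradome data are flagged
`"no data"` rather than silently unconfirmed. No p-value/noise model of
t-plots is attempted.

# Expression analysis

`delta_delta_ct()` implements the Livak–Schmittgen method on replicate Ct
tables: dCt = target − internal control per replicate, fold change
−ΔΔCt = dCt(control) − dCt(treatment), relative expression 2^(−ΔΔCt).
Significance is a two-sample t-test on replicate dCt values; Welch's
unequal-variance flavour is the default (the safer reading of "Student's
t-test" when replicate variances are unknown), with the pooled-variance
option available. No multiple-testing correction is applied, matching
per-assay significance asterisks at P ≤ 0.05. Replicate counts are
data-driven; with fewer than two replicates per condition the p-value is
`NA`. `compare_rpm()` reports linear and log2 treatment/control RPM ratios
with a ±10% dead-band for "unchanged" and an explicit flag for families
absent from the control.

# The synthetic-data generator

`generate_synthetic()` is first-class, tested code, not a fixture. Its
defaults define the study conditions for all recovery tests:

* 5 valid hairpins: 21-nt miRNAs at offset 20 inside 70-bp perfect stems
  (loop 8 nt), planted between 200-nt unstructured flanks built from the
  {A, C} alphabet — no A/C base can pair with any other, so the designed
  duplex is unambiguously the MFE structure and planted-truth recovery is
  exact by construction;
* 5 decoys, each violating one named criterion: `mfe` decoys are tags in
  fully unstructured loci (window MFE 0), `ratio` decoys are sound hairpins
  whose star strand is sequenced at half the mature count (ratio ≈ 2);
* mature counts drawn log-uniformly in [20, 200] per library, emulating the
  wide dynamic range of real family abundances; star counts a tenth of the
  mature count (ratio ≈ 10:1);
* a 3' adapter on every read, two contaminant species, and length/ambiguity
  junk that the preprocess filters must remove;
* degradome tags: a 20-read peak exactly opposite miRNA position 10 of each
  planted target site plus singleton background noise, and decoy
  transcripts with noise only;
* Ct tables with 6 replicates, noise SD 0.05, and per-assay planted shifts
  drawn uniformly in [−2, 2] (−ΔΔCt units).

The truth object names, for every entry, the module it tests, and
regeneration with the same seed is byte-identical (asserted on file
checksums). What the generator does **not** emulate — and what passing
recovery tests therefore do not demonstrate — includes sequencing error,
quality-score variation, imperfect stems with natural bulges, paralogous
precursor families, cross-mapping tags, and degradome background shaped by
ribosome or exonuclease artefacts. Recovery at precision = recall = 1 is a
correctness statement about the pipeline's logic under noise-free
conditions, not a sensitivity estimate on real libraries.

# Problem sizes and runtime choices

The test suite folds windows up to 421 nt (an anchored 21-nt tag plus two
200-nt flanks); the O(n³) engine folds such a window in well under a
second. Oracle-equivalence testing enumerates all nested structures for 500
random sequences of up to 14 nt, the size at which exhaustive enumeration
is still exact and fast. Recovery tests use the generator defaults above
(5 + 5 loci, two libraries, a few thousand reads); these sizes exercise
every code path while keeping the full suite under a minute.

# Known limitations

* The energy model is minimal by design; absolute MFE values are not
  comparable to full Turner-2004 implementations, only threshold behaviour
  is.
* Star support lookup requires the star tag to have been sequenced exactly;
  shifted star isoforms are not aggregated.
* Target scanning is ungapped; bulged target sites must be curated
  manually.
* Contaminant removal is exact membership, not alignment against rRNA
  databases.
* Library-scale count reproduction (millions of reads, full miRBase family
  censuses) is outside desk scale and is not asserted anywhere; such
  numbers depend on the raw accession data and a specific reference
  version.
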