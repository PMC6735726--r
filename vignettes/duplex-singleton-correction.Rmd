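---
title: "Duplex UMI error suppression with Singleton Correction"
author: "duplexsc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplex UMI error suppression with Singleton Correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexsc)
library(dplyr)
```

## The problem

Calling variants below ~1% allele frequency from hybrid-capture sequencing
is limited by sequencer and polymerase errors (~0.1-1% per base) and by
strand-asymmetric artefacts such as oxidative 8-oxoguanine damage, which
reads out as G>T on one strand of a molecule. Duplex unique molecular
identifiers (UMIs) address both: PCR duplicates of one strand of one
template molecule are collapsed into a single-strand consensus sequence
(SSCS), and the two complementary SSCSs of a molecule are condensed into a
duplex consensus sequence (DCS) in which any base not confirmed by both
strands is masked.

The weakness of the traditional workflow is its appetite for redundancy:
only read families with at least two members can form an SSCS, and a DCS
needs both strands duplicated. In moderately deep libraries
(~1000-10000x), half or more of all reads are *singletons* - strands
sequenced exactly once - and they are simply discarded. Singleton
Correction closes this gap: a singleton is compared position by position
against the complementary strand of the *same molecule*, either a
complementary SSCS (*SC by SSCS*) or, failing that, the complementary
singleton (*SC by singletons*). Concordant bases are kept, mismatches are
masked with N. Because the two strands were replicated independently
before any shared error could arise, concordance carries almost the same
evidential weight as a classical duplex comparison.

## Molecular identifiers

Each library fragment carries a 2 bp in-line UMI at either end, followed
by an invariant spacer base (`T`) required by ligation. Read 1 therefore
starts with the UMI of its fragment end plus the spacer; both prefixes are
removed and the two UMIs concatenated into a 4 bp duplex barcode stored in
the read name. Pairs whose spacer base is mutated on either mate are
rejected outright as non-compliant.

A 4 bp barcode alone cannot identify a molecule, so the family key
combines it with the alignment features of the pair: contig, both mates'
leftmost mapping positions and CIGAR strings, read orientations, and the
strand of origin inferred from orientation and read number (mate 1
forward = plus strand). Reads sharing a family key are PCR duplicates of
one strand of one molecule. The complementary strand of the same molecule
carries the *interchanged* barcode (halves swapped: `AC|GT` on the plus
strand appears as `GT|AC` on the minus strand) with mate roles reversed;
the *duplex key* is the lexicographic minimum of a key and its transform,
so both strands of a molecule hash to the same duplex key. The transform
is an involution, which the test suite checks exhaustively on simulated
libraries.

Two design points are worth making explicit:

* Coordinates are used exactly as recorded in the alignment; soft clips
  are not unwound. Clip variants differ in CIGAR and therefore fall into
  different families, which is the conservative choice.
* Barcode matching is exact. UMI sequencing errors can split a family in
  two; with 2 bp UMIs and position/CIGAR keying the information loss is
  small, and edit-distance clustering is deliberately out of scope.
* Improper pairs (both mates mapped, unexpected orientation) are kept and
  keyed like any other pair; the orientation field keeps them from ever
  merging with proper-pair families.

## Consensus calling

SSCS collapsing works per aligned column of a read family. Bases below
the Phred quality threshold (default Q30, comparator `>=`, with the
strict `>` reading available as a configuration switch) are removed
first; among the survivors the most common base is called if its
proportion is **greater than or equal to** the consensus cutoff (default
0.7, following the duplex-sequencing literature), otherwise the position
is masked with N. The proportion's denominator is the quality-surviving
bases, not the family size, because filtering precedes evaluation. Ties
can never reach a cutoff above 0.5, so they are masked; an empty survivor
column is masked as well. The consensus base quality is the maximum
quality among agreeing reads - a deliberate choice to stay on the
interpretable Phred scale rather than invent a recalibration; masked
positions carry quality 0. Columns are paired by read offset, which is
legal because family members share a CIGAR by construction of the key;
indel-aware realignment within families is out of scope.

Singleton Correction compares two aligned records of complementary
strands in reference coordinates, so mate 1 of one strand overlays mate 2
of the other and no explicit reverse complement is needed. Both sides
must pass the quality threshold; concordant bases are retained with the
minimum of the two qualities, and everything else becomes N. Rescue is
step-wise: an SSCS partner takes priority over a singleton partner, each
singleton is consumed at most once, and the three outcome streams
(`SC_by_SSCS`, `SC_by_singleton`, `uncorrected_singleton`) are disjoint.
When correction is by singletons, *both* corrected strands are emitted so
duplex formation sees the pair. Correcting against an SSCS leaves the
SSCS itself untouched.

DCS formation applies the same concordance rule to the two strand
consensuses under one duplex key (no quality gate - both inputs are
already quality-filtered consensus reads) and records the maximum quality
at concordant positions. The DCS takes the plus strand's coordinates and
is named by the canonical duplex key, so re-runs are byte-stable. Because
a duplex key can only ever hold one family per strand, more than two
strand consensuses under one key indicates corrupted grouping and raises
an assertion rather than a silent merge.

For downstream review the package also emits the merged
all-unique-molecules table (DCS + duplex-unpaired SSCS + uncorrected
singletons). With Singleton Correction every molecule lands in exactly
one stream and the merge enforces uniqueness per duplex key; in a
traditional run the two strands of an unrescued molecule legitimately
remain separate single-strand records and the check relaxes to per-strand
uniqueness.

## Metrics

Coverage is fragment-based: a read pair is one template, so positions
covered by both mates count once. The mean is taken over all panel
positions, including uncovered ones, matching the usual
depth-of-coverage convention for targeted panels. From it derive

* efficiency = cov(consensus) / cov(uncollapsed) - consensus sequences
  produced per sequenced read (10% means ten reads per consensus);
* DCS recovery = cov(DCS) / (cov(SSCS)/2) - observed duplexes over the
  theoretical maximum, since each DCS consumes two strand consensuses.
  The bound cov(DCS) <= cov(SSCS)/2 holds on every input, with equality
  exactly when every strand consensus finds its partner.

The background error report counts non-reference bases over all sequenced
bases within the panel, per aligned position. A non-reference allele at
or above the allele-frequency ceiling (default 5%; the error comparison
is strictly below) is treated as a putative variant and excluded from the
numerator for that allele only; any single supporting read below the
ceiling counts. N bases are excluded from numerator and denominator;
indels are outside the 12-class substitution profile. The
`substitution_imbalance()` helper reports the G>T / C>A ratio used to
diagnose oxidative damage; an empty profile is defined as balanced
(ratio 1), since no substitution of either class was observed.

## The simulator

All tests and the acceptance analysis run against a bundled generator
with complete ground truth, so no external data are needed. It draws
template molecules from a target panel on a ~50 kb synthetic toy genome
(six 1.5 kb targets), assigns each a fragment (normal length, default
170 +/- 25 bp, floored at 30 bp with read-through truncation when the
fragment is shorter than the read length), a UMI pair uniform over the
16 x 16 dinucleotide space, and independent per-strand read-pair counts
from a configurable distribution:

* `fixed` - every strand sequenced exactly k times (saturated regimes);
* `ztpois` - zero-truncated Poisson, the singleton-rich moderately deep
  regime in which every strand is seen at least once;
* `pois` - plain Poisson, allowing strand dropout and hence uncorrectable
  singletons and unpaired SSCSs.

Two error channels are modelled. The substitution channel flips each
sequenced base independently with the configured probability, uniformly
to the three alternatives - polymerase and sequencer noise without
context effects. The oxidative channel damages a molecule with the
configured per-molecule probability: one reference-G site in the fragment
is chosen and *all reads derived from one strand* (chosen at random)
report T there, while the complementary strand is clean. This is a
phenomenological model of 8-oxoG: it reproduces the defining features -
strand confinement and a G>T excess over C>A in the raw substitution
profile - without modelling the lesion chemistry or the partial C>A
mirror seen in real libraries. Base qualities follow a two-point mixture
(Q37/Q25) with a configurable fraction below Q30, exercising the quality
gate with one knob. Quality values are independent of the injected
errors, so the Q30 filter prunes coverage, not errors specifically - a
simplification relative to real base callers, where quality predicts
error probability.

Because UMIs and coordinates are finite, two molecules can collide
(identical fragment coordinates and UMI pair). Collisions are invisible
to *any* UMI-based method and merge into one family per strand;
`collapse_truth()` folds them in the truth table so exact stream
accounting remains possible. At the scales used here (10^4 molecules over
a 9 kb panel) the expected number of collisions is well below one.

What passing tests on this simulator do **not** show: robustness to
alignment ambiguity (the default test path emits truth-aligned records,
bypassing an aligner by design to keep acceptance deterministic; a FASTQ
path exists for end-to-end runs through `bwa`), indel errors, UMI errors,
context-dependent error spectra, capture bias, or overdispersed
duplication. Those features of real data are listed as non-goals.

## Analytic expectations

For a per-strand count distribution with P(0), P(1), P(>=2) = p0, p1, p2,
each molecule's strand pattern determines its fate: (>=2, >=2) gives a
traditional DCS; (1, >=2) an SC-by-SSCS rescue; (1, 1) an SC-by-singleton
pair; (1, 0) an uncorrected singleton; (>=2, 0) an unpaired SSCS. With
and without rescue the expected DCS counts are n(p1 + p2)^2 and n p2^2.
`expected_stream_sizes()` returns these with their binomial standard
deviations, and the acceptance suite holds the pipeline to them within
3 sigma at n = 10^4 in three regimes - plus an *exact* accounting against
the collision-merged truth table.

The same algebra explains the depth sweep. Under Poisson thinning with
per-strand mean m, the singleton fraction among families p1/(1-p0) rises
monotonically as depth falls, while the rescue-event rate (rescued
singletons per family) equals p1 = m e^-m, which peaks at m = 1: at
saturation there are no singletons to rescue, at scarcity the
complementary strand is missing. The bundled sweep (a fixed-12 library
thinned to means of about 8, 3, 1, and 0.3 reads per strand, chosen
a priori to straddle that peak) reproduces both shapes. The downsampler
keeps mates together by sampling templates Bernoulli at the
target-to-current coverage ratio - unbiased, seed-stable, and within a
few percent of the target at realistic depths.

## Study conditions used by tests and the acceptance analysis

Problem sizes were chosen so the full suite runs in minutes on one core
while keeping sampling error far from the asserted margins: module tests
use 10^2-10^3 molecules on a 12 kb toy genome; stream combinatorics,
error ordering, and the oxidation analyses use 10^4 molecules on the
bundled 50 kb genome. The error-ordering condition injects 3e-3 per-base
error into the zero-truncated Poisson (lambda = 1.2) regime; corrected
singletons must come in more than tenfold below raw singletons and match
the DCS rate at the scale of the uncollapsed rate. The oxidation
condition uses a 1e-2 per-molecule lesion rate over a 5e-5 substitution
floor - the floor set low so the damage channel dominates the raw
profile, as it does in heavily oxidised libraries; the raw G>T/C>A
imbalance must exceed 5 and fall below 1.2 after correction. Perfect
recovery is demanded only where it is provable: an error-free, fully
duplicated library must reproduce every molecule exactly with 100% DCS
recovery.

## Limitations

* Indels: families are keyed on CIGAR, so indel-bearing reads form
  separate families; there is no indel consensus beyond identical-CIGAR
  agreement.
* Exact UMI matching: a sequencing error inside a UMI creates a spurious
  singleton rather than joining its family.
* The consensus quality model (max of agreeing qualities; min across
  strands for corrected singletons) is a bookkeeping convention, not a
  calibrated posterior.
* Variant calling on the outputs is out of scope; the merged
  all-unique-molecules table is the intended hand-off point.
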