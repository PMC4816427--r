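---
title: "Characterizing mature miRNA sequences: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing mature miRNA sequences: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirchar)
```

## The problem

Mature microRNAs are short (roughly 16–27 nt) single-stranded RNAs whose
sequence content carries functional signals beyond target
complementarity: a 5'-UGUGU-3' pentamer is associated with innate immune
(interferon) stimulation by small RNAs, GU-rich elements are bound by
dedicated RNA-binding proteins, strongly purine- or pyrimidine-biased
sequences interact with polypyrimidine-tract binders or purine-rich
translation signals, and short self-complementary stretches let a mature
miRNA fold back into a stem-loop that can modulate its stability and
target recognition. mirchar computes these censuses reproducibly for any
mature-miRNA FASTA library: length and composition profiles, positional
occupancy, purine/pyrimidine classification, exact-motif and
alternating-GU scans, microsatellite (SSR) detection, and hairpin /
tetraloop classification.

## Library construction

Sequences are normalized (T mapped to U, uppercased) and validated
against the strict alphabet {A, C, G, U}; a record with any other
character aborts the run naming the offending id, because silently
dropping records would corrupt every downstream census. Public miRNA
databases annotate identical sequences under multiple names, so
`deduplicate()` keeps exactly one record per distinct sequence — the
first seen, making the result deterministic given file order — and
retains all names in an alias map. Deduplication is idempotent, and every
census in the package is computed from the deduplicated snapshot. Species
subsets are selected by id prefix (human mature ids begin `hsa-`), the
only species marker present in mature-set headers.

## Composition and richness

`base_content()` pools nucleotide counts over all sequences;
`positional_frequency()` tallies per-position occupancy with sequences
anchored at the 5' end or, separately, at the 3' end (position p counts
only sequences of length at least p, so coverage is non-increasing).
Coordinates are 1-based throughout, matching the field's "seed =
positions 2–8" convention.

A sequence is purine-rich (A+G) or pyrimidine-rich (C+U) when the
relevant fraction strictly exceeds the threshold, default 0.70; the
strict inequality reflects the usual "over 70%" phrasing. A second flag
marks highly rich sequences at a fraction of 0.90 or more; `>=` is used
there because reference lists include sequences whose percentage rounds
to exactly 90. Both thresholds are arguments. Reported percentages are
rounded half away from zero to integers — the convention
(`round_half_up()`) that reproduces published tables exactly, where
round-half-to-even would not (e.g. 90.5 must print as 91).

## Motifs and GU tracts

`scan_motif()` reports exact occurrences of an {A,C,G,U} motif with
1-based inclusive coordinates. Overlapping occurrences are reported by
default: copies of UGUGU inside a GU-repeat region overlap, and a census
that drops them undercounts. Only the given strand is scanned — mature
miRNAs are single-stranded, so reverse-complement hits are meaningless
here.

A GU tract is a maximal run of strictly alternating G and U in either
phase. No formal community definition of a "GU-rich" miRNA exists; the
package calls a sequence GU-rich when it carries at least one such tract
of 5 nt or more, the weakest rule satisfied by every published GU-rich
sequence, and exposes the length floor as an argument. Because this is a
necessary rather than exclusive criterion, equality with any published
curated list is treated as a regression check on membership, not as a
defining test.

## SSR detection

Microsatellite detection uses the minimum-three-complete-repeats rule for
every unit size 1–5: a mononucleotide tract needs a run of at least 3 nt,
a dinucleotide tract at least 6 nt, and so on. Three further choices pin
the census down:

* **Complete units only.** A trailing partial unit does not extend a
  tract: `GUGUGUG` is (GU)3 with the final G excluded, so repeat counts
  are integers.
* **Primitive units only.** A unit must not itself be a repetition of a
  shorter string, so an (A)6 run is never double-reported as (AA)3.
* **Leftmost-greedy, non-overlapping within a unit length.** Scanning
  resumes after each reported tract; phase-shifted alternatives of the
  same tract are not double-counted. Censuses of *different* unit lengths
  are independent and may overlap (the GGG runs inside a (UGGGC)4 tract
  are a legitimate mononucleotide finding).

The library summary reports totals per unit length and relative counts —
tracts divided by the number of miRNAs ("repeats per miRNA on average"),
printed to two decimals. `longest_mono_run()` deliberately ignores the
three-repeat floor so that maxima of 1 or 2 are well-defined on
degenerate libraries.

Published SSR censuses of this kind were produced with external
microsatellite servers whose overlap and normalization settings are not
fully specified; the per-unit-length totals of such tables are therefore
not used as numeric targets. Instead the detector is verified by
equivalence with an independent brute-force oracle (enumerate every unit
length and phase, keep maximal primitive tracts, apply the same greedy
selection) on enumerated edge cases and on 1,000 seeded random sequences
up to 30 nt, plus exact recovery of generator-planted tracts.

## Hairpin enumeration

`enumerate_hairpins()` considers every loop placement with loop length in
[`loop_min`, `loop_max`] (default 3–8) and grows the stem outward from
the closing pair while bases form Watson–Crick (A:U, G:C) or — by default
— G:U wobble pairs. Stems are contiguous: no bulges or internal loops.
For molecules of at most ~27 nt this simple-stem model is appropriate,
and it keeps the enumerator exactly verifiable against a brute-force
oracle; it is *not* a thermodynamic folding method, and counts of
"foldable" sequences from free-energy programs are version- and
model-dependent, so they are out of scope as numeric targets. Each loop
placement yields at most one (maximal) hairpin; candidates with stems of
at least `min_stem` (default 3) base pairs are returned sorted by
descending stem length, then ascending loop length, then position, and
`best_hairpin()` takes the first. The minimum loop length is 3 nt, the
smallest sterically plausible hairpin loop.

`stability_score()` ranks hairpins by a pairing-weight surrogate — 3 per
G:C, 2 per A:U, 1 per G:U, minus 0.5 per loop nucleotide beyond 3. It is
a documented heuristic for ordering structures, explicitly not a free
energy in kcal/mol.

The tetraloop census mirrors the standard three-stage cascade: loop is
one of the configured 4-mers (the stable-tetraloop set UUCG, GAAA, GCAA,
GAGA, GUGA, GGAA, CUUG, UUUG, plus UUUU, which reference censuses
tabulate alongside them); stem of at least 3 bp; C-G closing pair. The
closing-pair test is on the unordered pair {C,G} by default because
published phrasing does not fix an orientation; a strict 5'-C/3'-G mode
is available. When one sequence admits several qualifying hairpins the
cascade counts the sequence by its best motif-loop hairpin by default
(`count = "all"` credits any); stage counts are non-increasing in either
mode.

## The synthetic generator

`generate_library()` emulates the statistical shape of a real mature
library: lengths 16–27 nt with mode 22 at 47%, 21 at 12%, 23 at 14% and
the remaining mass uniform over the other lengths, and background bases
i.i.d. with A 0.23, C 0.22, G 0.29, U 0.26 (the pooled composition of the
human mature set). Both distributions are overridable; no claim is made
of matching the real length profile beyond these headline values.

Features — motif occurrences, SSR tracts, hairpins, terminal bases — are
planted in exactly `round(fraction * n)` records at random admissible,
mutually disjoint positions. Ground truth stores exact 1-based
coordinates for every planted instance. Two mechanisms keep the truth
exact without rejecting whole libraries:

* **Flank repair.** A base adjacent to a planted SSR tract that would
  extend it (as a complete unit or as a phase-shifted rotation) is
  redrawn from the remaining alphabet; likewise a flanking pair that
  would extend a planted stem. This local resampling is the documented
  departure from a pure i.i.d. background.
* **Record certification.** Each record is rescanned after planting:
  planted instances must be recovered exactly, and *background* regions
  must be free of chance occurrences of any planted feature type;
  failing records are regenerated (up to 500 attempts). Findings inside
  *other* planted inserts are accepted and are genuine — a planted (GU)3
  tract is the string `GUGUGU`, which necessarily contains the UGUGU
  motif, and a planted GAAA tetraloop necessarily contains a mono-A run.
  Tests of exclusive recovery therefore hold outside planted inserts,
  not inside them.

What passing recovery tests show is that the scanners report planted
signal with exact coordinates and nothing in certified-clean background.
They do not show that real libraries are i.i.d. — real miRNAs have
correlated composition, shared seed families and biased ends — so
full-library census values on real data remain a property of the data,
not of the detector.

All randomness is confined to the generator and derives from the spec's
mandatory seed; analysis stages are deterministic, and the caller's RNG
state is restored after generation.

## Orchestration and reporting

`run_characterization()` computes every table from one deduplicated
snapshot and returns them with a manifest (package version, configuration
hash, input checksum). Output bundles are byte-deterministic — no
timestamps — so identical input and configuration give identical files,
and the configuration hash changes exactly when an analysis-relevant
parameter changes. A thin command-line wrapper with subcommands (`run`,
`stats`, `ssr`, `motifs`, `hairpins`, `simulate`, `fixtures`) is
installed under `inst/cli/`.

## Verification scale and limitations

The test suite verifies the detectors by oracle equivalence on 1,000
seeded random sequences (lengths 5–30 for SSRs, 8–30 for hairpins) plus
enumerated edge cases, and end-to-end recovery on a 500-record synthetic
library with motif, SSR and hairpin plantings — sizes chosen so the whole
suite runs in about a minute while exercising every branch of the
scanners; the generator's certification makes larger n add repetition,
not coverage.

Known limitations: no bulged or multi-branch structures and no
thermodynamics in the hairpin model; no compound or interrupted SSRs; no
IUPAC-degenerate motif grammar (exact {A,C,G,U} strings only); GU-richness
is a presence rule, not an exclusive definition; and fixture tables are
stored exactly as printed in their source, including two typographical
quirks in the ids that are preserved deliberately (deduplication is by
sequence, so they are harmless).
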