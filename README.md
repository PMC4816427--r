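# mirchar

Sequence and structural motif characterization of mature human miRNAs.

Mature microRNAs (~16–27 nt, single-stranded) carry functional signals
in their raw sequence: the 5'-UGUGU-3' interferon-induction motif,
alternating-GU tracts, strong purine/pyrimidine bias, microsatellite
(simple sequence repeat, SSR) tracts, and short self-complementary
stretches that fold into stem-loops with stable tetraloops. mirchar is
an R package for researchers who need these censuses computed
reproducibly over a mature-miRNA FASTA library (miRBase `mature.fa`
dialect), with every detector verified against independent brute-force
oracles and a seeded synthetic generator for end-to-end validation.

## What it computes

Given a library *L* of sequences over {A, C, G, U}:

* **Library construction** — FASTA ingest with T→U normalization, strict
  alphabet validation, and deduplication of identical sequences
  annotated under different names (first-seen id kept, aliases mapped).
* **Composition** — length distribution; pooled base content; positional
  frequency matrices anchored at the 5' and 3' ends; terminal-base
  tables; purine/pyrimidine calls: purine-rich iff f(A+G) > 0.70
  (strict), highly rich iff the dominant fraction ≥ 0.90, percentages
  rounded half away from zero.
* **Motifs** — exact-motif scans (overlapping by default) and the UGUGU
  census; maximal alternating-GU tracts, with a sequence called GU-rich
  when it carries a tract ≥ 5 nt.
* **SSRs** — for unit sizes 1–5, maximal tracts of ≥ 3 complete repeats
  of a primitive unit, leftmost-greedy within each unit length; totals
  and relative counts (tracts per miRNA, e.g. 2326/2042 = 1.14).
* **Hairpins** — enumeration of contiguous stems (Watson–Crick + G:U
  wobble, no bulges) grown outward from every loop placement (loops
  3–8 nt); tetraloop cascade (loop in motif set / stem ≥ 3 bp / C-G
  closing pair); a pairing-weight stability score; dot-bracket output.
* **Synthetic data** — seeded libraries with plantable motifs, SSR
  tracts, hairpins and terminal bases, exact ground-truth coordinates,
  and certified feature-free background.

## Worked example

The package ships the published table of 50 UGUGU-containing miRNAs as a
plain-text fixture:

```r
library(mirchar)
fa <- system.file("extdata", "iim.fa", package = "mirchar")
report <- run_characterization(run_config(fa))
print(report)
#> miRNA characterization report
#>   input:     .../mirchar/extdata/iim.fa
#>   records:   50 (50 unique)
#>   lengths:   17-24 nt, mode 22 (64%)
#>   content:   A 17%, C 17%, G 31%, U 35%
#>   P/P-rich:  3 purine, 3 pyrimidine (> 70%)
#>   UGUGU:     50 sequences; GU-rich: 50
#>   SSR:       68 tracts (1.36 per miRNA)
#>   hairpins:  47 foldable sequences
```

All 50 records contain the motif (that is what the table collects), and
all are GU-rich — UGUGU is itself a 5-nt alternating tract. Per-record
detectors work on plain strings:

```r
find_ssrs("UGAGUGUGUGUGUGUGAGUGUGU", id = "miR-574-5p")
#>           id unit canonical_class unit_length repeat_count start end tract_length
#> 1 miR-574-5p   GU           GU/UG           2            6     4  15           12
#> 2 miR-574-5p   GU           GU/UG           2            3    18  23            6

hp <- best_hairpin("UGAGGUAGUAGGUUGUGUGGUU", id = "let-7b-5p")
print(hp)
#> hairpin [let-7b-5p]: stem 4 bp, loop 9-12 "UAGG", closing pair G-U, score 4.5
cat(dot_bracket(hp, 22))
#> ....((((....))))......
```

The (GU)6 tract spans complete units only (the trailing G at position 16
is excluded), and the let-7b-5p fold is the maximal contiguous stem over
all loop placements, with the wobble G:U closing pair permitted by
default. `write_report_bundle(report, dir)` writes every table as TSV
plus a JSON manifest, byte-identical across reruns of the same input and
configuration.

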