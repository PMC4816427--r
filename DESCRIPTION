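Package: mirchar
Title: Sequence and Structural Motif Characterization of Mature miRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize libraries of mature microRNA sequences:
    FASTA import with miRBase-style headers, sequence-level deduplication,
    length and nucleotide-composition profiles, positional occupancy
    matrices anchored at either end, purine/pyrimidine-richness
    classification, exact-motif scanning (including the 5'-UGUGU-3'
    interferon-induction motif), alternating-GU tract detection, simple
    sequence repeat (SSR, microsatellite) detection for unit sizes 1-5
    under a minimum-three-repeats rule with library-level relative counts,
    and enumeration of intramolecular stem-loop (hairpin) structures with
    tetraloop classification. A seeded synthetic-library generator with
    plantable features and exact ground truth supports end-to-end testing,
    and a single orchestrator produces a reproducible report bundle.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
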