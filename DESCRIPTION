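Package: altorf
Title: Prediction and Proteogenomic Analysis of Alternative Open Reading Frames
Version: 0.1.0
Authors@R: person("altorf", "developers", role = c("aut", "cre"),
    email = "altorf@example.org")
Description: Enumerates alternative open reading frames (AltORFs) on annotated
    mature mRNAs: AUG-to-stop regions distinct from the annotated coding
    sequence, located in untranslated regions or overlapping the CDS in a
    shifted reading frame. Classifies AltORFs by reading frame and location,
    translates and collapses them to distinct alternative proteins, and
    computes transcriptome-level summary statistics. Builds augmented
    proteomics search databases (reference + alternative + contaminant +
    reversed decoys), performs in-silico tryptic digestion and
    peptide-to-protein mapping with protein grouping, sequence coverage,
    posterior-error-probability filtering, N-terminal-acetylation based
    validation of predicted translation initiation sites, co-expression
    summaries and hypergeometric set-overlap enrichment. Profiles
    cross-species conservation of protein sets via best-hit local alignment
    with Karlin-Altschul E-values. Includes seeded synthetic-data generators
    with planted ground truth and an independent brute-force scanning oracle,
    plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    digest,
    methods,
    stats,
    utils
Suggests:
    readxl,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
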