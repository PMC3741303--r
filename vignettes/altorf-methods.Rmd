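---
title: "Methods: AltORF prediction and proteogenomic evidence"
author: "altorf developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AltORF prediction and proteogenomic evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altorf)
```

## The model

A mature mRNA carries one annotated coding sequence, the reference ORF
(RefORF). The same nucleotide sequence, however, also contains *alternative
open reading frames* (AltORFs): AUG-to-stop intervals that either sit in the
5′ or 3′ untranslated regions, or overlap the CDS in a shifted reading frame.
This package enumerates those AltORFs, translates them into candidate
*alternative proteins*, and supports the downstream proteogenomic questions —
can these proteins be detected from peptide evidence, are their predicted
start sites correct, and are they conserved across species?

An AltORF here is defined purely combinatorially:

* it starts at an AUG (non-AUG initiation is deliberately not modelled;
  reliable prediction of non-AUG starts is not available, and restricting to
  AUG keeps the search space interpretable);
* within each stop-delimited "slot" of a reading frame, only the 5′-most AUG
  opens an ORF — the scanning model of initiation (the *first-AUG rule*);
* it must terminate at an in-frame stop codon **inside** the transcript; a
  reading frame that runs off the 3′ end is not an ORF;
* it must be distinct from the RefORF: the RefORF's own interval is excluded,
  and so is any same-frame ORF sharing the RefORF's stop codon (those are
  N-terminal truncations/extensions of the reference protein, not alternative
  proteins);
* no Kozak-context scoring and no location filtering are applied — an ORF in
  any of the six location classes is retained.

The six location classes are determined by the interval relation between the
AltORF (stop codon included) and the CDS: `utr5`, `utr5_cds`, `cds`,
`cds_utr3`, `utr3`, and `spanning` for an ORF that covers the whole CDS. The
five overlap relations drawn in the field's figures leave the covering case
undefined; we make it an explicit sixth class rather than folding it into a
neighbour.

Reading frames are labelled relative to the RefORF start: `+1` is the
RefORF's own frame, `+2` and `+3` are shifted by one and two nucleotides.
`+1` AltORFs exist — in UTRs, with their own stop codons — and are retained;
the stop-distinctness rule, not the frame, separates them from the reference
protein.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `min_len` | 40 | amino acids, stop excluded | polypeptides shorter than ~40 residues are rarely detectable by shotgun MS; the cut keeps databases tractable |
| `max_missed` | 2 | cleavage sites | standard tryptic search setting |
| peptide length window | 7–40 | amino acids | common search-engine defaults; not printed in the source protocols, therefore configurable |
| `pep_threshold` | 0.05 | posterior error probability | retention requires PEP strictly `< 0.05` — equality rejects |
| `min_unique` | 1 | peptides | small proteins rarely yield more than one usable tryptic fragment |
| `e_cutoff` | 1e-4 | E-value | conservative homology threshold for best-hit searches |
| `lambda`, `K` | 0.267, 0.041 | — | standard gapped Karlin–Altschul constants for BLOSUM62 with gap open 11 / extend 1 |

"Minimum size of 40 codons" is interpreted as **protein length ≥ 40 aa with
the stop codon excluded**; the stop codon is not a residue, and the
discussion of the size cut-off in the source literature is phrased in amino
acids ("shorter than 40 residues").

## Digestion, mapping, and grouping

`digest_tryptic()` implements trypsin/P: cleavage after every K or R,
*including* before proline, with all contiguous unions of up to `max_missed`
internal sites. The zero-missed fragments concatenate exactly to the protein
— this is a tested invariant.

`map_peptides()` requires fully tryptic termini: a peptide's N-side must be
the protein N-terminus, follow a K/R, or start at position 2 of a protein
whose first residue is the initiator methionine (co-translational Met
cleavage); its C-side must end in K/R or at the protein C-terminus.
Semi-tryptic matching is not offered. Proteins whose observed peptide sets
are identical are merged into a single protein group; a peptide is *unique*
when it maps to exactly one group. Decoys (exact sequence reversals, one per
forward entry) are never counted in assignments; a peptide matching only
decoys is excluded and reported as an anomaly.

TIS validation uses N-terminal acetylation, a modification specific to
protein N-termini: the predicted start is supported when an acetylated
peptide begins at position 1, or at position 2 of a Met-initiated protein.

`overlap_enrichment()` is the one-sided hypergeometric upper tail
P(X ≥ k), accumulated in log space from `lchoose` terms so that p-values of
the order 1e-29 are computed without underflow. With the detected-set sizes
129 and 45 sharing 14 proteins over a universe of 83,886 predicted
alternative proteins, the tail evaluates to 3.1957e-29 — numerically
matching the published 3.196e-29, which strongly suggests the database size
itself was the universe of that test. Because the universe is not stated in
the source, the acceptance machinery reports this value alongside the
published one without asserting equality.

## Conservation statistics

`best_hit()` runs Smith–Waterman local alignment (BLOSUM62, affine gaps
11/1, through `Biostrings::pairwiseAlignment` by default; the backend is a
plain function argument so an external engine can substitute). The raw score
is converted to an expectation value with the Karlin–Altschul form
E = K·m·n·exp(−λS) using **raw, unadjusted** sequence lengths — the
effective-length correction of full search engines is deliberately omitted
for transparency, which makes our E-values slightly conservative for short
sequences. Percent identity is computed over aligned columns (gaps
included). One hit per query is kept: best score, ties broken by the
lexicographically smallest subject identifier, and only reported when
E ≤ `e_cutoff`.

## The synthetic world

`generate_transcript()` produces transcripts whose complete AltORF content
is known *by construction*, not by re-scanning. The key device is a
C-lattice background: every third nucleotide position is fixed to `C`, the
rest are uniform over {A,C,G,T}. Every trigram in every frame covers exactly
one lattice position, and neither `ATG` nor any stop codon contains a `C` —
so the background provably contains no start and no stop codon in any frame.
The RefORF and each planted AltORF are then spliced in as explicit
`ATG`/`TAA` trigrams with single-base `C` guards; a short case analysis of
the trigrams overlapping a guarded splice shows no unintended start or stop
can arise. Plants may overlap across frames (biologically realistic) but
never within one frame.

Four class/frame combinations are refused as infeasible: a `+1`-frame AltORF
overlapping the CDS would need an in-frame stop codon inside the annotated
CDS (an invalid annotation) or would share the RefORF's stop codon and thus
be excluded by definition. The planted-recovery acceptance criterion
therefore runs over the 14 feasible combinations and asserts that the four
impossible ones raise errors. Likewise, two plants of the same frame cannot
both cross the CDS on one transcript — the generator searches for a
placement and fails loudly, naming the plant, when geometry forbids one.

What the generator does **not** emulate: realistic codon usage, GC content,
expression levels, sequencing error, or transcript-isoform structure. A
green recovery test establishes that the scanner implements the stated
combinatorial definition exactly; it says nothing about biological
prevalence of AltORFs. The headline census numbers of the human
transcriptome (fractions of mRNAs with AltORFs, median lengths, location
percentages) depend on the actual RefSeq sequence corpus and are therefore
not reproducible from synthetic data; the package recomputes those
statistics from any database table it is given (`summarize_altorf_db()`,
`annotate_altorf_rows()`), and the acceptance suite verifies the computation
path on synthetic tables with planted truth.

`random_transcript()` is intentionally different: fully random content with
an arbitrary (not necessarily well-formed) CDS, used for the
scanner-versus-oracle equivalence property, where hostile inputs are the
point.

## Numerical and design choices

* **Coordinates** are 1-based inclusive everywhere a user sees them, stop
  codons included in ORF intervals. Internally the same convention is kept
  (R strings are 1-based); converting to 0-based half-open internally would
  add conversion layers without benefit in this language.
* **Medians** of integer lengths use the lower median (the smaller central
  order statistic for even counts), so reported medians of integer data are
  integers.
* **Deduplication accessions** are `ALT_` plus the first 12 hex digits of
  the SHA-1 of the protein sequence — deterministic across sessions, no
  registry needed. Instance lists are sorted; output ordering is by
  accession.
* **Ties in scanning** cannot occur (a slot has one first AUG and one stop);
  output is sorted by start position, then frame label.
* **GenBank parsing** accepts single, simple-interval, non-partial CDS
  features only; joined, partial (`<`/`>`), multiple-CDS or zero-CDS records
  are skipped with a logged reason rather than guessed at. This matches the
  one-RefORF-per-mRNA assumption of the whole pipeline.
* **Spreadsheet dialect**: headers of the supplementary-style AltORF
  spreadsheets are mapped case-insensitively through an extensible alias
  table, because the exact header spellings vary between published files.
* The `brute_force_scan()` oracle shares no scanning logic with
  `scan_altorfs()` (per-AUG walk with nearest-stop lookup versus frame-slot
  partition); its translation is cross-checked against
  `Biostrings::translate` in dedicated tests.

## Known limitations

* E-values are not comparable bit-for-bit with any specific external search
  engine (no composition-based statistics, no effective-length correction).
* Search-engine scoring (PEP computation, FDR from decoy counts) is consumed
  from upstream tables, never computed here.
* Minus-strand ORFs, non-AUG starts, and Kozak-context scoring are out of
  scope by design.
* The GenBank reader targets mRNA flat files; genome records with compound
  CDS locations are out of scope (use the FASTA + CDS-table path).
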