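STOP_CODONS <- c("TAA", "TAG", "TGA")

# snapshot of the standard genetic code; avoids repeated namespace fetches in
# per-codon hot loops
GENCODE <- Biostrings::GENETIC_CODE

empty_altorf_frame <- function() {
  data.frame(transcript_accession = character(),
             start = integer(), end = integer(),
             frame_label = character(), location_class = character(),
             protein_sequence = character(), length_aa = integer(),
             stringsAsFactors = FALSE)
}

#' Translate a nucleotide ORF with the standard genetic code
#'
#' The terminal stop codon (if any) is dropped from the protein; any codon
#' containing `N` translates to `X`.
#'
#' @param nt Nucleotide string whose length is a multiple of 3.
#' @return Amino-acid string.
#' @examples
#' translate_orf("ATGGCCTAA")  # "MA"
#' @export
translate_orf <- function(nt) {
  stopifnot(is.character(nt), length(nt) == 1L)
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("ORF length ", n, " is not a multiple of 3")
  if (n == 0L) return("")
  nt <- toupper(nt)
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(GENCODE[codons])
  aa[is.na(aa)] <- "X"
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Reading-frame label of an AltORF relative to the RefORF
#'
#' Frames are labelled from the RefORF's own frame: `+1` when the start
#' positions are congruent modulo 3, `+2` when the AltORF start is shifted by
#' one nucleotide, `+3` when shifted by two.
#'
#' @param alt_start,cds_start 1-based start positions on the same transcript
#'   (vectorised over `alt_start`).
#' @return Character vector over `{"+1","+2","+3"}`.
#' @export
assign_frame <- function(alt_start, cds_start) {
  c("+1", "+2", "+3")[((alt_start - cds_start) %% 3L) + 1L]
}

#' Location class of an AltORF relative to the RefORF
#'
#' Classifies the AltORF interval (stop codon included) against the RefORF
#' interval into one of six classes: entirely 5'UTR (`utr5`), overlapping the
#' 5'UTR and the CDS (`utr5_cds`), contained in the CDS (`cds`), overlapping
#' the CDS and the 3'UTR (`cds_utr3`), entirely 3'UTR (`utr3`), or covering
#' the whole CDS (`spanning`).
#'
#' @param alt_start,alt_end,cds_start,cds_end 1-based inclusive interval
#'   bounds (vectorised over the alt interval).
#' @return Character vector of class labels.
#' @export
classify_location <- function(alt_start, alt_end, cds_start, cds_end) {
  if (any(alt_start == cds_start & alt_end == cds_end))
    stop("internal error: RefORF interval passed to classify_location")
  ifelse(alt_end < cds_start, "utr5",
  ifelse(alt_start > cds_end, "utr3",
  ifelse(alt_start < cds_start & alt_end > cds_end, "spanning",
  ifelse(alt_start < cds_start, "utr5_cds",
  ifelse(alt_end > cds_end, "cds_utr3", "cds")))))
}

#' Scan a transcript for alternative open reading frames
#'
#' Enumerates AltORFs on the sense strand of one mRNA.  In each of the three
#' absolute reading frames the codon sequence is partitioned into
#' stop-delimited slots; within a slot the 5'-most AUG opens at most one
#' candidate ORF running to that slot's stop codon (the first-AUG rule).
#' Candidates are kept when (i) an in-frame stop codon exists within the
#' transcript, (ii) the encoded protein has at least `min_len` residues (stop
#' codon excluded), and (iii) the candidate is neither the RefORF itself nor a
#' same-frame ORF sharing the RefORF's stop codon (an N-terminal variant).
#' No Kozak-context filtering and no location filtering is applied; non-AUG
#' starts and the minus strand are never considered.
#'
#' @param record A [transcript_record].
#' @param min_len Minimum protein length in amino acids (default 40).
#' @return Data frame with one row per AltORF, sorted by `(start,
#'   frame_label)`: columns `transcript_accession`, `start`, `end` (1-based,
#'   stop codon included), `frame_label`, `location_class`,
#'   `protein_sequence`, `length_aa`.
#' @examples
#' tr <- transcript_record("toyA", "TOYA", "ATGAAATGAATGGCCTAA", 1, 9)
#' scan_altorfs(tr, min_len = 2)
#' @export
scan_altorfs <- function(record, min_len = 40L) {
  stopifnot(inherits(record, "transcript_record"))
  min_len <- as.integer(min_len)
  if (is.na(min_len) || min_len < 1L) stop("min_len must be a positive integer")
  seq <- record$sequence
  n <- nchar(seq)
  starts <- ends <- integer(0)
  for (f in 0:2) {
    pos <- seq.int(f + 1L, by = 3L, length.out = (n - f) %/% 3L)
    if (length(pos) == 0L) next
    codons <- substring(seq, pos, pos + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    if (!any(is_stop) || !any(is_atg)) next
    # slot id increments after each stop; a stop codon closes its own slot
    slot <- cumsum(c(0L, is_stop[-length(is_stop)]))
    atg_first <- tapply(which(is_atg), slot[is_atg], min)
    stop_idx <- which(is_stop)
    sl <- as.character(slot[stop_idx])
    a <- atg_first[sl]
    keep <- !is.na(a)
    a <- as.integer(a[keep]); s <- stop_idx[keep]
    keep2 <- a < s  # ATG strictly before the stop codon
    starts <- c(starts, pos[a[keep2]])
    ends <- c(ends, pos[s[keep2]] + 2L)
  }
  if (length(starts) == 0L) return(empty_altorf_frame())

  length_aa <- (ends - starts + 1L) %/% 3L - 1L
  keep <- length_aa >= min_len
  # drop the RefORF itself and same-frame ORFs sharing the RefORF stop codon
  frame <- assign_frame(starts, record$cds_start)
  keep <- keep & !(starts == record$cds_start & ends == record$cds_end)
  keep <- keep & !(frame == "+1" & ends == record$cds_end)
  starts <- starts[keep]; ends <- ends[keep]
  frame <- frame[keep]; length_aa <- length_aa[keep]
  if (length(starts) == 0L) return(empty_altorf_frame())

  cls <- classify_location(starts, ends, record$cds_start, record$cds_end)
  prot <- vapply(seq_along(starts), function(i)
    translate_orf(substr(seq, starts[i], ends[i])), character(1L))
  out <- data.frame(transcript_accession = record$accession,
                    start = starts, end = ends,
                    frame_label = frame, location_class = cls,
                    protein_sequence = prot, length_aa = length_aa,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$frame_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a set of transcripts
#'
#' Applies [scan_altorfs()] to every record and binds the results.
#'
#' @param transcripts List of [transcript_record] objects.
#' @inheritParams scan_altorfs
#' @return Combined AltORF data frame (see [scan_altorfs()]).
#' @export
scan_transcriptome <- function(transcripts, min_len = 40L) {
  res <- lapply(transcripts, scan_altorfs, min_len = min_len)
  out <- do.call(rbind, c(list(empty_altorf_frame()), res))
  rownames(out) <- NULL
  out
}

#' Build the canonical AltORF database table from scan results
#'
#' Joins per-transcript AltORF scans with the RefORF annotation into the
#' nine-column table written by [write_altorf_table()].  All coordinates are
#' 1-based with respect to the first nucleotide of the mRNA; the RefORF is by
#' definition in frame `+1`.
#'
#' @param transcripts List of [transcript_record] objects.
#' @inheritParams scan_altorfs
#' @return Data frame with columns `gene_symbol`, `transcript_accession`,
#'   `ref_frame`, `ref_start`, `ref_stop`, `alt_frame`, `alt_start`,
#'   `alt_stop`, `alt_protein_sequence`.
#' @export
build_altorf_table <- function(transcripts, min_len = 40L) {
  scans <- scan_transcriptome(transcripts, min_len = min_len)
  meta <- data.frame(
    transcript_accession = vapply(transcripts, `[[`, "", "accession"),
    gene_symbol = vapply(transcripts, `[[`, "", "gene_symbol"),
    ref_start = vapply(transcripts, `[[`, 0L, "cds_start"),
    ref_stop = vapply(transcripts, `[[`, 0L, "cds_end"),
    stringsAsFactors = FALSE)
  m <- match(scans$transcript_accession, meta$transcript_accession)
  data.frame(gene_symbol = meta$gene_symbol[m],
             transcript_accession = scans$transcript_accession,
             ref_frame = rep("+1", nrow(scans)),
             ref_start = meta$ref_start[m],
             ref_stop = meta$ref_stop[m],
             alt_frame = scans$frame_label,
             alt_start = scans$start,
             alt_stop = scans$end,
             alt_protein_sequence = scans$protein_sequence,
             stringsAsFactors = FALSE)
}

#' Deterministic accession for an alternative protein sequence
#'
#' `"ALT_"` followed by the first 12 hexadecimal digits of the SHA-1 digest of
#' the amino-acid sequence.  Stable across sessions and platforms; no registry
#' required.
#'
#' @param protein_sequence Character vector of amino-acid sequences.
#' @return Character vector of accessions.
#' @export
alt_accession <- function(protein_sequence) {
  vapply(toupper(protein_sequence), function(s)
    paste0("ALT_", substr(digest::digest(s, algo = "sha1", serialize = FALSE),
                          1L, 12L)),
    character(1L), USE.NAMES = FALSE)
}

#' Collapse AltORF instances to distinct alternative proteins
#'
#' Groups AltORF instances by exact amino-acid sequence equality.  A protein
#' encoded by AltORFs on several transcripts yields a single entry whose
#' `instances` record every (transcript, start, end) encoding it.
#'
#' @param altorfs AltORF data frame from [scan_altorfs()] /
#'   [scan_transcriptome()], or any data frame with columns
#'   `transcript_accession`, `start`, `end`, `protein_sequence`.
#' @return Data frame sorted by `alt_accession` with columns `alt_accession`,
#'   `protein_sequence`, `n_instances`, `n_transcripts`, and a list-column
#'   `instances` of per-protein instance data frames (sorted by transcript,
#'   start).
#' @export
dedupe_distinct <- function(altorfs) {
  if (nrow(altorfs) == 0L)
    return(data.frame(alt_accession = character(),
                      protein_sequence = character(),
                      n_instances = integer(), n_transcripts = integer(),
                      instances = I(list()), stringsAsFactors = FALSE))
  seqs <- toupper(altorfs$protein_sequence)
  groups <- split(seq_len(nrow(altorfs)), seqs)
  prot <- names(groups)
  inst <- lapply(groups, function(i) {
    d <- altorfs[i, c("transcript_accession", "start", "end"), drop = FALSE]
    d <- unique(d)
    d <- d[order(d$transcript_accession, d$start, d$end), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  out <- data.frame(alt_accession = alt_accession(prot),
                    protein_sequence = prot,
                    n_instances = vapply(inst, nrow, 0L),
                    n_transcripts = vapply(inst, function(d)
                      length(unique(d$transcript_accession)), 0L),
                    stringsAsFactors = FALSE)
  out$instances <- I(unname(inst))
  out <- out[order(out$alt_accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}
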