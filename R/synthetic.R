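#' Seeded synthetic transcripts with planted AltORFs
#'
#' Generates one transcript whose complete AltORF content is known by
#' construction, for generator/oracle/scanner triangulation tests.
#'
#' The background is built on a "C-lattice": every position `p` with
#' `p %% 3 == 0` is fixed to `C` and the remaining positions are drawn
#' uniformly from `{A,C,G,T}`.  Because every nucleotide trigram, in every
#' frame, covers exactly one lattice position, and neither `ATG` nor any stop
#' codon contains a `C`, such background contains no start and no stop codon
#' in any reading frame.  The RefORF and each planted AltORF are then spliced
#' in as explicit `ATG` / `TAA` trigrams with single-base `C` guards flanking
#' them, which (by the same trigram argument) cannot create unintended starts
#' or stops.  Plants may overlap across reading frames but never within one;
#' all spliced trigrams are kept disjoint.
#'
#' Four class/frame combinations are geometrically impossible for a
#' well-formed annotation and raise an error: a `+1`-frame AltORF overlapping
#' the CDS (`utr5_cds`, `cds`, `cds_utr3`, `spanning`) would either require an
#' in-frame stop codon inside the annotated CDS or terminate at the RefORF's
#' own stop codon.
#'
#' @param plants Data frame of plant specifications with columns
#'   `location_class`, `frame_label` (`"+1"`, `"+2"`, `"+3"` or 1:3),
#'   `length_aa`, `count`.  May have zero rows (no AltORFs).
#' @param background_len Total transcript length in nucleotides.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param accession,gene_symbol Metadata for the generated record.
#' @return List with elements `record` (a [transcript_record]) and `truth`
#'   (an AltORF data frame in [scan_altorfs()] layout, sorted the same way).
#' @export
generate_transcript <- function(plants, background_len, seed,
                                accession = "SYN1", gene_symbol = "SYNGENE1") {
  L <- as.integer(background_len)
  stopifnot(L >= 60L)
  if (is.null(plants) || nrow(plants) == 0L)
    plants <- data.frame(location_class = character(),
                         frame_label = character(),
                         length_aa = integer(), count = integer())
  plants$frame_label <- normalize_frame_label(plants$frame_label)
  plants$location_class <- as.character(plants$location_class)
  plants$length_aa <- as.integer(plants$length_aa)
  plants$count <- as.integer(plants$count)
  bad <- !plants$location_class %in% LOCATION_CLASSES
  if (any(bad)) stop("unknown location class: ",
                     paste(unique(plants$location_class[bad]), collapse = ", "))
  infeasible <- plants$frame_label == "+1" &
    plants$location_class %in% c("utr5_cds", "cds", "cds_utr3", "spanning")
  if (any(infeasible))
    stop("infeasible plant: a +1-frame AltORF overlapping the CDS would ",
         "require an in-frame stop inside the annotated CDS or share the ",
         "RefORF stop codon (classes: ",
         paste(unique(plants$location_class[infeasible]), collapse = ", "), ")")
  if (any(plants$length_aa < 1L)) stop("length_aa must be >= 1")
  plants <- plants[rep(seq_len(nrow(plants)), plants$count), , drop = FALSE]

  orf_nt <- 3L * (plants$length_aa + 1L)

  # CDS length: big enough for CDS-contained plants, small enough that
  # spanning plants can cover it, multiple of 3
  lb <- 9L
  if (any(plants$location_class == "cds"))
    lb <- max(lb, max(orf_nt[plants$location_class == "cds"]) + 30L)
  if (any(plants$location_class == "utr5_cds")) lb <- max(lb, 15L)
  ub <- if (any(plants$location_class == "spanning"))
    min(orf_nt[plants$location_class == "spanning"]) - 9L else .Machine$integer.max
  if (lb > ub)
    stop("infeasible plant set: spanning AltORF of ",
         min(plants$length_aa[plants$location_class == "spanning"]),
         " aa cannot cover a CDS that must hold a ",
         max(plants$length_aa[plants$location_class == "cds"]), " aa AltORF")
  cds_nt <- min(max(60L, lb), ub)
  cds_nt <- cds_nt - cds_nt %% 3L
  if (cds_nt < lb) cds_nt <- cds_nt + 3L

  # upstream room needed, then CDS, then the rest is 3'UTR
  u5 <- 12L +
    sum(orf_nt[plants$location_class == "utr5"] + 9L) +
    sum(pmax(orf_nt[plants$location_class == "utr5_cds"] - 6L, 0L) + 9L) +
    sum(plants$location_class == "spanning") * 9L
  cds_start <- u5 + 1L
  cds_end <- cds_start + cds_nt - 1L
  u3_need <- 12L +
    sum(orf_nt[plants$location_class == "utr3"] + 9L) +
    sum(orf_nt[plants$location_class == "cds_utr3"] + 9L) +
    sum(pmax(orf_nt[plants$location_class == "spanning"] - cds_nt, 0L) + 9L)
  if (cds_end + u3_need > L)
    stop("background_len too small: need at least ", cds_end + u3_need,
         " nt for the requested plants, got ", L)

  # spliced trigram blocks that must stay disjoint: ATG block [p-1, p+3],
  # stop block [e-2, e+1] (guards included)
  blocks <- list(c(cds_start - 1L, cds_start + 3L),
                 c(cds_end - 2L, cds_end + 1L))
  placements <- data.frame(start = integer(), end = integer(),
                           frame_abs = integer())
  block_clash <- function(a, b) any(vapply(blocks, function(x)
    a <= x[2L] && x[1L] <= b, logical(1L)))
  try_place <- function(p, pe) {
    if (p < 2L || pe > L - 1L) return(FALSE)
    fr <- p %% 3L
    same <- placements$frame_abs == fr &
      placements$start <= pe & p <= placements$end
    if (any(same)) return(FALSE)
    if (block_clash(p - 1L, p + 3L) || block_clash(pe - 2L, pe + 1L))
      return(FALSE)
    TRUE
  }
  commit <- function(p, pe) {
    blocks[[length(blocks) + 1L]] <<- c(p - 1L, p + 3L)
    blocks[[length(blocks) + 1L]] <<- c(pe - 2L, pe + 1L)
    placements[nrow(placements) + 1L, ] <<- c(p, pe, p %% 3L)
  }

  align_up <- function(x, target_mod) x + (target_mod - x) %% 3L

  truth_start <- truth_end <- integer(nrow(plants))
  for (i in seq_len(nrow(plants))) {
    d <- match(plants$frame_label[i], c("+1", "+2", "+3"))
    o <- (cds_start + d - 1L) %% 3L  # required start position mod 3
    nt <- orf_nt[i]
    cls <- plants$location_class[i]
    lims <- switch(cls,
      utr5     = c(2L, cds_start - 3L - nt + 1L),
      utr5_cds = c(cds_start + 6L - nt + 1L, cds_start - 2L),
      cds      = c(cds_start + 5L, cds_end - 4L - nt + 1L),
      cds_utr3 = c(max(cds_start + 5L, cds_end + 4L - nt + 1L), cds_end),
      utr3     = c(cds_end + 3L, L - 1L - nt + 1L),
      spanning = c(2L, cds_start - 5L))
    extra_ok <- switch(cls,
      utr5_cds = function(p) p + nt - 1L >= cds_start + 6L &&
                             p + nt - 1L <= cds_end - 4L,
      spanning = function(p) p + nt - 1L >= cds_end + 4L,
      function(p) TRUE)
    p <- align_up(lims[1L], o)
    placed <- FALSE
    while (p <= lims[2L]) {
      if (extra_ok(p) && try_place(p, p + nt - 1L)) {
        commit(p, p + nt - 1L)
        truth_start[i] <- p
        truth_end[i] <- p + nt - 1L
        placed <- TRUE
        break
      }
      p <- p + 3L
    }
    if (!placed)
      stop("cannot place plant ", i, " (", cls, ", frame ",
           plants$frame_label[i], ", ", plants$length_aa[i],
           " aa) within background_len ", L)
  }

  # assemble: C-lattice background, then splice RefORF and plants with guards
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  base[seq(3L, L, by = 3L)] <- "C"
  splice <- function(p, pe) {
    if (p > 2L) base[p - 1L] <<- "C"
    base[p:(p + 2L)] <<- c("A", "T", "G")
    base[p + 3L] <<- "C"
    base[(pe - 2L):pe] <<- c("T", "A", "A")
    if (pe < L) base[pe + 1L] <<- "C"
  }
  splice(cds_start, cds_end)
  for (i in seq_len(nrow(plants))) splice(truth_start[i], truth_end[i])
  sequence <- paste(base, collapse = "")

  record <- transcript_record(accession, gene_symbol, sequence,
                              cds_start, cds_end)
  truth <- if (nrow(plants) == 0L) empty_altorf_frame() else {
    prot <- vapply(seq_len(nrow(plants)), function(i)
      translate_orf(substr(sequence, truth_start[i], truth_end[i])),
      character(1L))
    data.frame(transcript_accession = accession,
               start = truth_start, end = truth_end,
               frame_label = plants$frame_label,
               location_class = plants$location_class,
               protein_sequence = prot,
               length_aa = plants$length_aa,
               stringsAsFactors = FALSE)
  }
  truth <- truth[order(truth$start, truth$frame_label), , drop = FALSE]
  rownames(truth) <- NULL
  list(record = record, truth = truth)
}

normalize_frame_label <- function(x) {
  x <- as.character(x)
  x[x %in% c("1", "2", "3")] <- paste0("+", x[x %in% c("1", "2", "3")])
  if (!all(x %in% c("+1", "+2", "+3")))
    stop("frame_label must be one of +1, +2, +3")
  x
}

#' Random transcript without planted structure
#'
#' Draws a fully random sequence over `{A,C,G,T}` with a random in-range CDS
#' whose coordinates satisfy the record invariants (the CDS need not be a
#' biologically well-formed ORF).  Used by the oracle-equivalence property
#' tests, where arbitrary sequence content is the point.
#'
#' @param len Sequence length (>= 30).
#' @param seed Integer seed.
#' @param accession Record accession.
#' @return A [transcript_record].
#' @export
random_transcript <- function(len, seed, accession = "RND1") {
  set.seed(seed)
  len <- as.integer(len)
  stopifnot(len >= 30L)
  seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
  cds_start <- sample.int(len %/% 3L, 1L)
  max_codons <- (len - cds_start + 1L) %/% 3L
  n_codons <- sample(2:max_codons, 1L)
  transcript_record(accession, paste0("G", accession), seq,
                    cds_start, cds_start + 3L * n_codons - 1L)
}

#' Independent brute-force AltORF oracle
#'
#' Re-derives the AltORF set of a transcript by direct enumeration, sharing no
#' scanning logic with [scan_altorfs()]: every `ATG` occurrence is walked
#' codon by codon to its nearest in-frame stop; candidates keep only the
#' 5'-most `ATG` per (frame, stop) slot; then the length and RefORF-exclusion
#' filters are applied.  Classification and translation are also recomputed
#' locally (translation through `Biostrings::translate`).
#'
#' @param record A [transcript_record].
#' @param min_len Minimum protein length in amino acids.
#' @return AltORF data frame in the [scan_altorfs()] layout.
#' @export
brute_force_scan <- function(record, min_len = 40L) {
  seq <- record$sequence
  n <- nchar(seq)
  atg <- unlist(gregexpr("ATG", seq, fixed = TRUE))
  atg <- as.integer(atg[atg > 0L])
  stops <- sort(unlist(lapply(c("TAA", "TAG", "TGA"), function(cod) {
    h <- unlist(gregexpr(cod, seq, fixed = TRUE))
    h[h > 0L]
  })))
  stops <- as.integer(stops[stops + 2L <= n])
  if (length(atg) == 0L || length(stops) == 0L) return(empty_altorf_frame())
  # nearest downstream in-frame stop per AUG, one findInterval per frame
  stops_by_frame <- split(stops, stops %% 3L)
  cand_start <- cand_stop <- integer(length(atg))
  for (i in seq_along(atg)) {
    a <- atg[i]
    sf <- stops_by_frame[[as.character(a %% 3L)]]
    if (is.null(sf)) next
    k <- findInterval(a + 2L, sf) + 1L  # first in-frame stop start >= a + 3
    if (k <= length(sf)) { cand_start[i] <- a; cand_stop[i] <- sf[k] + 2L }
  }
  sel0 <- cand_start > 0L
  if (!any(sel0)) return(empty_altorf_frame())
  m <- cbind(cand_start[sel0], cand_stop[sel0])
  # first-AUG rule: smallest start per stop position (frame is implied by it)
  keep <- !duplicated(m[, 2L]) # gregexpr output is ascending, so first wins
  m <- m[keep, , drop = FALSE]

  starts <- m[, 1L]; ends <- m[, 2L]
  aa_len <- (ends - starts + 1L) / 3L - 1L
  sel <- aa_len >= min_len &
    !(starts == record$cds_start & ends == record$cds_end)
  same_frame <- (starts %% 3L) == (record$cds_start %% 3L)
  sel <- sel & !(same_frame & ends == record$cds_end)
  starts <- starts[sel]; ends <- ends[sel]; aa_len <- aa_len[sel]
  if (length(starts) == 0L) return(empty_altorf_frame())

  shift <- (starts - record$cds_start) %% 3L
  frame <- ifelse(shift == 0L, "+1", ifelse(shift == 1L, "+2", "+3"))
  cls <- character(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- ends[i]
    cs <- record$cds_start; ce <- record$cds_end
    cls[i] <-
      if (e < cs) "utr5"
      else if (s > ce) "utr3"
      else if (s >= cs && e <= ce) "cds"
      else if (s < cs && e <= ce) "utr5_cds"
      else if (s >= cs) "cds_utr3"
      else "spanning"
  }
  # local codon-matrix translation (hot loop; equivalence of the package
  # translator with Biostrings::translate is established in its own tests)
  prot <- vapply(seq_along(starts), function(i) {
    ch <- strsplit(substring(seq, starts[i], ends[i] - 3L), NULL)[[1L]]
    cod <- paste0(ch[c(TRUE, FALSE, FALSE)], ch[c(FALSE, TRUE, FALSE)],
                  ch[c(FALSE, FALSE, TRUE)])
    aa <- GENCODE[cod]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1L))
  out <- data.frame(transcript_accession = record$accession,
                    start = starts, end = ends,
                    frame_label = frame, location_class = cls,
                    protein_sequence = prot, length_aa = as.integer(aa_len),
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$frame_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Seeded peptide-observation tables with planted detections
#'
#' Emits a synthetic peptide identification table for a set of proteins in a
#' search space, with planted PEP values (straddling the 0.05 retention
#' threshold as the plan dictates), planted N-terminal acetylation, and
#' log-normal intensities.  The returned truth records which proteins must
#' survive [filter_identifications()] at the default thresholds, assuming
#' each planted protein's peptides are unique to it.
#'
#' @param db_entries Search-space data frame ([build_search_fasta()] layout).
#' @param plan Data frame with columns `protein_id`, `pep` (planted posterior
#'   error probability), and optionally `n_peptides` (default 2),
#'   `acetylated` (plant an N-terminal acetylated peptide; default `FALSE`),
#'   `sample_id` (default `"S1"`).
#' @param seed Integer seed.
#' @param min_len,max_len Peptide length window used when digesting.
#' @return List with `observations` (data frame with columns `sequence`,
#'   `is_nterm_acetylated`, `intensity`, `sample_id`, `pep_score`) and
#'   `truth` (data frame `protein_id`, `expected_retained`).
#' @export
generate_peptide_table <- function(db_entries, plan, seed,
                                   min_len = 7L, max_len = 40L) {
  stopifnot(all(c("protein_id", "pep") %in% names(plan)))
  unknown <- setdiff(plan$protein_id, db_entries$id)
  if (length(unknown))
    stop("plan references unknown protein(s): ",
         paste(unknown, collapse = ", "))
  if (!"n_peptides" %in% names(plan)) plan$n_peptides <- 2L
  if (!"acetylated" %in% names(plan)) plan$acetylated <- FALSE
  if (!"sample_id" %in% names(plan)) plan$sample_id <- "S1"
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(plan))) {
    pid <- plan$protein_id[i]
    prot <- db_entries$sequence[match(pid, db_entries$id)]
    frags <- digest_tryptic(prot, max_missed = 2L,
                            min_len = min_len, max_len = max_len)
    if (nrow(frags) == 0L)
      stop("protein ", pid, " yields no peptide in the ",
           min_len, "-", max_len, " aa window")
    chosen <- frags[frags$n_missed == 0L, , drop = FALSE]
    if (nrow(chosen) == 0L) chosen <- frags
    take <- chosen[sample.int(nrow(chosen),
                              min(plan$n_peptides[i], nrow(chosen))), ,
                   drop = FALSE]
    acet_flags <- rep(FALSE, nrow(take))
    if (isTRUE(plan$acetylated[i])) {
      nt <- frags[frags$start %in% c(1L, 2L), , drop = FALSE]
      if (nrow(nt) == 0L)
        stop("cannot plant an N-terminal peptide for ", pid,
             ": no tryptic fragment starts at position 1 or 2")
      nt <- nt[order(nt$n_missed, nt$start), , drop = FALSE][1L, , drop = FALSE]
      take <- rbind(take, nt)
      acet_flags <- c(acet_flags, TRUE)
    }
    rows[[i]] <- data.frame(
      sequence = take$peptide,
      is_nterm_acetylated = acet_flags,
      intensity = stats::rlnorm(nrow(take), meanlog = 20, sdlog = 1),
      sample_id = plan$sample_id[i],
      pep_score = plan$pep[i],
      stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, rows)
  obs <- unique(obs)
  rownames(obs) <- NULL
  truth <- data.frame(protein_id = plan$protein_id,
                      expected_retained = plan$pep < 0.05,
                      stringsAsFactors = FALSE)
  list(observations = obs, truth = truth)
}
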