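#' Build an augmented proteomics search space with reversed decoys
#'
#' Combines reference, alternative and contaminant protein sets into a single
#' search space and appends one reversed-sequence decoy per forward entry, so
#' the output holds exactly twice as many entries as the forward union.
#' Identifier namespaces must not overlap; decoy identifiers are the forward
#' identifier prefixed with `REV_`.
#'
#' @param reference,alternative,contaminants Data frames with columns `id` and
#'   `sequence` (optional `gene`, `source_transcript` are carried through).
#' @return Data frame with columns `id`, `kind` (`reference`, `alternative`,
#'   `contaminant`, `decoy`), `sequence`, `source_id` (the forward entry a
#'   decoy reverses; `NA` for forward entries), plus `gene` and
#'   `source_transcript` where supplied.
#' @export
build_search_fasta <- function(reference, alternative, contaminants) {
  pick <- function(d, kind) {
    stopifnot(all(c("id", "sequence") %in% names(d)))
    n <- nrow(d)
    data.frame(id = as.character(d$id), kind = rep(kind, n),
               sequence = toupper(d$sequence),
               gene = if ("gene" %in% names(d)) as.character(d$gene)
                      else rep(NA_character_, n),
               source_transcript = if ("source_transcript" %in% names(d))
                 as.character(d$source_transcript)
                 else rep(NA_character_, n),
               stringsAsFactors = FALSE)
  }
  fwd <- rbind(pick(reference, "reference"),
               pick(alternative, "alternative"),
               pick(contaminants, "contaminant"))
  dup <- unique(fwd$id[duplicated(fwd$id)])
  if (length(dup))
    stop("identifier collision across namespaces: ", paste(dup, collapse = ", "))
  dec <- fwd
  dec$id <- paste0("REV_", fwd$id)
  dec$kind <- "decoy"
  dec$sequence <- reverse_sequence(fwd$sequence)
  fwd$source_id <- NA_character_
  dec$source_id <- fwd$id
  out <- rbind(fwd, dec)
  rownames(out) <- NULL
  out
}

#' Reverse protein sequences (decoy construction)
#' @param x Character vector of sequences.
#' @return Character vector with each sequence reversed.
#' @export
reverse_sequence <- function(x) {
  vapply(strsplit(x, NULL), function(ch) paste(rev(ch), collapse = ""),
         character(1L))
}

#' In-silico tryptic digestion (trypsin/P)
#'
#' Cleaves after every K or R, including when the next residue is proline
#' (trypsin/P), and enumerates all contiguous fragment unions with up to
#' `max_missed` internal cleavage sites.  Peptides are length-filtered and
#' reported with 1-based coordinates on the protein.
#'
#' @param protein Amino-acid sequence.
#' @param max_missed Maximum number of missed cleavages (default 2).
#' @param min_len,max_len Peptide length bounds in residues (defaults 7 and
#'   40, the usual search-engine window; set `min_len = 1`,
#'   `max_len = Inf` to disable).
#' @return Data frame with columns `peptide`, `start`, `end`, `n_missed`.
#' @examples
#' digest_tryptic("MKAAARPK", max_missed = 0, min_len = 1)
#' @export
digest_tryptic <- function(protein, max_missed = 2L, min_len = 7L,
                           max_len = 40L) {
  stopifnot(is.character(protein), length(protein) == 1L)
  protein <- toupper(protein)
  n <- nchar(protein)
  if (n == 0L)
    return(data.frame(peptide = character(), start = integer(),
                      end = integer(), n_missed = integer(),
                      stringsAsFactors = FALSE))
  res <- strsplit(protein, NULL)[[1L]]
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n]
  frag_start <- c(1L, cut_after + 1L)
  frag_end <- c(cut_after, n)
  nf <- length(frag_start)
  rows <- list()
  for (i in seq_len(nf)) {
    for (j in i:min(nf, i + max_missed)) {
      len <- frag_end[j] - frag_start[i] + 1L
      if (len < min_len || len > max_len) next
      rows[[length(rows) + 1L]] <- c(frag_start[i], frag_end[j], j - i)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(peptide = character(), start = integer(),
                      end = integer(), n_missed = integer(),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, rows)
  data.frame(peptide = substring(protein, m[, 1L], m[, 2L]),
             start = m[, 1L], end = m[, 2L], n_missed = m[, 3L],
             stringsAsFactors = FALSE)
}

# All tryptic-consistent placements of one peptide inside one protein:
# N-side at the protein N-terminus, after K/R, or at position 2 of an
# initiator-Met protein; C-side ending in K/R or at the protein C-terminus.
tryptic_matches <- function(peptide, protein) {
  hits <- gregexpr(peptide, protein, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  plen <- nchar(peptide)
  n <- nchar(protein)
  ok <- vapply(hits, function(s) {
    nterm_ok <- s == 1L ||
      substr(protein, s - 1L, s - 1L) %in% c("K", "R") ||
      (s == 2L && substr(protein, 1L, 1L) == "M")
    last <- substr(protein, s + plen - 1L, s + plen - 1L)
    cterm_ok <- (s + plen - 1L) == n || last %in% c("K", "R")
    nterm_ok && cterm_ok
  }, logical(1L))
  as.integer(hits[ok])
}

#' Map identified peptides onto a protein search space
#'
#' Assigns every observed peptide to each forward (non-decoy) entry containing
#' it as an exact substring with fully tryptic termini (protein N-terminus,
#' preceded by K/R, or position 2 of an initiator-Met protein; C-terminal
#' residue K/R or protein C-terminus).  Proteins whose assigned peptide sets
#' are identical are merged into one protein group, and each observation is
#' flagged `is_unique` when it maps to exactly one group.  Peptides matching
#' only decoy entries are excluded and reported as anomalies.
#'
#' @param observations Data frame of peptide observations with at least a
#'   `sequence` column (optional `is_nterm_acetylated`, `intensity`,
#'   `sample_id`, `pep_score` are carried through).
#' @param db_entries Search-space data frame from [build_search_fasta()].
#' @return A list of class `peptide_mapping`:
#'   \describe{
#'     \item{observations}{input rows with `assigned_proteins`,
#'       `assigned_groups` (`;`-separated), `is_unique`; decoy-only peptides
#'       removed.}
#'     \item{matches}{one row per (observation, protein, position) with
#'       `obs_row`, `sequence`, `protein_id`, `start`, `end`.}
#'     \item{groups}{protein groups: `group_id`, `members`, `n_members`.}
#'     \item{decoy_only}{character vector of excluded peptide sequences.}
#'   }
#' @export
map_peptides <- function(observations, db_entries) {
  stopifnot("sequence" %in% names(observations))
  fwd <- db_entries[db_entries$kind != "decoy", , drop = FALSE]
  dec <- db_entries[db_entries$kind == "decoy", , drop = FALSE]
  obs <- observations
  obs$sequence <- toupper(obs$sequence)

  match_rows <- list()
  assigned <- vector("list", nrow(obs))
  decoy_only <- character(0)
  for (i in seq_len(nrow(obs))) {
    pep <- obs$sequence[i]
    prot_ids <- character(0)
    for (j in seq_len(nrow(fwd))) {
      ss <- tryptic_matches(pep, fwd$sequence[j])
      if (length(ss)) {
        prot_ids <- c(prot_ids, fwd$id[j])
        match_rows[[length(match_rows) + 1L]] <- data.frame(
          obs_row = i, sequence = pep, protein_id = fwd$id[j],
          start = ss, end = ss + nchar(pep) - 1L, stringsAsFactors = FALSE)
      }
    }
    if (length(prot_ids) == 0L &&
        any(vapply(dec$sequence, function(s)
          length(tryptic_matches(pep, s)) > 0L, logical(1L))))
      decoy_only <- c(decoy_only, pep)
    assigned[[i]] <- prot_ids
  }

  # group proteins by identical assigned-peptide sets
  pepsets <- tapply(
    rep(obs$sequence, lengths(assigned)),
    unlist(assigned),
    function(p) paste(sort(unique(p)), collapse = "\r"))
  groups <- if (length(pepsets)) {
    members <- split(names(pepsets), unname(pepsets))
    members <- lapply(members, sort)
    ids <- vapply(members, paste, "", collapse = ";")
    data.frame(group_id = unname(ids),
               members = unname(ids),
               n_members = vapply(members, length, 0L),
               stringsAsFactors = FALSE)
  } else data.frame(group_id = character(), members = character(),
                    n_members = integer(), stringsAsFactors = FALSE)
  prot_group <- if (length(pepsets)) {
    g <- rep(groups$group_id, groups$n_members)
    names(g) <- unlist(strsplit(groups$members, ";", fixed = TRUE))
    g
  } else character(0)

  obs$assigned_proteins <- vapply(assigned, function(p)
    paste(sort(p), collapse = ";"), character(1L))
  obs$assigned_groups <- vapply(assigned, function(p)
    paste(sort(unique(prot_group[p])), collapse = ";"), character(1L))
  obs$is_unique <- vapply(assigned, function(p)
    length(unique(prot_group[p])) == 1L, logical(1L))

  keep <- !(obs$sequence %in% decoy_only & obs$assigned_proteins == "")
  if (length(decoy_only))
    message("excluded ", length(unique(decoy_only)),
            " peptide(s) matching only decoy entries")
  matches <- if (length(match_rows)) do.call(rbind, match_rows)
             else data.frame(obs_row = integer(), sequence = character(),
                             protein_id = character(), start = integer(),
                             end = integer(), stringsAsFactors = FALSE)
  structure(list(observations = obs[keep, , drop = FALSE],
                 observations_all = obs,  # obs_row in `matches` indexes this
                 matches = matches,
                 groups = groups,
                 protein_group = prot_group,
                 decoy_only = unique(decoy_only)),
            class = "peptide_mapping")
}

#' Sequence coverage from mapped peptides
#'
#' 100 times the fraction of protein residues covered by at least one peptide.
#' Invariant under duplication and reordering of peptides.
#'
#' @param protein Protein sequence (or its integer length).
#' @param peptides Data frame with 1-based `start`, `end` columns.
#' @return Coverage percentage in `[0, 100]`.
#' @export
compute_coverage <- function(protein, peptides) {
  n <- if (is.character(protein)) nchar(protein) else as.integer(protein)
  stopifnot(n >= 1L)
  if (nrow(peptides) == 0L) return(0)
  if (any(peptides$start < 1L | peptides$end > n | peptides$start > peptides$end))
    stop("peptide coordinates out of range for protein of length ", n)
  covered <- logical(n)
  for (i in seq_len(nrow(peptides)))
    covered[peptides$start[i]:peptides$end[i]] <- TRUE
  100 * sum(covered) / n
}

#' Validate a predicted translation initiation site from acetylation evidence
#'
#' N-terminal acetylation marks a true protein N-terminus.  The predicted TIS
#' is supported when some N-terminally acetylated peptide starts at protein
#' position 1, or at position 2 when residue 1 is the (cleaved) initiator
#' methionine.
#'
#' @param protein Protein sequence.
#' @param observations Data frame of peptides mapped onto this protein with
#'   columns `start` and `is_nterm_acetylated`.
#' @return `TRUE` or `FALSE`.
#' @export
validate_tis <- function(protein, observations) {
  if (nrow(observations) == 0L) return(FALSE)
  ac <- observations[observations$is_nterm_acetylated %in% TRUE, , drop = FALSE]
  met <- substr(protein, 1L, 1L) == "M"
  any(ac$start == 1L | (ac$start == 2L & met))
}

#' Per-protein detection summaries
#'
#' Aggregates a [map_peptides()] result into one row per detected forward
#' protein: peptide counts, unique-peptide counts (a peptide is unique when it
#' maps to a single protein group), sequence coverage, TIS support from
#' N-terminal acetylation, the best (minimum) peptide PEP score, mean
#' intensity, and the samples the protein was seen in.
#'
#' @param mapping A `peptide_mapping` from [map_peptides()].
#' @param db_entries The search-space data frame the mapping was built on.
#' @return Data frame with columns `protein_id`, `kind`, `group_id`,
#'   `n_peptides`, `n_unique_peptides`, `coverage_pct`, `tis_supported`,
#'   `pep`, `mean_intensity`, `samples`.
#' @export
summarize_detections <- function(mapping, db_entries) {
  stopifnot(inherits(mapping, "peptide_mapping"))
  obs <- mapping$observations_all
  mt <- mapping$matches
  prot_ids <- sort(unique(mt$protein_id))
  get <- function(col, default) if (col %in% names(obs)) obs[[col]] else default
  pep_score <- get("pep_score", rep(NA_real_, nrow(obs)))
  intensity <- get("intensity", rep(NA_real_, nrow(obs)))
  sample_id <- get("sample_id", rep(NA_character_, nrow(obs)))
  acet <- get("is_nterm_acetylated", rep(FALSE, nrow(obs)))

  out <- lapply(prot_ids, function(pid) {
    m <- mt[mt$protein_id == pid, , drop = FALSE]
    prot_seq <- db_entries$sequence[match(pid, db_entries$id)]
    tis_obs <- data.frame(start = m$start,
                          is_nterm_acetylated = acet[m$obs_row])
    data.frame(
      protein_id = pid,
      kind = db_entries$kind[match(pid, db_entries$id)],
      group_id = unname(mapping$protein_group[pid]),
      n_peptides = length(unique(m$sequence)),
      n_unique_peptides = length(unique(m$sequence[obs$is_unique[m$obs_row]])),
      coverage_pct = compute_coverage(prot_seq, m),
      tis_supported = validate_tis(prot_seq, tis_obs),
      pep = if (all(is.na(pep_score[m$obs_row]))) NA_real_
            else min(pep_score[m$obs_row], na.rm = TRUE),
      mean_intensity = if (all(is.na(intensity[m$obs_row]))) NA_real_
                       else mean(intensity[m$obs_row], na.rm = TRUE),
      samples = paste(sort(unique(stats::na.omit(sample_id[m$obs_row]))),
                      collapse = ";"),
      stringsAsFactors = FALSE)
  })
  if (length(out) == 0L)
    return(data.frame(protein_id = character(), kind = character(),
                      group_id = character(), n_peptides = integer(),
                      n_unique_peptides = integer(), coverage_pct = numeric(),
                      tis_supported = logical(), pep = numeric(),
                      mean_intensity = numeric(), samples = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter detections on PEP and unique-peptide evidence
#'
#' Retains proteins with a posterior error probability strictly below
#' `pep_threshold` (equality rejects) and at least `min_unique` unique
#' peptides.
#'
#' @param summaries Data frame from [summarize_detections()] (columns `pep`,
#'   `n_unique_peptides`).
#' @param pep_threshold PEP cutoff (default 0.05, strict `<`).
#' @param min_unique Minimum number of unique peptides (default 1).
#' @return The retained rows of `summaries`.
#' @export
filter_identifications <- function(summaries, pep_threshold = 0.05,
                                   min_unique = 1L) {
  keep <- !is.na(summaries$pep) & summaries$pep < pep_threshold &
    summaries$n_unique_peptides >= min_unique
  out <- summaries[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes co-expressing a reference and an alternative protein
#'
#' Collapses retained detections by gene and reports the genes for which both
#' a reference and an alternative protein passed [filter_identifications()],
#' with each kind's mean peptide intensity.
#'
#' @param detections Retained detection summaries (columns `protein_id`,
#'   `kind`, `mean_intensity`).
#' @param gene_map Data frame mapping `protein_id` to `gene_symbol`.
#' @return Data frame with columns `gene_symbol`, `mean_intensity_reference`,
#'   `mean_intensity_alternative`, sorted by gene.
#' @export
coexpression_genes <- function(detections, gene_map) {
  d <- detections[detections$kind %in% c("reference", "alternative"), ,
                  drop = FALSE]
  d$gene_symbol <- gene_map$gene_symbol[match(d$protein_id, gene_map$protein_id)]
  d <- d[!is.na(d$gene_symbol), , drop = FALSE]
  out <- lapply(split(d, d$gene_symbol), function(g) {
    if (!all(c("reference", "alternative") %in% g$kind)) return(NULL)
    data.frame(
      gene_symbol = g$gene_symbol[1L],
      mean_intensity_reference =
        mean(g$mean_intensity[g$kind == "reference"], na.rm = TRUE),
      mean_intensity_alternative =
        mean(g$mean_intensity[g$kind == "alternative"], na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(gene_symbol = character(),
                      mean_intensity_reference = numeric(),
                      mean_intensity_alternative = numeric(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric upper-tail overlap enrichment
#'
#' One-sided probability of observing an overlap of at least `k` between a set
#' of size `n_a` and a set of size `n_b` drawn from a universe of size
#' `universe`: `P(X >= k)` for `X ~ Hypergeometric(universe, n_a, n_b)`.  The
#' tail is accumulated in log space from `lchoose` terms, so extreme
#' probabilities (e.g. 1e-29) are computed without underflow.
#'
#' @param n_a,n_b Sizes of the two sets.
#' @param k Observed overlap.
#' @param universe Universe size.
#' @return The p-value.
#' @examples
#' overlap_enrichment(2, 2, 2, 10)  # 1/45
#' @export
overlap_enrichment <- function(n_a, n_b, k, universe) {
  n_a <- as.numeric(n_a); n_b <- as.numeric(n_b)
  k <- as.numeric(k); universe <- as.numeric(universe)
  if (anyNA(c(n_a, n_b, k, universe)) || k < 0 ||
      n_a > universe || n_b > universe || k > min(n_a, n_b))
    stop("inconsistent counts: need 0 <= k <= min(n_a, n_b) <= universe")
  if (k == 0) return(1)
  j <- k:min(n_a, n_b)
  logp <- lchoose(n_a, j) + lchoose(universe - n_a, n_b - j) -
    lchoose(universe, n_b)
  mx <- max(logp)
  min(1, exp(mx + log(sum(exp(logp - mx)))))
}
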