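#' Karlin-Altschul expectation value
#'
#' `E = K * m * n * exp(-lambda * S)` for a local alignment of raw score `S`
#' between sequences of lengths `m` and `n`.  The default gapped constants
#' `lambda = 0.267`, `K = 0.041` are the standard values for BLOSUM62 with
#' affine gap costs 11 (open) / 1 (extend).  Lengths are used unadjusted; no
#' effective-length correction is applied.
#'
#' @param score Raw alignment score (vectorised).
#' @param m,n Query and subject lengths.
#' @param lambda,K Gapped Karlin-Altschul constants.
#' @return Expectation value(s).
#' @export
karlin_altschul_evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  K * m * n * exp(-lambda * score)
}

#' Default local aligner: Smith-Waterman via Biostrings
#'
#' Aligns one query against each subject with `Biostrings::pairwiseAlignment`
#' (`type = "local"`, BLOSUM62, gap open 11, gap extend 1) and returns the
#' standard tabular alignment fields.  Any function with this signature and
#' return layout can replace it through the `aligner` argument of
#' [best_hit()], so an external search engine can substitute.
#'
#' @param query Amino-acid sequence (character scalar).
#' @param subjects Character vector of subject sequences.
#' @return Data frame with one row per subject: `score`, `pident` (percent
#'   identity over aligned columns, gaps included), `length` (alignment
#'   columns), `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`.
#' @export
biostrings_aligner <- function(query, subjects) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(subjects),
    subject = Biostrings::AAString(query),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  # in this call pattern = subjects, subject = the (single) query
  alen <- Biostrings::nchar(aln)
  nid <- Biostrings::nmatch(aln)
  ins <- Biostrings::insertion(aln)
  del <- Biostrings::deletion(aln)
  ngap <- vapply(seq_along(alen), function(i)
    sum(BiocGenerics::width(ins[[i]])) + sum(BiocGenerics::width(del[[i]])),
    numeric(1L))
  data.frame(
    score = Biostrings::score(aln),
    pident = 100 * nid / pmax(alen, 1L),
    length = alen,
    mismatch = alen - nid - ngap,
    gapopen = vapply(seq_along(alen), function(i)
      length(ins[[i]]) + length(del[[i]]), numeric(1L)),
    qstart = BiocGenerics::start(Biostrings::subject(aln)),
    qend = BiocGenerics::end(Biostrings::subject(aln)),
    sstart = BiocGenerics::start(Biostrings::pattern(aln)),
    send = BiocGenerics::end(Biostrings::pattern(aln)),
    stringsAsFactors = FALSE)
}

#' Best cross-species hit for one query protein
#'
#' Aligns `query` against every subject, scores the best local alignment per
#' subject, converts the best raw score to a Karlin-Altschul expectation
#' value, and returns the single best hit (highest score; ties broken by the
#' lexicographically smallest subject id) when its E-value passes the cutoff.
#'
#' @param query Query sequence, optionally named (the name becomes
#'   `query_id`).
#' @param subject_db Named character vector of subject sequences, or a data
#'   frame with `id` and `sequence` columns.
#' @param e_cutoff Expectation-value cutoff (default `1e-4`); hits with
#'   `e_value > e_cutoff` are discarded.
#' @param lambda,K Karlin-Altschul constants, see [karlin_altschul_evalue()].
#' @param aligner Pluggable alignment backend, see [biostrings_aligner()].
#' @param query_id Query identifier (overrides the name of `query`).
#' @return One-row data frame (`query_id`, `subject_id`, `percent_identity`,
#'   `alignment_score`, `e_value`, `alignment_length`, `mismatch`, `gapopen`,
#'   `qstart`, `qend`, `sstart`, `send`, `bit_score`), or `NULL` when no hit
#'   passes the cutoff (including an empty subject set).
#' @export
best_hit <- function(query, subject_db, e_cutoff = 1e-4,
                     lambda = 0.267, K = 0.041,
                     aligner = biostrings_aligner, query_id = NULL) {
  if (is.data.frame(subject_db)) {
    subjects <- subject_db$sequence
    names(subjects) <- subject_db$id
  } else subjects <- subject_db
  if (length(subjects) == 0L) return(NULL)
  if (is.null(names(subjects)))
    names(subjects) <- paste0("subject", seq_along(subjects))
  if (is.null(query_id))
    query_id <- if (!is.null(names(query)) && nzchar(names(query)[1L]))
      names(query)[1L] else "query"
  query <- unname(toupper(query))

  tab <- aligner(query, toupper(unname(subjects)))
  tab$subject_id <- names(subjects)
  tab$e_value <- karlin_altschul_evalue(
    tab$score, nchar(query), nchar(subjects), lambda = lambda, K = K)
  tab <- tab[order(-tab$score, tab$subject_id), , drop = FALSE]
  top <- tab[1L, , drop = FALSE]
  if (top$e_value > e_cutoff) return(NULL)
  data.frame(query_id = query_id,
             subject_id = top$subject_id,
             percent_identity = top$pident,
             alignment_score = top$score,
             e_value = top$e_value,
             alignment_length = top$length,
             mismatch = top$mismatch,
             gapopen = top$gapopen,
             qstart = top$qstart, qend = top$qend,
             sstart = top$sstart, send = top$send,
             bit_score = (lambda * top$score - log(K)) / log(2),
             stringsAsFactors = FALSE)
}

#' Cross-species conservation profile of a protein set
#'
#' Runs [best_hit()] for every query against the subject set and aggregates
#' the passing hits into an identity histogram (1% bins), the median identity,
#' and the conserved-query count.
#'
#' @param query_db,subject_db Protein sets: named character vectors or data
#'   frames with `id` and `sequence`.
#' @inheritParams best_hit
#' @return List of class `conservation_profile`: `hits` (data frame of
#'   per-query best hits), `n_conserved`, `median_identity`, `histogram`
#'   (counts per integer identity bin, identities floored).
#' @export
conservation_profile <- function(query_db, subject_db, e_cutoff = 1e-4,
                                 lambda = 0.267, K = 0.041,
                                 aligner = biostrings_aligner) {
  if (is.data.frame(query_db)) {
    queries <- query_db$sequence
    names(queries) <- query_db$id
  } else queries <- query_db
  hits <- list()
  for (i in seq_along(queries)) {
    h <- best_hit(queries[i], subject_db, e_cutoff = e_cutoff,
                  lambda = lambda, K = K, aligner = aligner,
                  query_id = names(queries)[i])
    if (!is.null(h)) hits[[length(hits) + 1L]] <- h
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(query_id = character(), subject_id = character(),
               percent_identity = numeric(), alignment_score = numeric(),
               e_value = numeric(), stringsAsFactors = FALSE)
  ids <- hits$percent_identity
  histogram <- if (length(ids)) table(factor(pmin(floor(ids), 100),
                                            levels = 0:100)) else NULL
  structure(list(hits = hits,
                 n_conserved = nrow(hits),
                 median_identity = if (length(ids)) stats::median(ids) else NA_real_,
                 histogram = histogram),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("<conservation_profile> ", x$n_conserved, " conserved quer",
      if (x$n_conserved == 1L) "y" else "ies",
      if (!is.na(x$median_identity))
        sprintf(", median identity %.1f%%", x$median_identity) else "",
      "\n", sep = "")
  invisible(x)
}

#' Write best-hit rows as a 12-column tabular alignment report
#'
#' Standard tabular alignment-output column order: query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, E-value, bit score.
#'
#' @param hits Data frame of [best_hit()] rows.
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  out <- data.frame(query = hits$query_id, subject = hits$subject_id,
                    pident = sprintf("%.2f", hits$percent_identity),
                    length = hits$alignment_length,
                    mismatch = hits$mismatch, gapopen = hits$gapopen,
                    qstart = hits$qstart, qend = hits$qend,
                    sstart = hits$sstart, send = hits$send,
                    evalue = format(hits$e_value, digits = 3),
                    bitscore = sprintf("%.1f", hits$bit_score),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
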