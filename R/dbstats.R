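LOCATION_CLASSES <- c("utr5", "utr5_cds", "cds", "cds_utr3", "utr3", "spanning")

# Lower median: for an even number of integer values, the smaller of the two
# central order statistics, so integer inputs give integer medians.
lower_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) return(NA_real_)
  x[(n + 1L) %/% 2L]
}

#' Re-derive AltORF instance annotations from a database table
#'
#' Given canonical AltORF table rows (e.g. read back by
#' [read_altorf_database()]), recomputes the frame label, location class and
#' protein length of every instance from its coordinates, independently of
#' whatever the table claimed.
#'
#' @param rows AltORF table data frame with the canonical columns.
#' @return `rows` with added columns `frame_label`, `location_class`,
#'   `length_aa`.
#' @export
annotate_altorf_rows <- function(rows) {
  rows$frame_label <- assign_frame(rows$alt_start, rows$ref_start)
  rows$location_class <- classify_location(rows$alt_start, rows$alt_stop,
                                           rows$ref_start, rows$ref_stop)
  rows$length_aa <- (rows$alt_stop - rows$alt_start + 1L) %/% 3L - 1L
  rows
}

#' Location-class distribution of AltORF instances
#'
#' Percentages are computed over AltORF instances (table rows), not over
#' distinct proteins, matching the row semantics of the database table.
#'
#' @param altorfs Data frame with a `location_class` column.
#' @return Named numeric vector of percentages over all six location classes
#'   (summing to 100).
#' @export
location_distribution <- function(altorfs) {
  if (nrow(altorfs) == 0L) stop("empty AltORF set: no location distribution")
  cls <- factor(altorfs$location_class, levels = LOCATION_CLASSES)
  if (anyNA(cls)) stop("unknown location class label")
  100 * table(cls) / nrow(altorfs)
}

#' Summarise an AltORF database
#'
#' Computes the transcriptome-level descriptive statistics of an AltORF
#' database: instance and distinct-protein counts, the fraction of mRNAs
#' carrying at least one AltORF, the mean number of AltORFs per mRNA, lower
#' medians of alternative and reference protein lengths, the location-class
#' distribution, a per-mRNA count histogram, and the percentage of genes
#' (transcripts collapsed by gene symbol) with at least one CDS-contained
#' AltORF.
#'
#' @param altorfs AltORF data frame from [scan_transcriptome()] (columns
#'   `transcript_accession`, `location_class`, `protein_sequence`,
#'   `length_aa`).
#' @param transcripts List of [transcript_record] objects, including mRNAs
#'   with zero AltORFs (they enter the denominators).
#' @param ref_proteins Optional reference protein lengths: a numeric vector, a
#'   character vector of sequences, or a data frame with a `sequence` column.
#'   When `NULL`, reference protein lengths are derived from each transcript's
#'   CDS (stop codon excluded).
#' @return A list of class `altorf_db_summary`.
#' @export
summarize_altorf_db <- function(altorfs, transcripts, ref_proteins = NULL) {
  if (length(transcripts) == 0L) stop("empty transcript set")
  accs <- vapply(transcripts, `[[`, "", "accession")
  genes <- vapply(transcripts, `[[`, "", "gene_symbol")
  if (is.null(ref_proteins)) {
    ref_len <- vapply(transcripts, function(tr)
      (tr$cds_end - tr$cds_start + 1L) %/% 3L - 1L, 0L)
  } else if (is.data.frame(ref_proteins)) {
    ref_len <- nchar(ref_proteins$sequence)
  } else if (is.character(ref_proteins)) {
    ref_len <- nchar(ref_proteins)
  } else ref_len <- as.numeric(ref_proteins)

  counts <- table(factor(altorfs$transcript_accession, levels = accs))
  n_with <- sum(counts > 0L)
  hist <- table(counts)

  gene_cds <- character(0)
  if (nrow(altorfs) > 0L) {
    gmap <- genes[match(altorfs$transcript_accession, accs)]
    gene_cds <- unique(gmap[altorfs$location_class == "cds"])
    gene_cds <- gene_cds[!is.na(gene_cds)]
  }

  out <- list(
    n_altorf_instances = nrow(altorfs),
    n_distinct_proteins = nrow(dedupe_distinct(altorfs)),
    n_transcripts_total = length(transcripts),
    n_transcripts_with_altorf = n_with,
    fraction_with_altorf = 100 * n_with / length(transcripts),
    mean_altorfs_per_mrna = nrow(altorfs) / length(transcripts),
    median_alt_length_aa = lower_median(altorfs$length_aa),
    median_ref_length_aa = lower_median(ref_len),
    location_percentages = if (nrow(altorfs) > 0L)
      location_distribution(altorfs) else NULL,
    per_mrna_count_histogram = hist,
    genes_with_cds_contained_altorf =
      100 * length(gene_cds) / length(unique(genes)))
  class(out) <- "altorf_db_summary"
  out
}

#' @export
print.altorf_db_summary <- function(x, ...) {
  cat("AltORF database summary\n")
  cat(sprintf("  AltORF instances:            %d\n", x$n_altorf_instances))
  cat(sprintf("  distinct alternative prots:  %d\n", x$n_distinct_proteins))
  cat(sprintf("  mRNAs (with AltORF / total): %d / %d (%.2f%%)\n",
              x$n_transcripts_with_altorf, x$n_transcripts_total,
              x$fraction_with_altorf))
  cat(sprintf("  mean AltORFs per mRNA:       %.2f\n", x$mean_altorfs_per_mrna))
  cat(sprintf("  median length (alt / ref):   %s / %s aa\n",
              x$median_alt_length_aa, x$median_ref_length_aa))
  if (!is.null(x$location_percentages)) {
    cat("  location classes (%):\n")
    for (cl in names(x$location_percentages))
      cat(sprintf("    %-9s %6.2f\n", cl, x$location_percentages[[cl]]))
  }
  cat(sprintf("  genes with CDS-contained AltORF: %.2f%%\n",
              x$genes_with_cds_contained_altorf))
  invisible(x)
}

#' Write a database summary as a two-column TSV report
#'
#' @param summary An `altorf_db_summary` from [summarize_altorf_db()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_db_summary <- function(summary, path) {
  kv <- c(
    n_altorf_instances = summary$n_altorf_instances,
    n_distinct_proteins = summary$n_distinct_proteins,
    n_transcripts_total = summary$n_transcripts_total,
    n_transcripts_with_altorf = summary$n_transcripts_with_altorf,
    fraction_with_altorf = summary$fraction_with_altorf,
    mean_altorfs_per_mrna = summary$mean_altorfs_per_mrna,
    median_alt_length_aa = summary$median_alt_length_aa,
    median_ref_length_aa = summary$median_ref_length_aa,
    genes_with_cds_contained_altorf = summary$genes_with_cds_contained_altorf)
  if (!is.null(summary$location_percentages)) {
    lp <- as.numeric(summary$location_percentages)
    names(lp) <- paste0("pct_", names(summary$location_percentages))
    kv <- c(kv, lp)
  }
  utils::write.table(
    data.frame(statistic = names(kv), value = unname(kv)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
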