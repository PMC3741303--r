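#' Construct a transcript record
#'
#' A `transcript_record` holds one mature mRNA: its nucleotide sequence and the
#' 1-based inclusive coordinates of the annotated reference ORF (RefORF),
#' including both the start codon's first base (`cds_start`) and the stop
#' codon's last base (`cds_end`).
#'
#' The sequence is uppercased and `U` is normalised to `T` on construction, so
#' downstream code works over a single canonical alphabet `{A,C,G,T,N}`.
#' Records whose CDS length is not a multiple of 3 are rejected as partial.
#'
#' @param accession Transcript accession, e.g. `"NM_001100167"`.
#' @param gene_symbol Gene symbol the transcript belongs to.
#' @param sequence Nucleotide sequence (character scalar; RNA accepted).
#' @param cds_start,cds_end 1-based inclusive RefORF coordinates.
#' @param version Optional accession version string.
#' @return An object of class `transcript_record`.
#' @examples
#' tr <- transcript_record("T1", "GENE1", "ATGGCCTAAGGG", 1, 9)
#' tr$cds_end
#' @export
transcript_record <- function(accession, gene_symbol, sequence,
                              cds_start, cds_end, version = NULL) {
  stopifnot(is.character(accession), length(accession) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- chartr("u", "U", toupper(sequence))
  sequence <- chartr("U", "T", sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence of '", accession, "' contains characters outside {A,C,G,T,N,U}")
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  n <- nchar(sequence)
  if (is.na(cds_start) || is.na(cds_end) || cds_start < 1L ||
      cds_start >= cds_end || cds_end > n)
    stop("invalid CDS coordinates [", cds_start, ", ", cds_end,
         "] for '", accession, "' (sequence length ", n, ")")
  if ((cds_end - cds_start + 1L) %% 3L != 0L)
    stop("partial CDS: length of [", cds_start, ", ", cds_end,
         "] in '", accession, "' is not a multiple of 3")
  structure(
    list(accession = accession,
         version = if (is.null(version)) NA_character_ else as.character(version),
         gene_symbol = as.character(gene_symbol),
         sequence = sequence,
         cds_start = cds_start,
         cds_end = cds_end),
    class = "transcript_record")
}

#' @export
print.transcript_record <- function(x, ...) {
  cat("<transcript_record> ", x$accession,
      if (!is.na(x$version)) paste0(".", x$version) else "",
      "  gene=", x$gene_symbol,
      "  length=", nchar(x$sequence),
      "  CDS=[", x$cds_start, ", ", x$cds_end, "]\n", sep = "")
  invisible(x)
}

skip_log <- function(accession = character(), reason = character()) {
  data.frame(accession = as.character(accession),
             reason = as.character(reason),
             stringsAsFactors = FALSE)
}

#' Read annotated mRNA records from a GenBank flat file
#'
#' Parses a GenBank flat file of mRNA records and returns one
#' [transcript_record] per record carrying a single, unambiguous, non-partial
#' `CDS` feature.  Records with zero CDS features, with more than one CDS
#' feature, with a joined (`join(...)`) or partial (`<`/`>`) CDS location, or
#' whose CDS length is not a multiple of 3 are skipped; skipped records are
#' collected in the `"skipped"` attribute of the result with a reason string.
#'
#' Only the feature table and the ORIGIN sequence are consumed; a `/gene=`
#' qualifier on the CDS feature (falling back to the `gene` feature, then to
#' the accession) provides the gene symbol.
#'
#' @param path Path to a GenBank flat file.
#' @return A list of [transcript_record] objects with attribute `"skipped"`
#'   (a data frame with columns `accession`, `reason`).  Zero usable records
#'   yield an empty list plus a warning.
#' @export
read_genbank_transcripts <- function(path) {
  if (!file.exists(path)) stop("cannot read GenBank file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    warning("no records in ", path)
    return(structure(list(), skipped = skip_log()))
  }
  term <- grep("^//\\s*$", lines)
  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0L) stop("not a GenBank flat file (no LOCUS line): ", path)
  # pair each LOCUS with the next record terminator
  recs <- lapply(starts, function(s) {
    e <- term[term > s]
    e <- if (length(e)) e[1L] else length(lines)
    lines[s:e]
  })
  out <- list()
  skipped <- skip_log()
  for (rl in recs) {
    parsed <- tryCatch(parse_genbank_record(rl), error = function(e) e)
    if (inherits(parsed, "error")) {
      acc <- sub("^LOCUS\\s+(\\S+).*$", "\\1", rl[1L])
      skipped <- rbind(skipped, skip_log(acc, conditionMessage(parsed)))
    } else {
      out[[length(out) + 1L]] <- parsed
    }
  }
  if (length(out) == 0L) warning("no usable mRNA records in ", path)
  attr(out, "skipped") <- skipped
  out
}

# Parse one GenBank record (vector of lines) or stop() with a skip reason.
parse_genbank_record <- function(rl) {
  acc_line <- grep("^ACCESSION", rl, value = TRUE)
  accession <- if (length(acc_line)) sub("^ACCESSION\\s+(\\S+).*$", "\\1", acc_line[1L])
               else sub("^LOCUS\\s+(\\S+).*$", "\\1", rl[1L])
  ver_line <- grep("^VERSION", rl, value = TRUE)
  version <- NA_character_
  if (length(ver_line)) {
    v <- sub("^VERSION\\s+(\\S+).*$", "\\1", ver_line[1L])
    if (grepl("\\.", v)) version <- sub("^[^.]*\\.", "", v)
  }

  feat_i <- grep("^FEATURES", rl)
  orig_i <- grep("^ORIGIN", rl)
  if (!length(feat_i)) stop("no FEATURES table")
  if (!length(orig_i)) stop("no ORIGIN sequence")
  feat <- rl[(feat_i[1L] + 1L):(orig_i[1L] - 1L)]

  # feature keys start at column 6; qualifiers/continuations at column 22
  key_i <- grep("^\\s{5}\\S", feat)
  keys <- sub("^\\s{5}(\\S+).*$", "\\1", feat[key_i])
  cds_i <- key_i[keys == "CDS"]
  if (length(cds_i) == 0L) stop("no CDS feature")
  if (length(cds_i) > 1L) stop("multiple CDS features")

  # location may continue over lines until the first qualifier line
  blk_end <- if (any(key_i > cds_i)) min(key_i[key_i > cds_i]) - 1L else length(feat)
  blk <- feat[cds_i:blk_end]
  qual_start <- grep("^\\s+/", blk)
  loc_lines <- if (length(qual_start)) blk[1:(qual_start[1L] - 1L)] else blk
  loc <- gsub("\\s", "", paste(sub("^\\s{5}CDS\\s+", "", loc_lines), collapse = ""))
  if (grepl("[<>]", loc)) stop("partial CDS location")
  if (grepl("join|complement|order", loc)) stop("compound CDS location")
  m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1L]]
  if (length(m) != 3L) stop("unparseable CDS location: ", loc)
  cds_start <- as.integer(m[2L]); cds_end <- as.integer(m[3L])

  gene <- NA_character_
  g <- grep("/gene=\"([^\"]*)\"", blk, value = TRUE)
  if (!length(g)) g <- grep("/gene=\"([^\"]*)\"", feat, value = TRUE)
  if (length(g)) gene <- sub(".*/gene=\"([^\"]*)\".*", "\\1", g[1L])
  if (is.na(gene)) gene <- accession

  seq_lines <- rl[(orig_i[1L] + 1L):length(rl)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("empty ORIGIN sequence")

  transcript_record(accession, gene, sequence, cds_start, cds_end,
                    version = version)
}

#' Read transcripts from a FASTA file plus a CDS coordinate table
#'
#' Download-free input path: a plain FASTA of mRNA sequences joined by
#' accession to a tab-separated table with columns `accession`, `gene_symbol`,
#' `cds_start`, `cds_end` (1-based inclusive).  Accessions present on only one
#' side, and records failing coordinate validation, are skipped and logged.
#'
#' @param fasta Path to a FASTA file; the first whitespace-delimited token of
#'   each header is the accession.
#' @param cds_table Path to the TSV coordinate table.
#' @return As [read_genbank_transcripts()]: list of records with a `"skipped"`
#'   attribute.
#' @export
read_fasta_with_cds_table <- function(fasta, cds_table) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  tab <- utils::read.delim(cds_table, stringsAsFactors = FALSE,
                           na.strings = ".", check.names = FALSE)
  need <- c("accession", "gene_symbol", "cds_start", "cds_end")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("CDS table is missing column(s): ", paste(miss, collapse = ", "))
  out <- list()
  skipped <- skip_log()
  for (i in seq_len(nrow(tab))) {
    acc <- tab$accession[i]
    if (!acc %in% names(seqs)) {
      skipped <- rbind(skipped, skip_log(acc, "accession absent from FASTA"))
      next
    }
    rec <- tryCatch(
      transcript_record(acc, tab$gene_symbol[i],
                        as.character(seqs[[acc]]),
                        tab$cds_start[i], tab$cds_end[i]),
      error = function(e) e)
    if (inherits(rec, "error")) {
      skipped <- rbind(skipped, skip_log(acc, conditionMessage(rec)))
    } else out[[length(out) + 1L]] <- rec
  }
  extra <- setdiff(names(seqs), tab$accession)
  if (length(extra))
    skipped <- rbind(skipped, skip_log(extra, "accession absent from CDS table"))
  attr(out, "skipped") <- skipped
  out
}

altorf_table_columns <- c("gene_symbol", "transcript_accession",
                          "ref_frame", "ref_start", "ref_stop",
                          "alt_frame", "alt_start", "alt_stop",
                          "alt_protein_sequence")

# Case-insensitive header aliases for the supplementary-spreadsheet dialect.
# The exact headers of the published spreadsheets are not fixed, so each
# canonical column accepts several plausible spellings; users can extend this.
default_altorf_aliases <- function() {
  list(
    gene_symbol = c("gene_symbol", "gene", "gene name", "gene_name", "symbol"),
    transcript_accession = c("transcript_accession", "accession",
                             "mrna accession", "mrna_accession",
                             "accession number", "transcript"),
    ref_frame = c("ref_frame", "reforf frame", "reference frame", "ref frame"),
    ref_start = c("ref_start", "reforf start", "reference start", "cds start",
                  "cds_start", "ref start"),
    ref_stop = c("ref_stop", "reforf stop", "reference stop", "cds stop",
                 "cds_end", "ref stop", "ref_end"),
    alt_frame = c("alt_frame", "altorf frame", "alternative frame", "alt frame",
                  "frame"),
    alt_start = c("alt_start", "altorf start", "alternative start", "alt start"),
    alt_stop = c("alt_stop", "altorf stop", "alternative stop", "alt stop",
                 "alt_end"),
    alt_protein_sequence = c("alt_protein_sequence", "protein sequence",
                             "alternative protein sequence", "protein",
                             "predicted amino acid sequence", "aa sequence"))
}

map_aliased_columns <- function(found, aliases) {
  key <- tolower(trimws(found))
  out <- character(length(aliases))
  names(out) <- names(aliases)
  for (col in names(aliases)) {
    hit <- which(key %in% tolower(aliases[[col]]))
    if (length(hit) == 0L)
      stop("missing mandatory column '", col, "' (aliases: ",
           paste(aliases[[col]], collapse = ", "), ")")
    out[col] <- found[hit[1L]]
  }
  out
}

#' Read an AltORF database table
#'
#' Two dialects are supported.  `"tsv"` is this package's own tab-separated
#' layout as emitted by [write_altorf_table()].  `"supplementary_xlsx"` reads a
#' spreadsheet in the layout of published AltORF databases: the first sheet
#' holds the AltORF table (headers mapped case-insensitively through an alias
#' table), and an optional second sheet holds cross-species conservation rows.
#' Reading spreadsheets requires the `readxl` package.
#'
#' @param path File to read.
#' @param dialect `"tsv"` or `"supplementary_xlsx"`.
#' @param aliases Named list of header aliases per canonical column
#'   (see `altorf:::default_altorf_aliases`).
#' @return A data frame of AltORF rows with the canonical columns
#'   `gene_symbol`, `transcript_accession`, `ref_frame`, `ref_start`,
#'   `ref_stop`, `alt_frame`, `alt_start`, `alt_stop`,
#'   `alt_protein_sequence`; protein sequences are uppercased.  For the
#'   spreadsheet dialect, a conservation sheet (if present) is attached as
#'   attribute `"conservation"`.
#' @export
read_altorf_database <- function(path,
                                 dialect = c("tsv", "supplementary_xlsx"),
                                 aliases = default_altorf_aliases()) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    # read everything as character: frame labels like "+1" must not be
    # coerced to integers; coordinates are converted explicitly below
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".",
                             check.names = FALSE, colClasses = "character")
    cols <- map_aliased_columns(names(tab), aliases)
    tab <- tab[, unname(cols), drop = FALSE]
    names(tab) <- names(cols)
  } else {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("dialect 'supplementary_xlsx' requires the 'readxl' package")
    sheets <- readxl::excel_sheets(path)
    raw <- as.data.frame(readxl::read_excel(path, sheet = 1L),
                         stringsAsFactors = FALSE)
    cols <- map_aliased_columns(names(raw), aliases)
    tab <- raw[, unname(cols), drop = FALSE]
    names(tab) <- names(cols)
    if (length(sheets) >= 2L) {
      cons <- as.data.frame(readxl::read_excel(path, sheet = 2L),
                            stringsAsFactors = FALSE)
      attr(tab, "conservation") <- cons
    }
  }
  for (col in c("ref_start", "ref_stop", "alt_start", "alt_stop"))
    tab[[col]] <- as.integer(tab[[col]])
  tab$alt_protein_sequence <- toupper(as.character(tab$alt_protein_sequence))
  message("read ", nrow(tab), " AltORF rows from ", path)
  tab
}

#' Write an AltORF database table
#'
#' Writes the canonical tab-separated layout (UTF-8, header row, `.` for
#' missing values) that [read_altorf_database()] reads back losslessly.
#'
#' @param rows Data frame with the canonical AltORF columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_altorf_table <- function(rows, path) {
  miss <- setdiff(altorf_table_columns, names(rows))
  if (length(miss))
    stop("AltORF table is missing column(s): ", paste(miss, collapse = ", "))
  out <- rows[, altorf_table_columns, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Protein FASTA with structured headers
#'
#' Protein sets move through the toolkit as data frames with columns `id`,
#' `kind` (`reference`, `alternative`, `contaminant` or `decoy`), `sequence`,
#' and optional `gene` and `source_transcript`.  On disk they are FASTA files
#' whose headers carry `id|kind|gene|source-transcript` with `.` for missing
#' fields; sequences are uppercased on write.
#'
#' @param entries Data frame of protein entries.
#' @param path File to write to / read from.
#' @return `write_protein_fasta` returns `path` invisibly;
#'   `read_protein_fasta` returns the entries data frame.
#' @export
write_protein_fasta <- function(entries, path) {
  stopifnot(all(c("id", "kind", "sequence") %in% names(entries)))
  dup <- unique(entries$id[duplicated(entries$id)])
  if (length(dup))
    stop("duplicate identifiers on write: ", paste(dup, collapse = ", "))
  gene <- if ("gene" %in% names(entries)) entries$gene else NA
  src <- if ("source_transcript" %in% names(entries)) entries$source_transcript else NA
  dot <- function(x) ifelse(is.na(x) | x == "", ".", as.character(x))
  headers <- paste(entries$id, entries$kind, dot(gene), dot(src), sep = "|")
  set <- Biostrings::AAStringSet(toupper(entries$sequence))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_protein_fasta
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L)
    return(data.frame(id = character(), kind = character(),
                      sequence = character(), gene = character(),
                      source_transcript = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(names(set), "|", fixed = TRUE)
  field <- function(i) vapply(parts, function(p)
    if (length(p) >= i) p[i] else ".", character(1L))
  undot <- function(x) ifelse(x == ".", NA_character_, x)
  data.frame(id = field(1L),
             kind = field(2L),
             sequence = unname(as.character(set)),
             gene = undot(field(3L)),
             source_transcript = undot(field(4L)),
             row.names = NULL,
             stringsAsFactors = FALSE)
}
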