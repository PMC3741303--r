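test_that("transcript_record normalises and validates", {
  tr <- transcript_record("T1", "G1", "augGCCuaaGGG", 1, 9)
  expect_equal(tr$sequence, "ATGGCCTAAGGG")
  expect_s3_class(tr, "transcript_record")

  expect_error(transcript_record("T1", "G1", "ATGQQQTAA", 1, 9), "characters")
  expect_error(transcript_record("T1", "G1", "ATGGCCTAA", 0, 9), "invalid CDS")
  expect_error(transcript_record("T1", "G1", "ATGGCCTAA", 1, 12), "invalid CDS")
  expect_error(transcript_record("T1", "G1", "ATGGCCTAAG", 1, 10), "partial CDS")
})

test_that("GenBank reader keeps usable records and logs skips", {
  set.seed(7)
  recs <- list(toy_a(), toy_b())
  path <- withr::local_tempfile(fileext = ".gb")

  # record 2 lacking a CDS feature
  write_genbank_fixture(recs, path, drop_cds = 2L)
  got <- read_genbank_transcripts(path)
  expect_length(got, 1L)
  expect_equal(got[[1L]]$accession, "toyA")
  sk <- attr(got, "skipped")
  expect_equal(nrow(sk), 1L)
  expect_match(sk$reason, "no CDS")

  # non-multiple-of-3 CDS is a partial CDS
  write_genbank_fixture(recs, path, cds_override = list(NULL, "1..20"))
  got <- read_genbank_transcripts(path)
  expect_length(got, 1L)
  expect_match(attr(got, "skipped")$reason, "partial|multiple of 3")

  # explicit partials and compound locations are skipped
  write_genbank_fixture(recs, path, cds_override = list("<1..9", "join(1..6,10..15)"))
  expect_warning(got <- read_genbank_transcripts(path), "no usable")
  expect_length(got, 0L)
  expect_equal(nrow(attr(got, "skipped")), 2L)

  # full round trip of sequence, coordinates and gene symbol
  write_genbank_fixture(recs, path)
  got <- read_genbank_transcripts(path)
  expect_equal(vapply(got, `[[`, "", "gene_symbol"), c("TOYA", "TOYB"))
  expect_equal(vapply(got, `[[`, "", "sequence"),
               vapply(recs, `[[`, "", "sequence"))
  expect_equal(vapply(got, `[[`, 0L, "cds_end"), c(9L, 15L))

  expect_error(read_genbank_transcripts(file.path(tempdir(), "nope.gb")),
               "cannot read")
})

test_that("FASTA + CDS-table input path joins, skips, and validates", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(">T1 some description", "ATGGCCTAAGGG",
               ">T2", "ATGAAATAA"), fa)

  write.table(data.frame(accession = "T1", gene_symbol = "geneA",
                         cds_start = 1, cds_end = 9),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_fasta_with_cds_table(fa, tsv)
  expect_length(got, 1L)
  expect_equal(got[[1L]]$cds_end, 9L)
  expect_true("T2" %in% attr(got, "skipped")$accession)

  # coordinates beyond the sequence are rejected with a logged reason
  write.table(data.frame(accession = "T1", gene_symbol = "geneA",
                         cds_start = 1, cds_end = 24),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_fasta_with_cds_table(fa, tsv)
  expect_length(got, 0L)
  expect_match(attr(got, "skipped")$reason[1L], "invalid CDS")

  writeLines(c("accession\tgene_symbol\tcds_start", "T1\tgeneA\t1"), tsv)
  expect_error(read_fasta_with_cds_table(fa, tsv), "cds_end")
})

test_that("AltORF table round-trips losslessly, including random content", {
  set.seed(42)
  n <- 25L
  rows <- data.frame(
    gene_symbol = paste0("G", sample(5, n, TRUE)),
    transcript_accession = paste0("NM_", sample(1e5, n)),
    ref_frame = "+1",
    ref_start = sample(100, n), ref_stop = sample(1000, n) + 200L,
    alt_frame = sample(c("+1", "+2", "+3"), n, TRUE),
    alt_start = sample(500, n), alt_stop = sample(500, n) + 600L,
    alt_protein_sequence = vapply(sample(10:50, n, TRUE), rnd_aa, ""),
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_altorf_table(rows, path)
  expect_message(back <- read_altorf_database(path), "25 AltORF rows")
  expect_equal(back, rows)

  expect_error(write_altorf_table(rows[, -3L], path), "ref_frame")
})

test_that("supplementary-dialect headers are alias-mapped case-insensitively", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("Gene Name", "Accession Number", "ref_frame",
                     "CDS Start", "CDS Stop", "Frame",
                     "AltORF Start", "AltORF Stop",
                     "Predicted Amino Acid Sequence", sep = "\t"),
               paste("g1", "NM_1", "+1", "10", "30", "+2", "2", "7",
                     "mkle", sep = "\t")), path)
  rows <- suppressMessages(read_altorf_database(path))
  expect_equal(names(rows), altorf:::altorf_table_columns)
  expect_equal(rows$alt_protein_sequence, "MKLE")  # uppercased on read
  expect_equal(rows$alt_start, 2L)

  writeLines(c("gene_symbol\tfoo", "g1\t1"), path)
  expect_error(read_altorf_database(path), "transcript_accession")
})

test_that("protein FASTA round-trips entries, kinds and metadata", {
  set.seed(3)
  entries <- data.frame(
    id = paste0("P", 1:5),
    kind = c("reference", "alternative", "alternative", "contaminant", "decoy"),
    sequence = vapply(rep(20, 5), rnd_aa, ""),
    gene = c("G1", NA, "G2", NA, NA),
    source_transcript = c("NM_1", "NM_2", NA, NA, NA),
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_protein_fasta(entries, path)
  back <- read_protein_fasta(path)
  expect_equal(back, entries)

  # normalization and duplicate guard
  low <- data.frame(id = "x", kind = "reference", sequence = "mkle")
  write_protein_fasta(low, path)
  expect_equal(read_protein_fasta(path)$sequence, "MKLE")
  expect_error(write_protein_fasta(rbind(low, low), path), "duplicate")

  # empty set still yields a readable file
  write_protein_fasta(entries[0, ], path)
  expect_equal(nrow(read_protein_fasta(path)), 0L)
})
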