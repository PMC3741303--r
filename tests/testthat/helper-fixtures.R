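# Shared fixture builders. Everything is generated in code at test time; no
# binary fixtures are stored.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

rnd_aa <- function(n, no_met = FALSE) {
  pool <- if (no_met) setdiff(AA20, "M") else AA20
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

toy_a <- function() transcript_record("toyA", "TOYA", "ATGAAATGAATGGCCTAA", 1, 9)
toy_b <- function() transcript_record("toyB", "TOYB", "ATGGATGCAGTGTGAATAGG", 1, 15)

# Minimal GenBank flat-file writer for fixtures (60 bases/line, 10-base
# groups, 1-based position numbers), mirroring the real dialect closely
# enough for parser tests.
write_genbank_fixture <- function(records, path, cds_override = NULL,
                                  drop_cds = integer(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records)) {
    r <- records[[i]]
    n <- nchar(r$sequence)
    writeLines(sprintf("LOCUS       %s             %d bp    mRNA    linear   PRI 01-JAN-2020",
                       r$accession, n), con)
    writeLines(sprintf("DEFINITION  synthetic fixture transcript %s.", r$accession), con)
    writeLines(sprintf("ACCESSION   %s", r$accession), con)
    writeLines(sprintf("VERSION     %s.1", r$accession), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", n), con)
    writeLines("                     /organism=\"synthetic construct\"", con)
    writeLines(sprintf("     gene            1..%d", n), con)
    writeLines(sprintf("                     /gene=\"%s\"", r$gene_symbol), con)
    if (!i %in% drop_cds) {
      loc <- if (!is.null(cds_override) && !is.null(cds_override[[i]]))
        cds_override[[i]] else sprintf("%d..%d", r$cds_start, r$cds_end)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf("                     /gene=\"%s\"", r$gene_symbol), con)
      writeLines("                     /codon_start=1", con)
      writeLines(sprintf("                     /product=\"%s protein\"", r$gene_symbol), con)
    }
    writeLines("ORIGIN      ", con)
    s <- tolower(r$sequence)
    for (off in seq(1L, n, by = 60L)) {
      chunk <- substr(s, off, min(off + 59L, n))
      groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                          pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      writeLines(sprintf("%9d %s", off, paste(groups, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

# Synthetic stand-in for a long mRNA whose 3'UTR hosts a ~95-codon AltORF
# (the AltMRVI1 geometry); purely generated, no real sequence content.
synthetic_mrvi1_like <- function(seed = 20130812) {
  plants <- data.frame(location_class = "utr3", frame_label = "+2",
                       length_aa = 94L, count = 1L)
  generate_transcript(plants, background_len = 2400L, seed = seed,
                      accession = "SYN_MRVI1_LIKE", gene_symbol = "MRVI1SYN")
}

make_protein_set <- function(ids, lens, seed = NULL, prefix_met = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(id = ids,
             sequence = vapply(lens, function(n)
               paste0(if (prefix_met) "M" else "", rnd_aa(n, no_met = TRUE)),
               character(1L)),
             stringsAsFactors = FALSE)
}
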