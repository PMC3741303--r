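test_that("build_search_fasta doubles the forward set with reversed decoys", {
  set.seed(1)
  ref <- make_protein_set(paste0("R", 1:2), c(30, 40))
  alt <- make_protein_set(paste0("A", 1:3), c(20, 25, 30))
  cont <- make_protein_set("C1", 35)
  db <- build_search_fasta(ref, alt, cont)
  expect_equal(nrow(db), 12L)
  expect_equal(sum(db$kind == "decoy"), 6L)
  expect_equal(db$sequence[db$id == "REV_R1"],
               reverse_sequence(ref$sequence[1]))
  # reversal is an involution
  expect_equal(reverse_sequence(reverse_sequence(db$sequence)), db$sequence)
  expect_equal(reverse_sequence("MKAV"), "VAKM")

  expect_error(build_search_fasta(ref, setNames(ref, names(alt))[1, ], cont),
               "collision")
})

test_that("tryptic digestion enumerates fragments and missed cleavages", {
  d0 <- digest_tryptic("MKAAARPK", max_missed = 0, min_len = 1)
  expect_setequal(d0$peptide, c("MK", "AAAR", "PK"))  # trypsin/P cuts before P
  d2 <- digest_tryptic("MKAAARPK", max_missed = 2, min_len = 1)
  expect_setequal(d2$peptide,
                  c("MK", "AAAR", "PK", "MKAAAR", "AAARPK", "MKAAARPK"))
  expect_equal(d2$n_missed[d2$peptide == "MKAAARPK"], 2L)
  # no cleavage site: whole protein, subject to the length filter
  expect_equal(digest_tryptic("MAAAW", min_len = 1)$peptide, "MAAAW")
  expect_equal(nrow(digest_tryptic("MAAAW", min_len = 7)), 0L)
})

test_that("zero-missed fragments concatenate back to the protein", {
  set.seed(33)
  for (i in 1:25) {
    prot <- rnd_aa(sample(20:200, 1))
    d <- digest_tryptic(prot, max_missed = 0, min_len = 1, max_len = Inf)
    expect_equal(paste(d$peptide, collapse = ""), prot)
    expect_equal(d$start[1], 1L)
    expect_equal(d$end[nrow(d)], nchar(prot))
  }
})

test_that("map_peptides assigns tryptic matches, groups and uniqueness", {
  db <- data.frame(
    id = c("P1", "P2", "P3"),
    kind = "reference",
    sequence = c("MSSSKAAAARLLLLK",      # unique host of AAAAR
                 "MTTTKGGGGRWWWWK",      # indistinguishable pair with P3
                 "MTTTKGGGGRWWWWK"),
    stringsAsFactors = FALSE)
  db <- rbind(db, data.frame(id = "REV_P1", kind = "decoy",
                             sequence = reverse_sequence(db$sequence[1]),
                             source_id = NA)[, names(db)])
  obs <- data.frame(sequence = c("AAAAR", "GGGGR", "SSSK"),
                    stringsAsFactors = FALSE)
  mp <- map_peptides(obs, db)
  o <- mp$observations
  expect_equal(o$assigned_proteins,
               c("P1", "P2;P3", "P1"))
  expect_true(all(o$is_unique))          # P2+P3 collapse to one group
  expect_equal(nrow(mp$groups), 2L)
  expect_true("P2;P3" %in% mp$groups$group_id)

  # non-tryptic substring is not matched: AAAA lacks a K/R C-terminus
  mp2 <- suppressMessages(map_peptides(data.frame(sequence = "AAAA"), db))
  expect_equal(mp2$observations$assigned_proteins[1], "")

  # peptide found only in a decoy is excluded and reported
  db2 <- db
  db2$sequence[db2$id == "P1"] <- "MSSSKAAAAR"
  db2$sequence[db2$id == "REV_P1"] <- "KLLLLKAAAR"
  expect_message(mp3 <- map_peptides(data.frame(sequence = "LLLLK"), db2),
                 "decoy")
  expect_equal(nrow(mp3$observations), 0L)
})

test_that("initiator-Met-cleaved N-terminal peptides are accepted", {
  db <- data.frame(id = "P1", kind = "reference", sequence = "MSTEAKLLLR",
                   stringsAsFactors = FALSE)
  mp <- map_peptides(data.frame(sequence = "STEAK"), db)
  expect_equal(mp$matches$start, 2L)
  mp2 <- suppressMessages(map_peptides(data.frame(sequence = "TEAK"), db))
  expect_equal(nrow(mp2$matches), 0L)  # position 3 is not a tryptic N-side
})

test_that("filter_identifications applies strict PEP and unique-peptide rules", {
  s <- data.frame(protein_id = c("a", "b", "c"),
                  pep = c(0.049, 0.05, 0.01),
                  n_unique_peptides = c(1L, 1L, 0L))
  kept <- filter_identifications(s)
  expect_equal(kept$protein_id, "a")
})

test_that("coverage is the union of peptide intervals", {
  peps <- data.frame(start = c(1L, 4L), end = c(5L, 8L))
  expect_equal(compute_coverage(10L, peps), 80)
  expect_equal(compute_coverage(10L, peps[0, ]), 0)
  expect_equal(compute_coverage("MKAVLLAVLY",
                                data.frame(start = 1L, end = 10L)), 100)
  expect_error(compute_coverage(10L, data.frame(start = 5L, end = 11L)),
               "out of range")
  # invariant under duplication and reordering
  shuffled <- peps[c(2, 1, 2, 1), ]
  expect_equal(compute_coverage(10L, shuffled), 80)
})

test_that("validate_tis requires acetylation at position 1 or Met-cleaved 2", {
  prot <- "MSTEAKAAAK"
  expect_true(validate_tis(prot, data.frame(start = 2L,
                                            is_nterm_acetylated = TRUE)))
  expect_false(validate_tis(prot, data.frame(start = 5L,
                                             is_nterm_acetylated = TRUE)))
  expect_false(validate_tis(prot, data.frame(start = 1L,
                                             is_nterm_acetylated = FALSE)))
  # position 2 only counts when residue 1 is Met
  expect_false(validate_tis("STEAKAAAK", data.frame(start = 2L,
                                                    is_nterm_acetylated = TRUE)))
})

test_that("coexpression_genes returns genes with both kinds detected", {
  det <- data.frame(protein_id = c("R1", "A1", "A2"),
                    kind = c("reference", "alternative", "alternative"),
                    mean_intensity = c(100, 10, 20))
  gm <- data.frame(protein_id = c("R1", "A1", "A2"),
                   gene_symbol = c("G1", "G1", "G2"))
  co <- coexpression_genes(det, gm)
  expect_equal(co$gene_symbol, "G1")
  expect_equal(co$mean_intensity_reference, 100)
  expect_equal(co$mean_intensity_alternative, 10)
})

test_that("overlap_enrichment matches exact references and is monotone", {
  expect_equal(overlap_enrichment(2, 2, 0, 10), 1)
  expect_equal(overlap_enrichment(2, 2, 2, 10), 1 / 45)
  expect_equal(overlap_enrichment(7, 7, 7, 7), 1)
  expect_error(overlap_enrichment(5, 5, 6, 10), "inconsistent")

  # independent oracle: stats::phyper upper tail, over a seeded grid
  set.seed(77)
  for (i in 1:200) {
    N <- sample(5:200, 1)
    na <- sample.int(N, 1); nb <- sample.int(N, 1)
    k <- sample(0:min(na, nb), 1)
    expect_equal(overlap_enrichment(na, nb, k, N),
                 phyper(k - 1, na, N - na, nb, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # p is non-increasing in k
  p <- vapply(0:10, function(k) overlap_enrichment(20, 15, k, 100), 0)
  expect_true(all(diff(p) <= 1e-15))
})
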