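test_that("translate_orf follows the standard code, drops the stop, maps N to X", {
  expect_equal(translate_orf("ATGGCCTAA"), "MA")
  expect_equal(translate_orf("ATGNNNTAA"), "MX")
  expect_equal(translate_orf("ATGCAGTGTGAATAG"), "MQCE")
  expect_equal(translate_orf(""), "")
  expect_error(translate_orf("ATGA"), "multiple of 3")
})

test_that("translate_orf agrees with Biostrings::translate on random ORFs", {
  set.seed(11)
  for (i in 1:100) {
    nt <- paste(sample(c("A", "C", "G", "T"), 3 * sample(2:50, 1), TRUE),
                collapse = "")
    mine <- translate_orf(nt)
    ref <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                              no.init.codon = TRUE))
    ref <- sub("\\*$", "", ref)
    # internal stops: both keep them as '*'
    expect_equal(mine, ref, info = nt)
  }
})

test_that("assign_frame and classify_location implement the interval rules", {
  expect_equal(assign_frame(10, 1), "+1")
  expect_equal(assign_frame(5, 1), "+2")
  expect_equal(assign_frame(6, 1), "+3")
  expect_equal(assign_frame(7, 7), "+1")

  expect_equal(classify_location(10, 18, 1, 9), "utr3")
  expect_equal(classify_location(5, 19, 1, 15), "cds_utr3")
  expect_equal(classify_location(2, 10, 8, 20), "utr5_cds")
  expect_equal(classify_location(1, 6, 8, 20), "utr5")
  expect_equal(classify_location(9, 17, 8, 20), "cds")
  expect_equal(classify_location(2, 25, 8, 20), "spanning")
  expect_error(classify_location(8, 20, 8, 20), "internal error")
})

test_that("scan_altorfs reproduces the worked toy examples exactly", {
  a <- scan_altorfs(toy_a(), min_len = 2)
  expect_equal(nrow(a), 1L)
  expect_equal(a$start, 10L)
  expect_equal(a$end, 18L)
  expect_equal(a$frame_label, "+1")
  expect_equal(a$location_class, "utr3")
  expect_equal(a$protein_sequence, "MA")

  b <- scan_altorfs(toy_b(), min_len = 2)
  expect_equal(b[, c("start", "end", "frame_label", "location_class",
                     "protein_sequence")],
               data.frame(start = 5L, end = 19L, frame_label = "+2",
                          location_class = "cds_utr3",
                          protein_sequence = "MQCE"))

  # only AUG is the RefORF start: nothing to report
  only_ref <- transcript_record("r", "g", "ATGGCCGCCTAAGGG", 1, 12)
  expect_equal(nrow(scan_altorfs(only_ref, min_len = 1)), 0L)
})

test_that("scan_altorfs excludes same-frame N-terminal variants of the RefORF", {
  # internal AUG in the RefORF frame shares the RefORF stop: not an AltORF
  seq <- "ATGAAAATGGCCGCCGCCTAA"
  tr <- transcript_record("t", "g", seq, 1, 21)
  expect_equal(nrow(scan_altorfs(tr, min_len = 1)), 0L)
  # and an upstream in-frame AUG reading into the RefORF stop is excluded too
  seq2 <- paste0("ATGCCC", seq)
  tr2 <- transcript_record("t2", "g", seq2, 7, 27)
  got <- scan_altorfs(tr2, min_len = 1)
  expect_false(any(got$end == tr2$cds_end & got$frame_label == "+1"))
})

test_that("scanner output satisfies the first-AUG and no-internal-stop properties", {
  set.seed(5)
  for (s in 1:50) {
    tr <- random_transcript(sample(200:1500, 1), seed = s)
    got <- scan_altorfs(tr, min_len = 5)
    for (i in seq_len(nrow(got))) {
      s0 <- got$start[i]; e0 <- got$end[i]
      orf <- substr(tr$sequence, s0, e0)
      codons <- substring(orf, seq(1, nchar(orf), 3), seq(3, nchar(orf), 3))
      expect_equal(codons[1], "ATG")
      expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
      expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
      # no in-frame AUG strictly between the slot boundary and the start
      j <- s0 - 3
      while (j >= 1 && !substr(tr$sequence, j, j + 2) %in% c("TAA", "TAG", "TGA")) {
        expect_false(substr(tr$sequence, j, j + 2) == "ATG")
        j <- j - 3
      }
    }
  }
})

test_that("raising min_len only removes AltORFs (monotonicity)", {
  set.seed(9)
  for (s in 1:20) {
    tr <- random_transcript(sample(300:2000, 1), seed = s + 1000)
    lo <- scan_altorfs(tr, min_len = 5)
    hi <- scan_altorfs(tr, min_len = 25)
    key <- function(d) paste(d$start, d$end)
    expect_true(all(key(hi) %in% key(lo)))
    expect_equal(key(lo)[lo$length_aa >= 25], key(hi))
  }
})

test_that("dedupe_distinct collapses identical proteins across transcripts", {
  x <- data.frame(
    transcript_accession = c("T1", "T2", "T1"),
    start = c(10L, 40L, 100L), end = c(30L, 60L, 150L),
    protein_sequence = c("MKLE", "MKLE", "MAAA"),
    stringsAsFactors = FALSE)
  dd <- dedupe_distinct(x)
  expect_equal(nrow(dd), 2L)
  shared <- dd[dd$protein_sequence == "MKLE", ]
  expect_equal(shared$n_transcripts, 2L)
  expect_equal(shared$n_instances, 2L)
  expect_match(dd$alt_accession, "^ALT_[0-9a-f]{12}$")
  # deterministic, content-derived accessions
  expect_equal(dd$alt_accession, alt_accession(dd$protein_sequence))
  expect_equal(nrow(dedupe_distinct(x[0, ])), 0L)
})
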