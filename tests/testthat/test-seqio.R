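test_that("FASTA parsing preserves records, order and normalizes U/case", {
  recs <- read_seqs(text = ">g\nATGTAA", format = "fasta")
  expect_length(recs, 1L)
  expect_identical(recs[[1L]]$seq, "ATGTAA")

  recs <- read_seqs(text = ">a first\nauggcu\n>b\nATGTGG", format = "fasta")
  expect_identical(vapply(recs, `[[`, "", "id"), c("a", "b"))
  expect_identical(recs[[1L]]$seq, "ATGGCT")
  expect_identical(recs[[1L]]$desc, "first")

  expect_error(read_seqs(text = "", format = "fasta"), "no records")
  expect_error(seq_record("x", "ATGN"), "non-ACGT")
})

test_that("FASTA write/parse round-trips ids and sequences exactly", {
  set.seed(42)
  recs <- lapply(1:5, function(i) {
    seq_record(paste0("gene", i), random_dna(3L * sample(30:80, 1L)))
  })
  f <- tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  back <- read_seqs(f, "fasta")
  expect_identical(lapply(back, `[[`, "id"), lapply(recs, `[[`, "id"))
  expect_identical(lapply(back, `[[`, "seq"), lapply(recs, `[[`, "seq"))
  # normalization idempotence: re-reading written output changes nothing
  f2 <- tempfile(fileext = ".fasta")
  write_fasta(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("GenBank reader extracts CDS features incl. join() locations", {
  gb <- paste(
    "LOCUS       TEST1        24 bp DNA",
    "DEFINITION  toy record.",
    "FEATURES             Location/Qualifiers",
    "     CDS             4..12",
    "                     /gene=\"x\"",
    "ORIGIN",
    "        1 aaaatggagt tgaaaaaaaa aaaa",
    "//", sep = "\n")
  rec <- read_seqs(text = gb, format = "genbank")[[1L]]
  expect_identical(rec$id, "TEST1")
  expect_identical(rec$seq, "ATGGAGTTG")

  gb2 <- paste(
    "LOCUS       TEST2        30 bp DNA",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(1..6,10..15)",
    "ORIGIN",
    "        1 atggag tttcttgtaa aaaaaaaaa",
    "//", sep = "\n")
  rec2 <- read_seqs(text = gb2, format = "genbank")[[1L]]
  expect_identical(rec2$seq, "ATGGAGCTTGTA")

  # no CDS feature: whole ORIGIN sequence
  gb3 <- paste("LOCUS  T3  6 bp", "ORIGIN", "  1 atgtaa", "//", sep = "\n")
  expect_identical(read_seqs(text = gb3, format = "genbank")[[1L]]$seq,
                   "ATGTAA")
  expect_error(read_seqs(text = "LOCUS x\n//", format = "genbank"),
               "ORIGIN")
})

test_that("CDS validation enforces frame and stop rules", {
  v <- validate_cds(seq_record("g", "ATGGAGTTG"))
  expect_identical(v$codon_count, 3L)
  expect_false(v$has_terminal_stop)

  expect_error(validate_cds(seq_record("g", "ATGTAAGAG")),
               "internal stop at codon 2")
  expect_error(validate_cds(seq_record("g", "ATGGA")),
               "length not multiple of 3")
  expect_error(validate_cds(seq_record("g", "GAGTTGTAA"), require_atg = TRUE),
               "missing ATG")
  v2 <- validate_cds(seq_record("g", "ATGTGA"))
  expect_true(v2$has_terminal_stop)
})

test_that("translation follows the standard code, codon for codon", {
  expect_identical(translate_cds(validate_cds(seq_record("g", "ATG"))), "M")
  expect_identical(translate_cds(validate_cds(seq_record("g", "ATGGAGTTG"))),
                   "MEL")
  expect_identical(translate_cds(validate_cds(seq_record("g", "ATGTGA"))),
                   "M*")
  # length preservation in codons, over random CDSs
  set.seed(7)
  for (i in 1:20) {
    sense <- sample(codonharmony:::SENSE_CODONS, sample(5:40, 1L),
                    replace = TRUE)
    cds <- validate_cds(seq_record("r", paste(sense, collapse = "")))
    expect_identical(nchar(translate_cds(cds)), cds$codon_count)
  }
})
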