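test_that("GC content and windows count bases exactly", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("AAAA"), 0)
  expect_error(gc_content(""), "empty")

  p <- gc_window_profile(strrep("G", 40L), window = 40L, target = 0.45,
                         tolerance = 0.10)
  expect_length(p$centers, 1L)
  expect_equal(p$gc, 1.0)
  expect_identical(p$violations, p$centers)

  # windows across an AT|GC junction rise monotonically from 0 to 1
  s <- paste0(strrep("AT", 20L), strrep("GC", 20L))
  p2 <- gc_window_profile(s, window = 40L)
  expect_equal(p2$gc[1L], 0)
  expect_equal(p2$gc[length(p2$gc)], 1)
  expect_true(all(diff(p2$gc) >= 0))

  # a window the size of the sequence reproduces gc_content exactly
  set.seed(3)
  for (i in 1:10) {
    s <- random_dna(sample(40:120, 1L))
    p3 <- gc_window_profile(s, window = nchar(s))
    expect_length(p3$gc, 1L)
    expect_equal(p3$gc, gc_content(s))
  }
  expect_error(gc_window_profile("ATGC", window = 40L), "exceeds")
  expect_error(gc_window_profile("ATGCATGC", window = 3L), ">= 4")
})

test_that("tandem codon repeats are maximal runs, counted once", {
  r1 <- find_tandem_codon_repeats(validate_cds(seq_record("a", "ATGGCTGCTTAA")))
  expect_identical(nrow(r1), 1L)
  expect_identical(r1$start, 2L)
  expect_identical(r1$codon, "GCT")

  r2 <- find_tandem_codon_repeats(validate_cds(seq_record("b", "ATGGCAGCCTAA")))
  expect_identical(nrow(r2), 0L)

  r3 <- find_tandem_codon_repeats(validate_cds(seq_record("c", strrep("AAA", 4L))))
  expect_identical(nrow(r3), 1L)
  expect_identical(r3$length, 4L)
  expect_identical(attr(r3, "n_pairs"), 3L)
})

test_that("AT/GC-rich runs are maximal single-class stretches", {
  r1 <- find_rich_runs("ATATATAT", min_len = 8L)
  expect_identical(r1$start, 1L)
  expect_identical(r1$end, 8L)
  expect_identical(r1$class, "AT")

  expect_identical(nrow(find_rich_runs("ACGTACGTACGT", min_len = 8L)), 0L)

  r3 <- find_rich_runs("AAAATTTTGGGGCCCC", min_len = 8L)
  expect_identical(r3$start, c(1L, 9L))
  expect_identical(r3$end, c(8L, 16L))
  expect_identical(r3$class, c("AT", "GC"))
  expect_error(find_rich_runs("ATGC", min_len = 1L), ">= 2")
})

test_that("hairpin hits match constructed inverted repeats", {
  arm1 <- "GCGCAGTCGC"
  hp <- paste0(arm1, "AAAA", revcomp1(arm1))
  h <- find_hairpins(hp, min_stem = 10L, min_loop = 4L)
  expect_identical(nrow(h), 1L)
  expect_identical(h$mismatches, 0L)
  expect_identical(h$stem, 10L)
  expect_identical(h$loop, 4L)

  expect_identical(nrow(find_hairpins(strrep("A", 60L))), 0L)

  # one substitution in arm2 consumes the floor(0.1 * 10) = 1 budget
  arm2 <- revcomp1(arm1)
  substr(arm2, 5L, 5L) <- "A"
  h2 <- find_hairpins(paste0(arm1, "AAAA", arm2), min_stem = 10L,
                      max_mismatch_frac = 0.1, min_loop = 4L)
  expect_identical(nrow(h2), 1L)
  expect_identical(h2$mismatches, 1L)
})

test_that("hairpin finder agrees with the brute-force all-substring oracle", {
  set.seed(20)
  params <- list(min_stem = 5L, frac = 0.2, min_loop = 4L, max_stem = 30L)
  n_cases <- 60L
  for (i in seq_len(n_cases)) {
    s <- random_dna(sample(20:60, 1L))
    got <- as.matrix(find_hairpins(s, params$min_stem, params$frac,
                                   params$min_loop, params$max_stem))
    want <- brute_hairpins(s, params$min_stem, params$frac, params$min_loop,
                           params$max_stem)
    storage.mode(got) <- "integer"
    storage.mode(want) <- "integer"
    expect_identical(unname(got), unname(want), info = s)
  }
})

test_that("detectors reflect coordinates under reverse complement", {
  set.seed(31)
  for (i in 1:8) {
    s <- random_dna(90L)
    rc <- revcomp1(s)
    n <- nchar(s)
    rr <- find_rich_runs(s, min_len = 5L)
    rr_rc <- find_rich_runs(rc, min_len = 5L)
    expect_identical(rr_rc$start, sort(n + 1L - rev(rr$end)))
    # hairpins map onto themselves under reflection
    h <- find_hairpins(s, 5L, 0.2, 4L, 30L)
    h_rc <- find_hairpins(rc, 5L, 0.2, 4L, 30L)
    expect_identical(nrow(h), nrow(h_rc))
    if (nrow(h) > 0L) {
      refl <- data.frame(a1_start = n + 1L - h$a2_end,
                         a1_end = n + 1L - h$a2_start,
                         a2_start = n + 1L - h$a1_end,
                         a2_end = n + 1L - h$a1_start)
      refl <- refl[order(refl$a1_start, refl$a1_end, refl$a2_start), ]
      expect_identical(refl$a1_start, h_rc$a1_start)
      expect_identical(refl$a2_start, h_rc$a2_start)
    }
  }
})

test_that("splice PWMs are trained by count arithmetic with pseudocounts", {
  m <- train_splice_model(rep("GTATGT", 5L), rep("TACTAAC", 5L),
                          rep("TAG", 5L), pseudocount = 0)
  pwm <- m$signals$donor$pwm
  expect_equal(unname(pwm["G", 1L]), 1)
  expect_equal(unname(pwm["T", 2L]), 1)
  expect_true(all(abs(colSums(pwm) - 1) < 1e-12))

  m2 <- train_splice_model(c(rep("GTATGT", 4L), "GAATGT"),
                           rep("TACTAAC", 2L), rep("TAG", 2L),
                           pseudocount = 0)
  expect_equal(unname(m2$signals$donor$pwm[c("T", "A"), 2L]), c(0.8, 0.2))

  expect_error(train_splice_model(character(), "TACTAAC", "TAG"), "empty")
  expect_error(train_splice_model(c("GTATGT", "GTAT"), "TACTAAC", "TAG"),
               "ragged")
})

test_that("splice scanning scores log-odds and respects thresholds", {
  model <- default_splice_model()
  s <- paste0(strrep("C", 20L), "GTATGT", strrep("C", 20L))
  hits <- scan_splice_sites(s, model)
  don <- hits[hits$type == "donor", ]
  expect_true(21L %in% don$position)
  max_score <- sum(apply(model$signals$donor$logodds, 2L, max))
  expect_equal(max(don$score), max_score)

  none <- scan_splice_sites(strrep("A", 50L), model)
  expect_identical(nrow(none[none$type == "donor", ]), 0L)

  # threshold -Inf yields one score per eligible position
  open <- model
  for (nm in names(open$signals)) open$signals[[nm]]$threshold <- -Inf
  all_hits <- scan_splice_sites(strrep("ACGT", 15L), open)
  expect_identical(sum(all_hits$type == "donor"), 60L - 6L + 1L)
  expect_identical(sum(all_hits$type == "acceptor"), 60L - 3L + 1L)
})

test_that("enzyme lists round-trip through two-column TSV", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("name\tmotif", "SalI\tGTCGAC", "Deg\tGRATTC"), f)
  enz <- read_enzyme_list(f)
  expect_identical(enz, c(SalI = "GTCGAC", Deg = "GRATTC"))
  writeLines(c("Bad\tGAZTC"), f)
  expect_error(read_enzyme_list(f), "IUPAC")
})

test_that("restriction-site search expands IUPAC codes on the forward strand", {
  expect_identical(find_restriction_sites("AGAATTCA", c(EcoRI = "GAATTC")),
                   list(EcoRI = 2L))
  pal <- find_restriction_sites("ACGCGT", c(MluI = "ACGCGT"))
  expect_identical(pal$MluI, 1L)
  deg <- find_restriction_sites("GAATTCGGATTC", c(X = "GRATTC"))
  expect_identical(deg$X, c(1L, 7L))
  expect_error(find_restriction_sites("ACGT", c(bad = "GAAZTC")), "IUPAC")
})

test_that("diagnose aggregates detectors and matches planted ground truth", {
  out <- planted_flaw_sequence(flaw_spec(3L, 1L, 0L, seed = 9L), 200L)
  tab <- host_reference_table()
  rep <- diagnose(out$cds, tab, opt_config())
  s <- summary(rep)
  expect_identical(unname(s["tandem_repeats"]), 3L)
  expect_identical(unname(s["hairpins"]), 1L)
  expect_identical(unname(s["rich_runs"]), 0L)
  expect_identical(rep$tandem_repeat_runs$start, out$truth$repeat_starts)

  # invariance under record id change and U-spelling of the input
  cds_u <- validate_cds(seq_record("other_name",
                                   chartr("T", "U", out$cds$record$seq)))
  rep2 <- diagnose(cds_u, tab, opt_config())
  expect_identical(summary(rep2), s)

  # report serialization writes the JSON + TSV bundle
  d <- tempfile()
  write_report(rep, d)
  expect_true(file.exists(file.path(d, "report.json")))
  js <- jsonlite::read_json(file.path(d, "report.json"))
  expect_identical(js$summary$tandem_repeats, 3L)
  expect_true(file.exists(file.path(d, "hairpins.tsv")))
})
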