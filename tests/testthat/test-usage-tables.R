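test_that("usage tables tally codons exactly and conserve totals", {
  cds <- validate_cds(seq_record("toy", "ATGGCTGCATAA"))
  tab <- build_usage_table(list(cds))
  expect_identical(tab$n_codons, 3L)
  expect_equal(unname(tab$family_fraction[c("GCT", "GCA")]), c(0.5, 0.5))
  expect_identical(unname(tab$counts[["TAA"]]), 0L)

  tab_s <- build_usage_table(list(cds), include_stops = TRUE)
  expect_identical(tab_s$n_codons, 4L)

  expect_error(build_usage_table(list()), "empty CDS set")

  # tally conservation and family normalization on random CDS sets
  set.seed(11)
  for (i in 1:10) {
    cdss <- lapply(1:3, function(j) {
      validate_cds(seq_record(paste0("r", j),
                              paste(sample(codonharmony:::SENSE_CODONS,
                                           sample(20:60, 1L), replace = TRUE),
                                    collapse = "")))
    })
    t2 <- build_usage_table(cdss)
    expect_identical(sum(t2$counts), t2$n_codons)
    for (fam in codonharmony:::AA_FAMILIES) {
      if (sum(t2$counts[fam]) > 0L) {
        expect_equal(sum(t2$family_fraction[fam]), 1, tolerance = 1e-9)
      }
    }
  }
})

test_that("low-frequency census uses a strict threshold and skips singletons", {
  tab <- make_table(c(GCT = 92, GCC = 5, GCA = 2, GCG = 1, ATG = 50,
                      TGG = 50))
  expect_identical(low_frequency_codons(tab, 0), character(0))
  expect_identical(low_frequency_codons(tab, 0.08),
                   c("GCA", "GCC", "GCG"))
  # boundary: exactly at threshold is retained; unseen family members are
  # low by definition (fraction 0)
  tab2 <- make_table(c(GCT = 92, GCC = 8, ATG = 10))
  expect_identical(low_frequency_codons(tab2, 0.08), c("GCA", "GCG"))
  expect_error(low_frequency_codons(tab, 1.5), "threshold")

  # monotonicity in the threshold
  set.seed(5)
  big <- build_usage_table(biased_cds_set(host_reference_table(), 3L, 400L,
                                          seed = 5L))
  ths <- sort(runif(6))
  sizes <- vapply(ths, function(th) length(low_frequency_codons(big, th)),
                  integer(1L))
  expect_true(all(diff(sizes) >= 0L))
})

test_that("harmonization zeroes rare codons and renormalizes families", {
  tab <- make_table(c(GCT = 59, GCC = 31, GCA = 9, GCG = 1))
  h <- harmonize(tab, 0.08)
  tf <- h$target_fraction
  expect_equal(unname(tf[c("GCT", "GCC", "GCA")]),
               c(0.59, 0.31, 0.09) / 0.99, tolerance = 1e-9)
  expect_identical(unname(tf[["GCG"]]), 0)

  tab2 <- make_table(c(CAC = 95, CAT = 5))
  expect_equal(unname(harmonize(tab2, 0.08)$target_fraction[c("CAC", "CAT")]),
               c(1, 0))
  tab3 <- make_table(c(ATG = 7))
  expect_equal(unname(harmonize(tab3, 0.08)$target_fraction[["ATG"]]), 1)

  # a family entirely below threshold is an error naming the family
  tab4 <- make_table(c(GCT = 1, GCC = 1, GCA = 1, GCG = 1, ATG = 96))
  expect_error(harmonize(tab4, 0.30), "'A'")

  # idempotence through as_usage_table
  h2 <- harmonize(as_usage_table(h), 0.08)
  expect_equal(h2$target_fraction, h$target_fraction, tolerance = 1e-12)
})

test_that("table comparison reports inversions and antisymmetric deltas", {
  a <- make_table(c(CAC = 73, CAT = 27, GCT = 60, GCC = 40))
  same <- compare_tables(a, a, 0.1)
  expect_identical(nrow(same$inversions), 0L)
  expect_true(all(same$per_codon_delta == 0))

  b <- make_table(c(CAC = 40, CAT = 60, GCT = 55, GCC = 45))
  ab <- compare_tables(a, b, 0.1)
  expect_identical(ab$inversions$aa, "H")
  ba <- compare_tables(b, a, 0.1)
  expect_identical(ba$inversions$aa, "H")          # symmetric under swap
  expect_equal(ab$per_codon_delta, -ba$per_codon_delta)
  expect_identical(ab$inversions$preferred_a, ba$inversions$preferred_b)
})

test_that("codon-table TSV round-trips through the declared dialect", {
  tab <- host_reference_table(5000L)
  f <- tempfile(fileext = ".tsv")
  write_usage_table(tab, f)
  lines <- readLines(f)
  expect_length(lines, 65L)  # header + 64 rows
  expect_identical(lines[1L], "codon\taa\tcount\tfamily_fraction")
  back <- read_usage_table(f)
  expect_identical(back$counts, tab$counts)
  expect_equal(back$family_fraction, tab$family_fraction, tolerance = 1e-6)
})

test_that("rebuilt tables recover generator fractions at scale", {
  ref <- host_reference_table()
  genes <- biased_cds_set(ref, 50L, 500L, seed = 7L)  # 25,000 codons
  got <- build_usage_table(genes)
  expect_identical(got$n_codons, 25000L)
  err <- abs(got$family_fraction - ref$family_fraction)
  expect_lt(max(err[codonharmony:::SENSE_CODONS]), 0.05)
})
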