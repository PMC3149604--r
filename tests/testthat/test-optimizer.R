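test_that("largest-remainder allocation apportions counts exactly", {
  tab <- make_table(c(GCT = 60, GCC = 30, GCA = 10, ATG = 5))
  target <- harmonize(tab, 0.08)
  a <- allocate_codon_counts(c(A = 10L), target)
  expect_identical(a$A, c(GCA = 1L, GCC = 3L, GCT = 6L)[names(a$A)])
  expect_identical(sum(a$A), 10L)

  # equal remainders break by codon order
  tab2 <- make_table(c(CAC = 50, CAT = 50))
  a2 <- allocate_codon_counts(c(H = 3L), harmonize(tab2, 0.08))
  expect_identical(a2$H[["CAC"]], 2L)
  expect_identical(a2$H[["CAT"]], 1L)

  a3 <- allocate_codon_counts(c(M = 5L), target)
  expect_identical(a3$M, c(ATG = 5L))

  # allocation conserves counts and deviates < 1/n per codon
  set.seed(13)
  ref <- harmonize(host_reference_table(), 0.08)
  for (i in 1:40) {
    aa <- sample(setdiff(names(codonharmony:::AA_FAMILIES), "*"), 1L)
    n <- sample(1:500, 1L)
    al <- allocate_codon_counts(stats::setNames(n, aa), ref)[[1L]]
    expect_identical(sum(al), n)
    tf <- ref$target_fraction[names(al)]
    expect_true(all(abs(al / n - tf / sum(tf)) < 1 / n + 1e-12))
  }
})

test_that("penalty terms are additive with their configured weights", {
  tab <- host_reference_table()
  target <- harmonize(tab, 0.08)
  out <- planted_flaw_sequence(flaw_spec(0L, 0L, 0L, seed = 21L), 120L)
  base <- out$cds
  # isolate the tandem-repeat term
  w <- c(rare_codon = 0, tandem_repeat = 2.5, rich_run = 0, hairpin = 0,
         splice_site = 0, gc_window = 0, forbidden_motif = 0,
         freq_divergence = 0)
  cfg <- opt_config(penalty_weights = w)
  p0 <- codon_penalty(base, target, cfg)
  expect_equal(p0$total, 0)

  codons <- base$codons
  codons[11L] <- codons[10L]  # plant one repeat pair
  planted <- validate_cds(seq_record("p", paste(codons, collapse = "")))
  p1 <- codon_penalty(planted, target, cfg)
  expect_equal(p1$total, 2.5)
  expect_identical(unname(p1$counts[["tandem_repeat"]]), 1)

  # a second independent flaw never decreases the total (weights >= 0)
  codons[31L] <- codons[30L]
  planted2 <- validate_cds(seq_record("p2", paste(codons, collapse = "")))
  p2 <- codon_penalty(planted2, target, cfg)
  expect_gte(p2$total, p1$total)
  expect_equal(p2$total, sum(p2$contributions))
})

test_that("required sites are carved synonymously and locked", {
  tab <- host_reference_table()
  target <- harmonize(tab, 0.08)
  # Val-Asp (GTN GAC) admits SalI GTCGAC purely synonymously
  cds <- validate_cds(seq_record("g", "ATGGTTGATTTGAAGTAA"))
  carved <- carve_required_sites(cds, c(SalI = "GTCGAC"), target)
  expect_identical(carved$sites$start, 4L)
  expect_identical(carved$cds$codons[2:3], c("GTC", "GAC"))
  expect_identical(carved$locked, 2:3)
  expect_identical(translate_cds(carved$cds), translate_cds(cds))

  # an already-present motif is kept in place and locked
  cds2 <- validate_cds(seq_record("g2", "ATGGTCGACTTGAAGTAA"))
  carved2 <- carve_required_sites(cds2, c(SalI = "GTCGAC"), target)
  expect_identical(carved2$cds$codons, cds2$codons)
  expect_identical(carved2$sites$start, 4L)

  # a motif no codon context can encode errors out, naming the motif
  cds3 <- validate_cds(seq_record("g3", "ATGAAGAAATAA"))
  expect_error(carve_required_sites(cds3, c(NotI = "GCGGCCGC"), target),
               "GCGGCCGC")
})

test_that("optimization satisfies hard constraints, reproducibly", {
  tab <- host_reference_table()
  wt <- synthetic_wt_gene(seed = 7L, n_codons = 301L, n_repeats = 6L)
  cfg <- opt_config(seed = 42L, max_iterations = 20000L,
                    required_unique_sites = c(SalI = "GTCGAC"))
  res <- optimize_cds(wt, tab, cfg)

  expect_true(res$success)
  expect_identical(translate_cds(res$output_cds), translate_cds(wt))
  # rare-codon exclusion outside locked positions
  target <- harmonize(tab, cfg$rare_threshold)
  zero <- names(which(target$target_fraction == 0))
  sense <- res$output_cds$codons[seq_len(300L)]
  unlocked <- setdiff(seq_len(300L), res$locked)
  expect_identical(sum(sense[unlocked] %in% zero), 0L)
  # GC windows within tolerance
  expect_length(res$report_after$gc$violations, 0L)
  # required site present exactly once
  pos <- find_restriction_sites(res$output_cds$record$seq,
                                c(SalI = "GTCGAC"))$SalI
  expect_length(pos, 1L)
  # recorded-best trace is non-increasing; best equals its minimum
  expect_true(all(diff(res$penalty_trace) <= 1e-12))
  expect_equal(res$penalty_after$total, min(res$penalty_trace))

  # frequency harmonization for well-represented amino acids
  aa_out <- codonharmony:::GENCODE[sense]
  for (aa in unique(aa_out)) {
    fam <- codonharmony:::AA_FAMILIES[[aa]]
    n_aa <- sum(aa_out == aa)
    if (n_aa < 20L) next
    realized <- vapply(fam, function(cd) sum(sense == cd), numeric(1L)) / n_aa
    tf <- target$target_fraction[fam]
    expect_lte(max(abs(realized - tf / sum(tf))), 0.05)
  }

  # determinism: same seed gives byte-identical output
  res2 <- optimize_cds(wt, tab, cfg)
  expect_identical(res2$output_cds$record$seq, res$output_cds$record$seq)
  expect_identical(res2$penalty_trace, res$penalty_trace)

  # independent verification passes and matches the recorded report
  v <- verify_result(res)
  expect_true(v$pass)
})

test_that("verification flags tampered results", {
  tab <- host_reference_table()
  wt <- synthetic_wt_gene(seed = 3L, n_codons = 151L, n_repeats = 3L)
  cfg <- opt_config(seed = 5L, max_iterations = 8000L)
  res <- optimize_cds(wt, tab, cfg)
  expect_true(verify_result(res)$pass)

  # non-synonymous mutation -> protein mismatch reported
  bad <- res
  codons <- bad$output_cds$codons
  codons[10L] <- if (codons[10L] == "GCT") "GAA" else "GCT"
  bad$output_cds <- validate_cds(seq_record("bad",
                                            paste(codons, collapse = "")))
  vb <- verify_result(bad)
  expect_false(vb$pass)
  expect_false(vb$checks$ok[vb$checks$check == "protein_identity"])

  # injected zero-target codon -> rare-codon violation listed
  bad2 <- res
  codons2 <- bad2$output_cds$codons
  target <- harmonize(tab, cfg$rare_threshold)
  # first unlocked position whose family has a zeroed codon (Ala, Arg, ...)
  p <- which(vapply(seq_along(codons2), function(i) {
    fam <- codonharmony:::AA_FAMILIES[[codonharmony:::GENCODE[[codons2[i]]]]]
    any(target$target_fraction[fam] == 0) && !(i %in% res$locked)
  }, logical(1L)))[1L]
  expect_false(is.na(p))
  fam <- codonharmony:::AA_FAMILIES[[codonharmony:::GENCODE[[codons2[p]]]]]
  codons2[p] <- fam[target$target_fraction[fam] == 0][1L]
  bad2$output_cds <- validate_cds(seq_record("bad2",
                                             paste(codons2, collapse = "")))
  vb2 <- verify_result(bad2)
  expect_false(vb2$checks$ok[vb2$checks$check == "rare_codon_exclusion"])
})

test_that("an unsatisfiable configuration yields a failure report", {
  # poly-Lys protein with only AAA retained: the sequence is forced to
  # near-zero GC and no move can fix any window
  tab <- make_table(c(AAA = 95, AAG = 5, ATG = 10))
  cds <- validate_cds(seq_record("polyK",
                                 paste(c("ATG", rep("AAA", 40L), "TAA"),
                                       collapse = "")))
  cfg <- opt_config(seed = 1L, max_iterations = 1500L, stall = 50L,
                    patience = 200L)
  res <- optimize_cds(cds, tab, cfg)
  expect_false(res$success)
  expect_true("gc_window" %in% names(res$residual_violations))
  expect_identical(translate_cds(res$output_cds), translate_cds(cds))
})
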