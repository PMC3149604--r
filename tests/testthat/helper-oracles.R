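# Shared test helpers: an independent brute-force inverted-repeat oracle
# and small table constructors.

# Exhaustive all-substring hairpin oracle.  Enumerates every (arm1 start,
# arm2 start, stem) triple, applies the validity rules directly, and keeps
# maximal hits (neither outward nor inward one-base extension valid).
# Written independently of the package's diagonal scan.
brute_hairpins <- function(seq, min_stem = 10L, frac = 0.1, min_loop = 4L,
                           max_stem = 60L) {
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(b)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  mm_of <- function(i, j, L) sum(comp[b[i:(i + L - 1L)]] != b[(j + L - 1L):j])
  valid <- function(i, j, L) {
    if (L < min_stem || L > max_stem) return(FALSE)
    if (i < 1L || j + L - 1L > n) return(FALSE)
    if (j - i - L < min_loop) return(FALSE)
    mm_of(i, j, L) <= floor(frac * L + 1e-9)
  }
  hits <- NULL
  if (n < 2L * min_stem + min_loop) {
    return(matrix(integer(0), ncol = 7L))
  }
  for (i in 1:(n - 2L * min_stem - min_loop + 1L)) {
    for (L in min_stem:max_stem) {
      if (i + L - 1L > n) break
      jmin <- i + L + min_loop
      jmax <- n - L + 1L
      if (jmin > jmax) next
      for (j in jmin:jmax) {
        if (!valid(i, j, L)) next
        if (valid(i - 1L, j, L + 1L) || valid(i, j - 1L, L + 1L)) next
        hits <- rbind(hits, c(i, i + L - 1L, j, j + L - 1L, L,
                              mm_of(i, j, L), j - i - L))
      }
    }
  }
  if (is.null(hits)) hits <- matrix(integer(0), ncol = 7L)
  colnames(hits) <- c("a1_start", "a1_end", "a2_start", "a2_end", "stem",
                      "mismatches", "loop")
  hits[order(hits[, 1L], hits[, 2L], hits[, 3L]), , drop = FALSE]
}

# usage table directly from a named count vector (unnamed codons get 0)
make_table <- function(counts) {
  full <- stats::setNames(integer(64L), codonharmony:::ALL_CODONS)
  full[names(counts)] <- as.integer(counts)
  codonharmony:::new_usage_table(full, source_ids = "test")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp1 <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
}
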