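# Codon-usage tables: tallies over CDS sets, within-family relative
# frequencies, low-frequency codon census, harmonized target distributions
# and table comparison.

new_usage_table <- function(counts, source_ids = character(),
                            family_fraction = NULL) {
  stopifnot(identical(sort(names(counts)), ALL_CODONS))
  counts <- counts[ALL_CODONS]
  if (is.null(family_fraction)) {
    family_fraction <- stats::setNames(numeric(64L), ALL_CODONS)
    for (fam in AA_FAMILIES) {
      tot <- sum(counts[fam])
      family_fraction[fam] <- if (tot > 0L) counts[fam] / tot else 0
    }
  }
  structure(list(counts = counts,
                 family_fraction = family_fraction[ALL_CODONS],
                 n_codons = sum(counts),
                 source_ids = source_ids),
            class = "codon_usage_table")
}

#' Build a codon-usage table from a set of coding sequences
#'
#' Tallies every codon over the concatenated reading frames and computes
#' relative frequencies within each synonymous family (six-codon Ser/Leu/Arg
#' families are treated as single families; stop codons form their own
#' family).  Terminal stop codons are excluded from the tally by default,
#' so `n_codons` counts sense codons only.
#'
#' @param cds_set list of `validated_cds` objects (see [validate_cds()]).
#' @param include_stops also tally terminal stop codons.
#' @return object of class `codon_usage_table` with elements `counts`
#'   (all 64 codons), `family_fraction`, `n_codons`, `source_ids`.
#' @examples
#' cds <- validate_cds(seq_record("toy", "ATGGCTGCATAA"))
#' build_usage_table(list(cds))$n_codons  # 3
#' @export
build_usage_table <- function(cds_set, include_stops = FALSE) {
  if (inherits(cds_set, "validated_cds")) cds_set <- list(cds_set)
  if (length(cds_set) == 0L) stop("empty CDS set", call. = FALSE)
  stopifnot(all(vapply(cds_set, inherits, logical(1L), "validated_cds")))
  all_codons <- unlist(lapply(cds_set, function(x) {
    if (include_stops) x$codons else sense_codons_of(x)
  }))
  counts <- stats::setNames(integer(64L), ALL_CODONS)
  tab <- table(all_codons)
  counts[names(tab)] <- as.integer(tab)
  new_usage_table(counts,
                  source_ids = vapply(cds_set, function(x) x$record$id,
                                      character(1L)))
}

#' @export
print.codon_usage_table <- function(x, digits_pct = 0L, ...) {
  cat(sprintf("<codon_usage_table> %d codons from %d sequence(s)\n",
              x$n_codons, length(x$source_ids)))
  for (aa in names(AA_FAMILIES)) {
    fam <- AA_FAMILIES[[aa]]
    if (sum(x$counts[fam]) == 0L) next
    pct <- round(100 * x$family_fraction[fam], digits_pct)
    cat(sprintf("  %s: %s\n", aa,
                paste(sprintf("%s %s%%", codon_as_rna(fam),
                              formatC(pct, format = "fg")), collapse = "  ")))
  }
  invisible(x)
}

#' @export
as.data.frame.codon_usage_table <- function(x, ...) {
  data.frame(codon = ALL_CODONS, aa = unname(GENCODE[ALL_CODONS]),
             count = unname(x$counts),
             family_fraction = unname(x$family_fraction),
             stringsAsFactors = FALSE)
}

#' Low-frequency codons of a usage table
#'
#' Codons whose within-family relative frequency is strictly below
#' `threshold`.  Single-codon families (Met, Trp), unobserved families and
#' the stop family are excluded.
#'
#' @param table a `codon_usage_table`.
#' @param threshold fraction in `[0, 1]`; default 0.08.
#' @return character vector of codons, sorted.
#' @export
low_frequency_codons <- function(table, threshold = 0.08) {
  stopifnot(inherits(table, "codon_usage_table"))
  if (threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]", call. = FALSE)
  }
  out <- character(0)
  for (aa in setdiff(names(AA_FAMILIES), "*")) {
    fam <- AA_FAMILIES[[aa]]
    if (length(fam) < 2L || sum(table$counts[fam]) == 0L) next
    out <- c(out, fam[table$family_fraction[fam] < threshold])
  }
  sort(out)
}

#' Harmonized target distribution
#'
#' Zeroes every codon whose base within-family frequency is strictly below
#' `threshold` and renormalizes the retained codons of each family so that
#' retained fractions stay proportional to the base fractions.  Single-codon
#' families are kept at 1; stop-family fractions pass through unchanged
#' (the redesign never touches a terminal stop).
#'
#' @param table a `codon_usage_table`.
#' @param threshold zeroing threshold (strict `<`); default 0.08 as used for
#'   harmonization against highly expressed host genes.
#' @return object of class `harmonized_target`: `base`, `threshold`,
#'   `target_fraction` (all 64 codons).
#' @export
harmonize <- function(table, threshold = 0.08) {
  stopifnot(inherits(table, "codon_usage_table"))
  if (threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]", call. = FALSE)
  }
  target <- stats::setNames(numeric(64L), ALL_CODONS)
  for (aa in names(AA_FAMILIES)) {
    fam <- AA_FAMILIES[[aa]]
    ff <- table$family_fraction[fam]
    if (sum(table$counts[fam]) == 0L && all(ff == 0)) next
    if (aa == "*" || length(fam) == 1L) {
      target[fam] <- ff
      if (length(fam) == 1L) target[fam] <- 1
      next
    }
    keep <- ff >= threshold
    if (!any(keep)) {
      stop("all codons of family '", aa, "' fall below threshold ",
           threshold, call. = FALSE)
    }
    target[fam[keep]] <- ff[keep] / sum(ff[keep])
  }
  structure(list(base = table, threshold = threshold,
                 target_fraction = target),
            class = "harmonized_target")
}

#' @export
print.harmonized_target <- function(x, ...) {
  zeroed <- low_frequency_codons(x$base, x$threshold)
  cat(sprintf("<harmonized_target> threshold %.3g: %d codon(s) zeroed\n",
              x$threshold, length(zeroed)))
  if (length(zeroed) > 0L) {
    cat("  zeroed:", paste(codon_as_rna(zeroed), collapse = " "), "\n")
  }
  invisible(x)
}

#' Convert a harmonized target back to a usage table
#'
#' Counts are apportioned by largest remainder on a fixed scale per family;
#' the `family_fraction` field carries the exact target fractions, so a
#' second [harmonize()] at the same threshold is an exact no-op.
#'
#' @param x a `harmonized_target`.
#' @param scale integer codon count assigned to each observed family.
#' @return a `codon_usage_table`.
#' @export
as_usage_table <- function(x, scale = 1e6L) {
  stopifnot(inherits(x, "harmonized_target"))
  counts <- stats::setNames(integer(64L), ALL_CODONS)
  for (aa in names(AA_FAMILIES)) {
    fam <- AA_FAMILIES[[aa]]
    tf <- x$target_fraction[fam]
    if (sum(tf) == 0) next
    counts[fam] <- largest_remainder(as.integer(scale), tf)
  }
  new_usage_table(counts, source_ids = x$base$source_ids,
                  family_fraction = x$target_fraction)
}

#' Compare two codon-usage tables
#'
#' @param a,b `codon_usage_table` objects.
#' @param threshold low-frequency threshold used for the `low_freq_diff`
#'   field.
#' @return object of class `codon_table_comparison`: `per_codon_delta`
#'   (`a` minus `b`), `inversions` (data frame of families whose preferred
#'   codon differs, ties broken lexicographically), `low_freq_diff`.
#' @export
compare_tables <- function(a, b, threshold = 0.08) {
  stopifnot(inherits(a, "codon_usage_table"), inherits(b, "codon_usage_table"))
  delta <- a$family_fraction - b$family_fraction
  inv <- list()
  for (aa in setdiff(names(AA_FAMILIES), "*")) {
    fam <- AA_FAMILIES[[aa]]
    if (length(fam) < 2L) next
    if (sum(a$counts[fam]) == 0L || sum(b$counts[fam]) == 0L) next
    pa <- fam[which.max(a$family_fraction[fam])]  # fam sorted -> lexicographic tie-break
    pb <- fam[which.max(b$family_fraction[fam])]
    if (pa != pb) {
      inv[[length(inv) + 1L]] <- data.frame(aa = aa, preferred_a = pa,
                                            preferred_b = pb,
                                            stringsAsFactors = FALSE)
    }
  }
  inv <- if (length(inv) > 0L) do.call(rbind, inv) else
    data.frame(aa = character(), preferred_a = character(),
               preferred_b = character(), stringsAsFactors = FALSE)
  la <- low_frequency_codons(a, threshold)
  lb <- low_frequency_codons(b, threshold)
  structure(list(per_codon_delta = delta, inversions = inv,
                 low_freq_diff = list(low_in_a_only = setdiff(la, lb),
                                      low_in_b_only = setdiff(lb, la)),
                 threshold = threshold),
            class = "codon_table_comparison")
}

#' @export
print.codon_table_comparison <- function(x, ...) {
  cat("<codon_table_comparison>\n")
  if (nrow(x$inversions) == 0L) {
    cat("  no inverted codon preferences\n")
  } else {
    for (i in seq_len(nrow(x$inversions))) {
      cat(sprintf("  %s: %s (a) vs %s (b)\n", x$inversions$aa[i],
                  codon_as_rna(x$inversions$preferred_a[i]),
                  codon_as_rna(x$inversions$preferred_b[i])))
    }
  }
  cat(sprintf("  low (<%g) in a only: %s\n", x$threshold,
              paste(codon_as_rna(x$low_freq_diff$low_in_a_only), collapse = " ")))
  cat(sprintf("  low (<%g) in b only: %s\n", x$threshold,
              paste(codon_as_rna(x$low_freq_diff$low_in_b_only), collapse = " ")))
  invisible(x)
}

#' Write a codon-usage table as TSV
#'
#' Dialect: header `codon aa count family_fraction`, 64 tab-separated data
#' rows keyed by DNA codons, fractions with 6 decimals.
#'
#' @param table a `codon_usage_table`.
#' @param file output path.
#' @export
write_usage_table <- function(table, file) {
  stopifnot(inherits(table, "codon_usage_table"))
  df <- as.data.frame(table)
  df$family_fraction <- sprintf("%.6f", df$family_fraction)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a codon-usage table from TSV
#'
#' Accepts the dialect written by [write_usage_table()].
#'
#' @param file input path.
#' @return a `codon_usage_table`.
#' @export
read_usage_table <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("codon", "aa", "count", "family_fraction")
  if (!all(need %in% names(df))) {
    stop("codon table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$codon <- chartr("U", "T", toupper(df$codon))
  if (!setequal(df$codon, ALL_CODONS) || nrow(df) != 64L) {
    stop("codon table must contain each of the 64 codons exactly once",
         call. = FALSE)
  }
  counts <- stats::setNames(as.integer(df$count), df$codon)
  ff <- stats::setNames(as.numeric(df$family_fraction), df$codon)
  new_usage_table(counts, family_fraction = ff)
}

# largest-remainder apportionment of n items over named fractions; floors
# first, leftovers by descending fractional remainder, ties by name order
largest_remainder <- function(n, fractions) {
  stopifnot(n >= 0L, all(fractions >= 0), sum(fractions) > 0)
  fractions <- fractions / sum(fractions)
  quota <- n * fractions
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0L) {
    ord <- order(-(quota - base), names(fractions))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}
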