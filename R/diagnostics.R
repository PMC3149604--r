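# Flaw detectors: GC content and windows, tandem codon repeats, AT/GC-rich
# runs, inverted-repeat hairpins, cryptic splice sites, restriction sites,
# and the aggregating diagnose() report.
#
# All detectors take a DNA string (or a seq_record / validated_cds) and
# report 1-based closed intervals on the forward strand.

as_dna <- function(x) {
  if (inherits(x, "validated_cds")) return(x$record$seq)
  if (inherits(x, "seq_record")) return(x$seq)
  normalize_dna(x)
}

#' Overall GC fraction of a sequence
#'
#' @param seq DNA string (or `seq_record` / `validated_cds`).
#' @return (G + C count) / length.
#' @export
gc_content <- function(seq) {
  seq <- as_dna(seq)
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  nchar(gsub("[AT]", "", seq)) / nchar(seq)
}

#' Centered sliding-window GC profile
#'
#' One window per center position at which the full window fits (windows
#' truncated at the sequence ends are excluded, not padded); for window
#' width `w` the window at center `c` covers
#' `[c - ceiling(w/2) + 1, c + floor(w/2)]`.  Centers whose GC deviates
#' from `target` by more than `tolerance` are flagged as violations.
#'
#' @param seq DNA string.
#' @param window window width in bp (default 40).
#' @param target GC target fraction (default 0.45).
#' @param tolerance allowed deviation (default 0.10, i.e. target +/- 10
#'   percentage points).
#' @return object of class `gc_window_profile`: `window`, `step` (always 1),
#'   `centers`, `gc`, `overall_gc`, `target`, `tolerance`, `violations`
#'   (center positions out of band).
#' @export
gc_window_profile <- function(seq, window = 40L, target = 0.45,
                              tolerance = 0.10) {
  seq <- as_dna(seq)
  n <- nchar(seq)
  window <- as.integer(window)
  if (window < 4L) stop("window must be >= 4 bp", call. = FALSE)
  if (window > n) stop("window (", window, ") exceeds sequence length (",
                       n, ")", call. = FALSE)
  is_gc <- split_bases(seq) %in% c("G", "C")
  cs <- c(0L, cumsum(is_gc))
  lo <- ceiling(window / 2)            # first center
  hi <- n - floor(window / 2)          # last center
  centers <- lo:hi
  starts <- centers - ceiling(window / 2) + 1L
  gc <- (cs[starts + window] - cs[starts]) / window
  viol <- centers[abs(gc - target) > tolerance + 1e-12]
  structure(list(window = window, step = 1L, centers = centers, gc = gc,
                 overall_gc = sum(is_gc) / n, target = target,
                 tolerance = tolerance, violations = viol),
            class = "gc_window_profile")
}

#' @export
print.gc_window_profile <- function(x, ...) {
  cat(sprintf(paste0("<gc_window_profile> %d bp windows: overall GC %.1f%%, ",
                     "%d/%d centers outside %.0f%% +/- %.0f%%\n"),
              x$window, 100 * x$overall_gc, length(x$violations),
              length(x$centers), 100 * x$target, 100 * x$tolerance))
  invisible(x)
}

#' @export
plot.gc_window_profile <- function(x, ...) {
  graphics::plot(x$centers, 100 * x$gc, type = "l", xlab = "position (bp)",
                 ylab = "GC (%)", ylim = c(0, 100), ...)
  graphics::abline(h = 100 * x$target, lty = 2)
  graphics::abline(h = 100 * (x$target + c(-1, 1) * x$tolerance), lty = 3)
  if (length(x$violations) > 0L) {
    graphics::rug(x$violations, col = "red")
  }
  invisible(x)
}

#' Maximal runs of identical consecutive codons
#'
#' Each maximal run of two or more identical codons is reported once, with
#' its start (in codons) and run length.  The attribute `n_pairs` carries
#' the alternative overlapping-pair count (`sum(length - 1)`).
#'
#' @param cds a `validated_cds`.
#' @return data frame with columns `start` (codon index), `length`, `codon`.
#' @export
find_tandem_codon_repeats <- function(cds) {
  stopifnot(inherits(cds, "validated_cds"))
  r <- rle(cds$codons)
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= 2L
  out <- data.frame(start = (ends - r$lengths + 1L)[keep],
                    length = r$lengths[keep], codon = r$values[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_pairs") <- sum(pmax(out$length - 1L, 0L))
  out
}

#' Maximal AT-rich / GC-rich runs
#'
#' A rich run is a maximal stretch of bases all drawn from one class
#' (`AT` = \{A, T\}, `GC` = \{G, C\}) of length at least `min_len`.
#'
#' @param seq DNA string.
#' @param min_len minimum run length in nt (default 8; must be >= 2).
#' @param classes which classes to report.
#' @return data frame with columns `start`, `end`, `class`.
#' @export
find_rich_runs <- function(seq, min_len = 8L, classes = c("AT", "GC")) {
  seq <- as_dna(seq)
  if (min_len < 2L) stop("min_len must be >= 2", call. = FALSE)
  classes <- match.arg(classes, several.ok = TRUE)
  cls <- ifelse(split_bases(seq) %in% c("A", "T"), "AT", "GC")
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_len & r$values %in% classes
  data.frame(start = (ends - r$lengths + 1L)[keep], end = ends[keep],
             class = r$values[keep], stringsAsFactors = FALSE)
}

#' Inverted-repeat (hairpin) hits
#'
#' Finds pairs of equal-length arms where the downstream arm is the reverse
#' complement of the upstream arm up to a mismatch budget of
#' `floor(max_mismatch_frac * stem)`, separated by a loop of at least
#' `min_loop` unpaired bases.  Reported hits are maximal: neither the
#' outward nor the inward one-base extension satisfies the (extended)
#' budget, the loop minimum, the stem cap and the sequence bounds.
#'
#' @param seq DNA string.
#' @param min_stem minimum stem (arm) length in nt; default 10.
#' @param max_mismatch_frac mismatch budget as a fraction of stem length
#'   (default 0.10).
#' @param min_loop minimum loop length in nt (default 4).
#' @param max_stem stem length cap; hits are never extended past it
#'   (default 60).
#' @return data frame with columns `a1_start`, `a1_end`, `a2_start`,
#'   `a2_end`, `stem`, `mismatches`, `loop`, sorted by `a1_start`.
#' @export
find_hairpins <- function(seq, min_stem = 10L, max_mismatch_frac = 0.10,
                          min_loop = 4L, max_stem = 60L) {
  seq <- as_dna(seq)
  stopifnot(min_stem >= 4L, max_mismatch_frac >= 0, max_mismatch_frac < 0.5,
            min_loop >= 1L, max_stem >= min_stem)
  m <- hairpin_scan_cpp(seq, as.integer(min_stem), max_mismatch_frac,
                        as.integer(min_loop), as.integer(max_stem))
  as.data.frame(m)
}

# --- splice-site model -----------------------------------------------------

pwm_from_seqs <- function(seqs, pseudocount, label) {
  if (length(seqs) == 0L) stop("empty ", label, " training set", call. = FALSE)
  seqs <- vapply(seqs, normalize_dna, character(1L), USE.NAMES = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop(label, " training sequences have ragged lengths", call. = FALSE)
  }
  L <- lens[1L]
  mat <- matrix(0, nrow = 4L, ncol = L, dimnames = list(c("A", "C", "G", "T")))
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  for (k in seq_len(L)) {
    tab <- table(factor(chars[, k], levels = c("A", "C", "G", "T")))
    mat[, k] <- (as.numeric(tab) + pseudocount) /
      (length(seqs) + 4 * pseudocount)
  }
  mat
}

#' Train a splice-site model
#'
#' Independent position-weight matrices for donor, branch and acceptor
#' signals with pseudocount smoothing; scanning scores are per-position
#' log-odds sums against the background base frequencies.  The default
#' score threshold of each signal is `threshold_frac` times the maximal
#' attainable (consensus self-) score.
#'
#' @param donors,branches,acceptors character vectors of training
#'   sequences, uniform length within each set.
#' @param pseudocount added to each base count per column (default 0.5).
#' @param background named base frequencies (default uniform).
#' @param threshold_frac fraction of the consensus self-score used as the
#'   hit threshold (default 0.8).
#' @return object of class `splice_site_model`.
#' @export
train_splice_model <- function(donors, branches, acceptors,
                               pseudocount = 0.5,
                               background = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                               threshold_frac = 0.8) {
  stopifnot(pseudocount >= 0, all(background > 0),
            abs(sum(background) - 1) < 1e-6)
  background <- background[c("A", "C", "G", "T")]
  sets <- list(donor = donors, branch = branches, acceptor = acceptors)
  signals <- lapply(names(sets), function(nm) {
    pwm <- pwm_from_seqs(sets[[nm]], pseudocount, nm)
    lw <- log2(pwm / background)
    list(pwm = pwm, logodds = lw,
         threshold = threshold_frac * sum(apply(lw, 2L, max)))
  })
  names(signals) <- names(sets)
  structure(list(signals = signals, background = background,
                 pseudocount = pseudocount, threshold_frac = threshold_frac),
            class = "splice_site_model")
}

#' @export
print.splice_site_model <- function(x, ...) {
  cat("<splice_site_model>\n")
  for (nm in names(x$signals)) {
    sig <- x$signals[[nm]]
    cons <- paste(rownames(sig$pwm)[apply(sig$pwm, 2L, which.max)],
                  collapse = "")
    cat(sprintf("  %-8s %d nt, consensus %s, threshold %.2f bits\n", nm,
                ncol(sig$pwm), cons, sig$threshold))
  }
  invisible(x)
}

#' Default yeast-like splice-site model
#'
#' Built from small consensus-derived training sets for the S. cerevisiae
#' donor (GTATGT), branch (TACTAAC) and acceptor (YAG) signals defined in
#' code; these are consensus motifs with minor variants, not a genomic
#' training corpus.
#'
#' @inheritParams train_splice_model
#' @return a `splice_site_model`.
#' @export
default_splice_model <- function(threshold_frac = 0.8) {
  donors <- c("GTATGT", "GTATGT", "GTATGT", "GTATGT", "GTAAGT", "GTATGA")
  branches <- c("TACTAAC", "TACTAAC", "TACTAAC", "TACTAAC", "TACTAAT",
                "AACTAAC")
  acceptors <- c("TAG", "TAG", "CAG", "CAG", "TAG", "CAG")
  train_splice_model(donors, branches, acceptors,
                     threshold_frac = threshold_frac)
}

#' Scan a sequence for cryptic splice sites
#'
#' Log-odds PWM score at every eligible forward-strand position; positions
#' scoring at or above the signal's threshold are reported.  With
#' `all_scores = TRUE` every eligible position is returned regardless of
#' threshold.
#'
#' @param seq DNA string.
#' @param model a `splice_site_model` (default [default_splice_model()]).
#' @param all_scores report all positions, not only hits.
#' @return data frame with columns `type`, `position`, `score`.
#' @export
scan_splice_sites <- function(seq, model = default_splice_model(),
                              all_scores = FALSE) {
  seq <- as_dna(seq)
  stopifnot(inherits(model, "splice_site_model"))
  b <- match(split_bases(seq), c("A", "C", "G", "T"))
  n <- length(b)
  out <- lapply(names(model$signals), function(nm) {
    sig <- model$signals[[nm]]
    L <- ncol(sig$logodds)
    if (n < L) return(NULL)
    np <- n - L + 1L
    sc <- numeric(np)
    for (k in seq_len(L)) sc <- sc + sig$logodds[, k][b[k:(k + np - 1L)]]
    keep <- if (all_scores) seq_len(np) else which(sc >= sig$threshold - 1e-12)
    if (length(keep) == 0L) return(NULL)
    data.frame(type = nm, position = keep, score = sc[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(type = character(), position = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  }
  out[order(out$position, out$type), , drop = FALSE]
}

#' Named default restriction-enzyme motif set
#'
#' The engineering set used when introducing unique sites (SacII, NruI,
#' AvrII, SalI, SpeI) plus the common flanking/cloning enzymes BstBI, XhoI
#' and EcoRI.
#'
#' @return named character vector, enzyme -> recognition motif.
#' @export
restriction_enzymes <- function() {
  c(SacII = "CCGCGG", NruI = "TCGCGA", AvrII = "CCTAGG", SalI = "GTCGAC",
    SpeI = "ACTAGT", BstBI = "TTCGAA", XhoI = "CTCGAG", EcoRI = "GAATTC")
}

#' Read an enzyme motif list from two-column TSV
#'
#' Expects tab-separated `name<TAB>motif` rows (a header line `name motif`
#' is allowed); motifs may use IUPAC degenerate codes.
#'
#' @param file input path.
#' @return named character vector, enzyme -> motif.
#' @export
read_enzyme_list <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("name", "motif"))
  if (nrow(df) > 0L && tolower(df$name[1L]) == "name") df <- df[-1L, ]
  for (m in df$motif) iupac_to_regex(m)  # validates
  stats::setNames(toupper(df$motif), df$name)
}

#' Forward-strand restriction-site positions
#'
#' Degenerate IUPAC codes are expanded; overlapping matches are counted and
#' a palindromic motif is reported once per start position.
#'
#' @param seq DNA string.
#' @param enzymes named character vector of IUPAC motifs (default
#'   [restriction_enzymes()]).
#' @return named list of integer vectors of 1-based match start positions.
#' @export
find_restriction_sites <- function(seq, enzymes = restriction_enzymes()) {
  seq <- as_dna(seq)
  stopifnot(length(enzymes) == 0L || !is.null(names(enzymes)))
  lapply(as.list(enzymes), function(motif) iupac_match_positions(seq, motif))
}

#' Aggregate flaw report for one coding sequence
#'
#' Runs every detector with the parameters in `config` against the
#' harmonized target derived from `table`, and collects the results.
#'
#' @param cds a `validated_cds`.
#' @param table host `codon_usage_table` (rare codons are those below
#'   `config$rare_threshold` within their family).
#' @param config an [opt_config()].
#' @return object of class `diagnostics_report`.
#' @export
diagnose <- function(cds, table, config = opt_config()) {
  stopifnot(inherits(cds, "validated_cds"),
            inherits(table, "codon_usage_table"),
            inherits(config, "opt_config"))
  seq <- cds$record$seq
  rare <- low_frequency_codons(table, config$rare_threshold)
  sense <- sense_codons_of(cds)
  rare_idx <- which(sense %in% rare)
  rare_hits <- data.frame(position = rare_idx, codon = sense[rare_idx],
                          stringsAsFactors = FALSE)
  report <- structure(list(
    id = cds$record$id,
    rare_codon_hits = rare_hits,
    tandem_repeat_runs = find_tandem_codon_repeats(cds),
    rich_runs = find_rich_runs(seq, config$rich_min_len),
    hairpins = find_hairpins(seq, config$min_stem, config$max_mismatch_frac,
                             config$min_loop, config$max_stem),
    splice_hits = scan_splice_sites(seq, config$splice_model),
    restriction_hits = find_restriction_sites(seq, config$enzymes),
    gc = gc_window_profile(seq, config$gc_window, config$gc_target,
                           config$gc_tolerance),
    config = config), class = "diagnostics_report")
  report
}

#' @export
summary.diagnostics_report <- function(object, ...) {
  c(rare_codons = nrow(object$rare_codon_hits),
    tandem_repeats = nrow(object$tandem_repeat_runs),
    rich_runs = nrow(object$rich_runs),
    hairpins = nrow(object$hairpins),
    splice_sites = nrow(object$splice_hits),
    restriction_sites = sum(lengths(object$restriction_hits)),
    gc_window_violations = length(object$gc$violations))
}

#' @export
print.diagnostics_report <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("<diagnostics_report> %s  (overall GC %.1f%%)\n", x$id,
              100 * x$gc$overall_gc))
  for (nm in names(s)) cat(sprintf("  %-22s %d\n", nm, s[[nm]]))
  invisible(x)
}

#' Serialize a diagnostics report
#'
#' Writes `report.json` plus one TSV per flaw class into `dir`.  Interval
#' tables carry a header comment declaring the 1-based closed-interval
#' convention.
#'
#' @param report a `diagnostics_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "diagnostics_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- summary(report)
  json <- list(id = report$id, summary = as.list(s),
               overall_gc = report$gc$overall_gc,
               coordinates = "1-based, closed intervals",
               rare_codon_hits = report$rare_codon_hits,
               tandem_repeat_runs = report$tandem_repeat_runs,
               rich_runs = report$rich_runs, hairpins = report$hairpins,
               splice_hits = report$splice_hits,
               restriction_hits = report$restriction_hits,
               gc_violation_centers = report$gc$violations)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  tabs <- list(tandem_repeats = report$tandem_repeat_runs,
               rich_runs = report$rich_runs, hairpins = report$hairpins,
               splice_sites = report$splice_hits,
               rare_codons = report$rare_codon_hits)
  for (nm in names(tabs)) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    con <- file(f, "w")
    writeLines("# coordinates: 1-based, closed intervals", con)
    utils::write.table(tabs[[nm]], con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  invisible(dir)
}
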