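# Synonymous-codon redesign: largest-remainder allocation against a
# harmonized target, deterministic GC calibration of the allocation,
# synonymous carving of required restriction sites, and seeded
# simulated-annealing repair of the placement under hard constraints
# (protein identity, rare-codon exclusion, forbidden motifs, required-site
# uniqueness, GC windows) with soft penalties for hairpins, tandem repeats,
# rich runs, splice sites and frequency divergence.

CODON_GC <- vapply(ALL_CODONS, function(cd) {
  sum(strsplit(cd, "", fixed = TRUE)[[1L]] %in% c("G", "C"))
}, numeric(1L))

#' Optimization configuration
#'
#' Collects every threshold, detector parameter, motif list, penalty weight
#' and annealing setting used by [diagnose()] and [optimize_cds()].
#'
#' @param rare_threshold within-family frequency below which a codon is
#'   excluded from the redesign (strict `<`; default 0.08).
#' @param gc_target,gc_tolerance,gc_window GC window constraint: every
#'   `gc_window` bp window must stay within `gc_target +/- gc_tolerance`
#'   (defaults 0.45, 0.10, 40).
#' @param gc_overall_tol how close the calibrated allocation brings the
#'   overall GC fraction to `gc_target` (default 0.004, i.e. the overall GC
#'   rounds to the target percentage).
#' @param min_stem,max_mismatch_frac,min_loop,max_stem hairpin detector
#'   parameters (see [find_hairpins()]).
#' @param rich_min_len minimum AT/GC-rich run length (default 8 nt).
#' @param splice_model a [train_splice_model()] object.
#' @param enzymes named motif vector reported by [diagnose()].
#' @param forbidden_motifs IUPAC motifs that must not occur in the output.
#' @param required_unique_sites named character vector (enzyme -> motif) of
#'   sites to introduce exactly once by synonymous substitution, or a data
#'   frame with columns `enzyme`, `motif` and optional `locus` (preferred
#'   nucleotide start, `NA` = anywhere).
#' @param locked_codon_positions codon indices the optimizer must not touch.
#' @param penalty_weights named nonnegative weights per flaw class; classes:
#'   `rare_codon`, `tandem_repeat`, `rich_run`, `hairpin`, `splice_site`,
#'   `gc_window`, `forbidden_motif`, `freq_divergence`.
#' @param max_iterations proposal budget for the annealer (default 200000).
#' @param seed integer seed; every random draw flows from it.
#' @param t0,alpha annealing start temperature and per-accepted-move cooling
#'   factor (defaults 1.0, 0.995).
#' @param stall proposals without an accepted move after which resampling
#'   moves are enabled (default 500).
#' @param patience proposals without improvement of the best penalty after
#'   which the run stops once hard constraints hold (default 3000).
#' @param hot_prob probability that a move proposal starts at a position
#'   covered by a current violation (default 0.9).
#' @return object of class `opt_config`.
#' @export
opt_config <- function(rare_threshold = 0.08, gc_target = 0.45,
                       gc_tolerance = 0.10, gc_window = 40L,
                       gc_overall_tol = 0.004,
                       min_stem = 10L, max_mismatch_frac = 0.10,
                       min_loop = 4L, max_stem = 60L, rich_min_len = 8L,
                       splice_model = default_splice_model(),
                       enzymes = restriction_enzymes(),
                       forbidden_motifs = character(),
                       required_unique_sites = character(),
                       locked_codon_positions = integer(),
                       penalty_weights = NULL,
                       max_iterations = 200000L, seed = 1L,
                       t0 = 1.0, alpha = 0.995, stall = 500L,
                       patience = 3000L, hot_prob = 0.9) {
  default_w <- c(rare_codon = 1, tandem_repeat = 1, rich_run = 1, hairpin = 1,
                 splice_site = 1, gc_window = 1, forbidden_motif = 1,
                 freq_divergence = 1)
  if (!is.null(penalty_weights)) {
    bad <- setdiff(names(penalty_weights), names(default_w))
    if (length(bad) > 0L) stop("unknown penalty class: ",
                               paste(bad, collapse = ", "), call. = FALSE)
    default_w[names(penalty_weights)] <- penalty_weights
  }
  stopifnot(rare_threshold >= 0, rare_threshold <= 1,
            gc_target >= 0, gc_target <= 1,
            gc_tolerance >= 0, gc_tolerance <= 1,
            all(default_w >= 0), length(seed) == 1L, is.finite(seed),
            t0 > 0, alpha > 0, alpha <= 1)
  structure(list(rare_threshold = rare_threshold, gc_target = gc_target,
                 gc_tolerance = gc_tolerance,
                 gc_window = as.integer(gc_window),
                 gc_overall_tol = gc_overall_tol,
                 min_stem = as.integer(min_stem),
                 max_mismatch_frac = max_mismatch_frac,
                 min_loop = as.integer(min_loop),
                 max_stem = as.integer(max_stem),
                 rich_min_len = as.integer(rich_min_len),
                 splice_model = splice_model, enzymes = enzymes,
                 forbidden_motifs = forbidden_motifs,
                 required_unique_sites = required_unique_sites,
                 locked_codon_positions = as.integer(locked_codon_positions),
                 penalty_weights = default_w,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed), t0 = t0, alpha = alpha,
                 stall = as.integer(stall), patience = as.integer(patience),
                 hot_prob = hot_prob),
            class = "opt_config")
}

#' @export
print.opt_config <- function(x, ...) {
  cat(sprintf(paste0("<opt_config> rare < %.3g, GC %d bp windows at ",
                     "%.0f%% +/- %.0f%%, seed %d, max %d iterations\n"),
              x$rare_threshold, x$gc_window, 100 * x$gc_target,
              100 * x$gc_tolerance, x$seed, x$max_iterations))
  invisible(x)
}

required_sites_df <- function(required) {
  if (is.data.frame(required)) {
    stopifnot(all(c("enzyme", "motif") %in% names(required)))
    if (is.null(required$locus)) required$locus <- NA_integer_
    return(required)
  }
  if (length(required) == 0L) {
    return(data.frame(enzyme = character(), motif = character(),
                      locus = integer(), stringsAsFactors = FALSE))
  }
  stopifnot(!is.null(names(required)))
  data.frame(enzyme = names(required), motif = unname(required),
             locus = NA_integer_, stringsAsFactors = FALSE)
}

#' Largest-remainder codon allocation
#'
#' Apportions each amino acid's occurrence count over the codons with
#' nonzero target fraction: integer floors of the quotas first, leftovers
#' by descending fractional remainder, equal remainders broken by codon
#' order.  Realized fractions deviate from the target by less than `1/n`
#' per codon.
#'
#' @param aa_counts named integer vector, amino acid -> occurrence count.
#' @param target a [harmonize()] target.
#' @return object of class `codon_allocation`: named list per amino acid of
#'   codon -> integer count.
#' @export
allocate_codon_counts <- function(aa_counts, target) {
  stopifnot(inherits(target, "harmonized_target"), all(aa_counts >= 0))
  out <- lapply(names(aa_counts), function(aa) {
    fam <- AA_FAMILIES[[aa]]
    if (is.null(fam)) stop("unknown amino acid '", aa, "'", call. = FALSE)
    tf <- target$target_fraction[fam]
    if (sum(tf) <= 0) {
      stop("amino acid '", aa, "' absent from target (no retained codons)",
           call. = FALSE)
    }
    keep <- tf > 0
    largest_remainder(as.integer(aa_counts[[aa]]),
                      stats::setNames(tf[keep], fam[keep]))
  })
  names(out) <- names(aa_counts)
  structure(out, class = "codon_allocation")
}

#' @export
print.codon_allocation <- function(x, ...) {
  cat("<codon_allocation>\n")
  for (aa in names(x)) {
    cat(sprintf("  %s (n=%d): %s\n", aa, sum(x[[aa]]),
                paste(sprintf("%s %d", names(x[[aa]]), x[[aa]]),
                      collapse = "  ")))
  }
  invisible(x)
}

# exact change in frequency divergence when one count moves x -> y in
# family `fam` (counts `cnt`, target `tf`, family weight nf/N already applied
# by caller)
.div_of <- function(cnt, tf) 0.5 * sum(abs(cnt / max(sum(cnt), 1L) - tf))

# deterministic GC calibration: shift allocation counts between retained
# codons of a family until the overall GC fraction is within
# gc_target +/- gc_overall_tol, choosing at each step the unit shift with
# the least divergence increase per base of GC gained
calibrate_gc_allocation <- function(alloc, target, fixed_gc, fixed_len,
                                    config) {
  goal <- config$gc_target
  tol <- config$gc_overall_tol
  total_len <- fixed_len + 3L * sum(vapply(alloc, sum, numeric(1L)))
  gc_now <- function() {
    (fixed_gc + sum(vapply(names(alloc), function(aa) {
      sum(alloc[[aa]] * CODON_GC[names(alloc[[aa]])])
    }, numeric(1L)))) / total_len
  }
  for (step in seq_len(2L * total_len)) {
    dev <- gc_now() - goal
    if (abs(dev) <= tol) break
    want <- if (dev > 0) -1L else 1L  # needed sign of gc change
    best <- NULL
    for (aa in names(alloc)) {
      cnt <- alloc[[aa]]
      if (length(cnt) < 2L) next
      fam <- names(cnt)
      tf <- target$target_fraction[fam]
      tf <- tf / sum(tf)
      d0 <- .div_of(cnt, tf)
      for (xi in seq_along(fam)) {
        if (cnt[xi] == 0L) next
        for (yi in seq_along(fam)) {
          dgc <- CODON_GC[fam[yi]] - CODON_GC[fam[xi]]
          if (yi == xi || sign(dgc) != want) next
          cnt2 <- cnt
          cnt2[xi] <- cnt2[xi] - 1L
          cnt2[yi] <- cnt2[yi] + 1L
          cost <- (.div_of(cnt2, tf) - d0) / abs(dgc)
          key <- paste(aa, fam[xi], fam[yi])
          if (is.null(best) || cost < best$cost - 1e-12 ||
              (abs(cost - best$cost) <= 1e-12 && key < best$key)) {
            best <- list(cost = cost, aa = aa, xi = xi, yi = yi, key = key)
          }
        }
      }
    }
    if (is.null(best)) break  # no shift can move GC in the needed direction
    alloc[[best$aa]][best$xi] <- alloc[[best$aa]][best$xi] - 1L
    alloc[[best$aa]][best$yi] <- alloc[[best$aa]][best$yi] + 1L
  }
  alloc
}

#' Introduce required restriction sites by synonymous substitution
#'
#' For each required motif, enumerates every placement where the motif can
#' be realized purely by synonymous codon changes, preferring an
#' already-present occurrence, then the placement whose codons have the
#' highest target fractions (ties: leftmost).  Covered codon positions are
#' locked.  Uniqueness of each motif is enforced later by the optimizer as
#' a hard constraint.
#'
#' @param cds a `validated_cds`.
#' @param required_sites named vector or data frame (see [opt_config()]).
#' @param target a `harmonized_target` used to score codon choices.
#' @return list with `cds` (possibly modified), `locked` (codon indices) and
#'   `sites` (data frame `enzyme`, `motif`, `start`).
#' @export
carve_required_sites <- function(cds, required_sites, target) {
  stopifnot(inherits(cds, "validated_cds"),
            inherits(target, "harmonized_target"))
  req <- required_sites_df(required_sites)
  codons <- cds$codons
  n_sense <- if (cds$has_terminal_stop) cds$codon_count - 1L else
    cds$codon_count
  locked <- integer(0)
  placed <- data.frame(enzyme = character(), motif = character(),
                       start = integer(), stringsAsFactors = FALSE)
  map <- Biostrings::IUPAC_CODE_MAP
  for (r in seq_len(nrow(req))) {
    motif <- chartr("U", "T", toupper(req$motif[r]))
    mlen <- nchar(motif)
    mset <- strsplit(map[split_bases(motif)], "", fixed = TRUE)
    seq_now <- paste(codons, collapse = "")
    existing <- iupac_match_positions(seq_now, motif)
    best <- NULL
    for (p in seq_len(3L * n_sense - mlen + 1L)) {
      c1 <- (p - 1L) %/% 3L + 1L
      c2 <- (p + mlen - 2L) %/% 3L + 1L
      if (c2 > n_sense) next
      if (any(seq(c1, c2) %in% locked)) next
      choice <- character(c2 - c1 + 1L)
      score <- 0
      ok <- TRUE
      for (ci in c1:c2) {
        aa <- GENCODE[[codons[ci]]]
        cands <- AA_FAMILIES[[aa]]
        for (off in 1:3) {               # constrain overlapping bases
          g <- (ci - 1L) * 3L + off      # global nt position of codon base
          k <- g - p + 1L                # motif offset
          if (k >= 1L && k <= mlen) {
            cands <- cands[substr(cands, off, off) %in% mset[[k]]]
          }
        }
        if (length(cands) == 0L) { ok <- FALSE; break }
        tf <- target$target_fraction[cands]
        pick <- cands[order(-tf, cands)][1L]
        choice[ci - c1 + 1L] <- pick
        score <- score + log(target$target_fraction[[pick]] + 1e-9)
      }
      if (!ok) next
      pre_existing <- p %in% existing
      pref <- if (!is.na(req$locus[r])) -abs(p - req$locus[r]) else 0
      key <- c(as.numeric(pre_existing), pref, score, -p)
      if (is.null(best) || is_key_greater(key, best$key)) {
        best <- list(key = key, p = p, c1 = c1, c2 = c2, choice = choice)
      }
    }
    if (is.null(best)) {
      stop("required motif '", motif, "' (", req$enzyme[r],
           ") is not encodable by synonymous substitution anywhere",
           call. = FALSE)
    }
    codons[best$c1:best$c2] <- best$choice
    locked <- sort(union(locked, best$c1:best$c2))
    placed <- rbind(placed, data.frame(enzyme = req$enzyme[r], motif = motif,
                                       start = best$p,
                                       stringsAsFactors = FALSE))
  }
  list(cds = cds_from_codons(codons, cds), locked = locked, sites = placed)
}

is_key_greater <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i] + 1e-12) return(TRUE)
    if (a[i] < b[i] - 1e-12) return(FALSE)
  }
  FALSE
}

# --- penalty evaluation ----------------------------------------------------

# precomputed evaluation context; everything the inner loop needs
make_eval_ctx <- function(target, config, locked, n_sense, sites) {
  motifs <- config$forbidden_motifs
  req <- sites
  list(target = target$target_fraction,
       rare_set = names(target$target_fraction)[
         target$target_fraction == 0 &
           GENCODE[names(target$target_fraction)] != "*"],
       w = config$penalty_weights, config = config,
       locked = locked, n_sense = n_sense,
       unlocked = setdiff(seq_len(n_sense), locked),
       forbidden_re = vapply(motifs, iupac_to_regex, character(1L)),
       req_motifs = req$motif,
       req_re = vapply(req$motif, iupac_to_regex, character(1L)),
       req_start = req$start)
}

count_re <- function(seq, re) {
  m <- gregexpr(paste0("(?=", re, ")"), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

# full penalty evaluation of a codon vector (sense codons + optional stop)
eval_penalty <- function(codons, ctx) {
  cfg <- ctx$config
  seq <- paste(codons, collapse = "")
  bases <- split_bases(seq)
  n <- length(bases)
  counts <- c(rare_codon = 0, tandem_repeat = 0, rich_run = 0, hairpin = 0,
              splice_site = 0, gc_window = 0, forbidden_motif = 0)
  hotmask <- logical(n)  # nt positions covered by violations
  mark <- function(from, to) {
    hotmask[pmax(from, 1L):pmin(to, n)] <<- TRUE
  }

  sense_idx <- seq_len(ctx$n_sense)
  unlocked <- ctx$unlocked
  rare_pos <- unlocked[codons[unlocked] %in% ctx$rare_set]
  counts["rare_codon"] <- length(rare_pos)
  if (length(rare_pos) > 0L) hotmask[3L * rare_pos - 1L] <- TRUE

  r <- rle(codons)
  rep_keep <- which(r$lengths >= 2L)
  counts["tandem_repeat"] <- length(rep_keep)
  if (length(rep_keep) > 0L) {
    ends <- cumsum(r$lengths)
    for (i in rep_keep) mark(3L * (ends[i] - r$lengths[i]) + 1L, 3L * ends[i])
  }

  cls <- bases %in% c("A", "T")
  rr <- rle(cls)
  rr_keep <- which(rr$lengths >= cfg$rich_min_len)
  counts["rich_run"] <- length(rr_keep)
  if (length(rr_keep) > 0L) {
    ends <- cumsum(rr$lengths)
    for (i in rr_keep) mark(ends[i] - rr$lengths[i] + 1L, ends[i])
  }

  hp <- hairpin_scan_cpp(seq, cfg$min_stem, cfg$max_mismatch_frac,
                         cfg$min_loop, cfg$max_stem)
  counts["hairpin"] <- nrow(hp)
  if (nrow(hp) > 0L) {
    for (i in seq_len(nrow(hp))) {
      mark(hp[i, 1L], hp[i, 2L])
      mark(hp[i, 3L], hp[i, 4L])
    }
  }

  b <- match(bases, c("A", "C", "G", "T"))
  for (nm in names(cfg$splice_model$signals)) {
    sig <- cfg$splice_model$signals[[nm]]
    L <- ncol(sig$logodds)
    if (n < L) next
    np <- n - L + 1L
    sc <- numeric(np)
    for (k in seq_len(L)) sc <- sc + sig$logodds[, k][b[k:(k + np - 1L)]]
    sh <- which(sc >= sig$threshold - 1e-12)
    counts["splice_site"] <- counts["splice_site"] + length(sh)
    for (p in sh) mark(p, p + L - 1L)
  }

  is_gc <- !cls
  cs <- c(0L, cumsum(is_gc))
  w <- cfg$gc_window
  if (n >= w) {
    starts <- 1L:(n - w + 1L)
    gcw <- (cs[starts + w] - cs[starts]) / w
    bad <- which(abs(gcw - cfg$gc_target) > cfg$gc_tolerance + 1e-12)
    counts["gc_window"] <- length(bad)
    if (length(bad) > 0L) {
      hotmask[unique(c(outer(bad, 0:(w - 1L), "+")))] <- TRUE
    }
  }

  for (re in ctx$forbidden_re) {
    pos <- count_re(seq, re)
    counts["forbidden_motif"] <- counts["forbidden_motif"] + length(pos)
    for (p in pos) mark(p, p + 5L)
  }
  if (length(ctx$req_re) > 0L) {
    for (i in seq_along(ctx$req_re)) {
      pos <- count_re(seq, ctx$req_re[i])
      extra <- setdiff(pos, ctx$req_start[i])
      miss <- !(ctx$req_start[i] %in% pos)
      counts["forbidden_motif"] <- counts["forbidden_motif"] +
        length(extra) + as.integer(miss)
      for (p in extra) mark(p, p + nchar(ctx$req_motifs[i]) - 1L)
    }
  }

  # frequency divergence: per-family total variation, occurrence-weighted
  sense <- codons[sense_idx]
  div <- 0
  tab <- table(factor(sense, levels = SENSE_CODONS))
  for (aa in setdiff(names(AA_FAMILIES), "*")) {
    fam <- AA_FAMILIES[[aa]]
    nf <- sum(tab[fam])
    if (nf == 0L) next
    tf <- ctx$target[fam]
    tfs <- sum(tf)
    if (tfs <= 0) next
    div <- div + (nf / ctx$n_sense) *
      0.5 * sum(abs(as.numeric(tab[fam]) / nf - tf / tfs))
  }

  hard <- sum(counts[c("rare_codon", "gc_window", "forbidden_motif")])
  total <- sum(ctx$w[names(counts)] * counts) + ctx$w[["freq_divergence"]] * div
  hot_codons <- unique((which(hotmask) - 1L) %/% 3L + 1L)
  list(counts = counts, div = div, total = total, hard = hard,
       hot = hot_codons[hot_codons <= ctx$n_sense])
}

#' Penalty breakdown of a coding sequence
#'
#' Deterministic multi-objective score: weighted per-class violation counts
#' (matching [diagnose()] under the same configuration) plus the
#' occurrence-weighted total-variation distance between realized and target
#' within-family codon frequencies.
#'
#' @param cds a `validated_cds`.
#' @param target a `harmonized_target`.
#' @param config an [opt_config()].
#' @return object of class `penalty_breakdown`: `counts`,
#'   `frequency_divergence`, `contributions`, `total`.
#' @export
codon_penalty <- function(cds, target, config = opt_config()) {
  stopifnot(inherits(cds, "validated_cds"),
            inherits(target, "harmonized_target"))
  n_sense <- if (cds$has_terminal_stop) cds$codon_count - 1L else
    cds$codon_count
  ctx <- make_eval_ctx(target, config, config$locked_codon_positions,
                       n_sense, required_sites_df(config$required_unique_sites))
  # required-site starts are unknown outside optimize(); score occurrences
  ctx$req_start <- rep(-1L, length(ctx$req_re))
  ev <- eval_penalty(cds$codons, ctx)
  contributions <- c(config$penalty_weights[names(ev$counts)] * ev$counts,
                     freq_divergence =
                       config$penalty_weights[["freq_divergence"]] * ev$div)
  structure(list(counts = ev$counts, frequency_divergence = ev$div,
                 contributions = contributions, total = ev$total),
            class = "penalty_breakdown")
}

#' @export
print.penalty_breakdown <- function(x, ...) {
  cat(sprintf("<penalty_breakdown> total %.4f\n", x$total))
  for (nm in names(x$counts)) {
    cat(sprintf("  %-16s %4d  (weighted %.3f)\n", nm, x$counts[[nm]],
                x$contributions[[nm]]))
  }
  cat(sprintf("  %-16s %.4f  (weighted %.4f)\n", "freq_divergence",
              x$frequency_divergence, x$contributions[["freq_divergence"]]))
  invisible(x)
}

# --- the optimizer ---------------------------------------------------------

#' Redesign the synonymous codons of a coding sequence
#'
#' Pipeline: harmonize the host table (zeroing codons below
#' `rare_threshold`), carve required restriction sites synonymously and
#' lock them, apportion each amino acid's unlocked occurrences over the
#' retained codons by largest remainder, calibrate the allocation's overall
#' GC to `gc_target`, place the allocated codons by a seeded shuffle, and
#' repair the placement by simulated annealing.  Moves either swap the
#' codons of two same-amino-acid positions (allocation-preserving) or,
#' after a stall, resample one position from the target distribution.
#' Hard constraints at termination: protein identity, no zero-target codon
#' outside locked positions, no forbidden motifs, each required site
#' present exactly once, every GC window within tolerance.  The same seed
#' reproduces the identical output sequence.
#'
#' @param cds a `validated_cds` (a terminal stop codon is left untouched).
#' @param table host `codon_usage_table`.
#' @param config an [opt_config()].
#' @return object of class `codon_opt`; see Details.  `success` is `FALSE`
#'   when a hard constraint could not be satisfied within
#'   `max_iterations`; the best-found sequence and residual violations are
#'   returned either way.
#' @export
optimize_cds <- function(cds, table, config = opt_config()) {
  stopifnot(inherits(cds, "validated_cds"),
            inherits(table, "codon_usage_table"),
            inherits(config, "opt_config"))
  target <- harmonize(table, config$rare_threshold)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  carved <- carve_required_sites(cds, config$required_unique_sites, target)
  locked <- sort(union(carved$locked, config$locked_codon_positions))
  n_sense <- if (cds$has_terminal_stop) cds$codon_count - 1L else
    cds$codon_count
  codons <- carved$cds$codons
  stop_codon <- if (cds$has_terminal_stop) codons[cds$codon_count] else NULL

  unlocked <- setdiff(seq_len(n_sense), locked)
  aa_vec <- unname(GENCODE[codons[seq_len(n_sense)]])
  aa_counts <- table(factor(aa_vec[unlocked], levels = sort(unique(aa_vec))))
  aa_counts <- aa_counts[aa_counts > 0L]
  alloc <- allocate_codon_counts(stats::setNames(as.integer(aa_counts),
                                                 names(aa_counts)), target)

  fixed_idx <- c(locked, if (cds$has_terminal_stop) cds$codon_count)
  fixed_gc <- sum(CODON_GC[codons[fixed_idx]])
  alloc <- calibrate_gc_allocation(alloc, target, fixed_gc,
                                   3L * length(fixed_idx), config)

  # seeded initial placement: shuffle each amino acid's allocated multiset
  for (aa in sort(names(alloc))) {
    pos <- unlocked[aa_vec[unlocked] == aa]
    pool <- rep(names(alloc[[aa]]), alloc[[aa]])
    codons[pos] <- if (length(pool) > 1L) sample(pool) else pool
  }

  ctx <- make_eval_ctx(target, config, locked, n_sense, carved$sites)
  pos_by_aa <- split(unlocked, aa_vec[unlocked])
  resample_ok <- vapply(names(pos_by_aa), function(aa) {
    sum(target$target_fraction[AA_FAMILIES[[aa]]] > 0) > 1L
  }, logical(1L))

  cur <- eval_penalty(codons, ctx)
  best <- list(codons = codons, ev = cur)
  trace <- cur$total
  accepted <- 0L
  since_accept <- 0L
  since_best <- 0L
  temp <- config$t0
  iter <- 0L

  while (iter < config$max_iterations) {
    iter <- iter + 1L
    if (best$ev$total <= 1e-12) break
    if (best$ev$hard == 0L && since_best >= config$patience) break

    use_resample <- since_accept >= config$stall
    hot <- intersect(cur$hot, unlocked)
    p1 <- if (length(hot) > 0L && stats::runif(1L) < config$hot_prob) {
      hot[sample.int(length(hot), 1L)]
    } else if (length(unlocked) > 0L) {
      unlocked[sample.int(length(unlocked), 1L)]
    } else break
    aa <- aa_vec[p1]
    cand <- codons

    moved <- FALSE
    if (!use_resample || stats::runif(1L) < 0.5) {
      mates <- pos_by_aa[[aa]]
      mates <- mates[codons[mates] != codons[p1]]
      if (length(mates) > 0L) {
        p2 <- mates[sample.int(length(mates), 1L)]
        tmp <- cand[p1]; cand[p1] <- cand[p2]; cand[p2] <- tmp
        moved <- TRUE
      }
    }
    if (!moved && use_resample && isTRUE(resample_ok[[aa]])) {
      fam <- AA_FAMILIES[[aa]]
      tf <- target$target_fraction[fam]
      opts <- fam[tf > 0 & fam != codons[p1]]
      if (length(opts) > 0L) {
        cand[p1] <- opts[sample.int(length(opts), 1L,
                                    prob = tf[opts] / sum(tf[opts]))]
        moved <- TRUE
      }
    }
    if (!moved) { since_accept <- since_accept + 1L
                  since_best <- since_best + 1L; next }

    ev <- eval_penalty(cand, ctx)
    delta <- ev$total - cur$total
    if (delta <= 0 || stats::runif(1L) < exp(-delta / max(temp, 1e-9))) {
      codons <- cand
      cur <- ev
      accepted <- accepted + 1L
      since_accept <- 0L
      temp <- temp * config$alpha
      if (ev$total < best$ev$total - 1e-12) {
        best <- list(codons = codons, ev = ev)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      trace <- c(trace, best$ev$total)
    } else {
      since_accept <- since_accept + 1L
      since_best <- since_best + 1L
    }
  }

  out_cds <- cds_from_codons(best$codons, cds)
  run_cfg <- config
  run_cfg$locked_codon_positions <- locked
  report_before <- diagnose(cds, table, run_cfg)
  report_after <- diagnose(out_cds, table, run_cfg)
  success <- best$ev$hard == 0L &&
    identical(translate_cds(out_cds), translate_cds(cds))
  residual <- best$ev$counts[c("rare_codon", "gc_window", "forbidden_motif")]
  structure(list(input_cds = cds, output_cds = out_cds,
                 report_before = report_before, report_after = report_after,
                 allocation = alloc, sites = carved$sites, locked = locked,
                 penalty_trace = trace,
                 penalty_before = eval_to_breakdown(
                   eval_penalty(cds$codons, ctx), config),
                 penalty_after = eval_to_breakdown(best$ev, config),
                 iterations = iter, accepted = accepted,
                 table = table, config = config, seed = config$seed,
                 success = success,
                 residual_violations = residual[residual > 0]),
            class = "codon_opt")
}

eval_to_breakdown <- function(ev, config) {
  contributions <- c(config$penalty_weights[names(ev$counts)] * ev$counts,
                     freq_divergence =
                       config$penalty_weights[["freq_divergence"]] * ev$div)
  structure(list(counts = ev$counts, frequency_divergence = ev$div,
                 contributions = contributions, total = ev$total),
            class = "penalty_breakdown")
}

#' @export
print.codon_opt <- function(x, ...) {
  cat(sprintf("<codon_opt> %s: %d codons, seed %d, %s\n",
              x$input_cds$record$id, x$input_cds$codon_count, x$seed,
              if (x$success) "all hard constraints satisfied"
              else "FAILED hard constraints"))
  cat(sprintf("  penalty %.3f -> %.3f over %d accepted / %d proposed moves\n",
              x$penalty_before$total, x$penalty_after$total, x$accepted,
              x$iterations))
  cat(sprintf("  GC %.1f%% -> %.1f%%\n",
              100 * x$report_before$gc$overall_gc,
              100 * x$report_after$gc$overall_gc))
  if (!x$success && length(x$residual_violations) > 0L) {
    cat("  residual:", paste(names(x$residual_violations),
                             x$residual_violations, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.codon_opt <- function(object, ...) {
  data.frame(metric = c("codons", "gc_before", "gc_after",
                        names(summary(object$report_before))),
             before = c(object$input_cds$codon_count,
                        object$report_before$gc$overall_gc, NA,
                        unname(summary(object$report_before))),
             after = c(object$output_cds$codon_count, NA,
                       object$report_after$gc$overall_gc,
                       unname(summary(object$report_after))))
}

#' @export
plot.codon_opt <- function(x, ...) {
  op <- graphics::par(mfrow = c(2L, 1L), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(seq_along(x$penalty_trace), x$penalty_trace, type = "s",
                 xlab = "accepted move", ylab = "best penalty",
                 main = "annealing trace")
  gcb <- x$report_before$gc
  gca <- x$report_after$gc
  graphics::plot(gcb$centers, 100 * gcb$gc, type = "l", col = "grey50",
                 xlab = "position (bp)", ylab = "GC (%)",
                 main = sprintf("%d bp GC windows", gcb$window))
  graphics::lines(gca$centers, 100 * gca$gc, col = "black")
  graphics::abline(h = 100 * (gca$target + c(-1, 0, 1) * gca$tolerance),
                   lty = c(3, 2, 3))
  invisible(x)
}

#' Independent verification of an optimization result
#'
#' Re-derives every hard-constraint check from the result's input and
#' output sequences alone, without trusting the optimizer's bookkeeping:
#' protein identity, rare-codon exclusion outside locked positions, GC
#' window compliance, forbidden-motif absence, required-site uniqueness,
#' and agreement of a fresh [diagnose()] with the recorded after-report.
#'
#' @param result a `codon_opt`.
#' @return object of class `codon_opt_verification` with elements `pass`
#'   and `checks` (data frame of check, ok, detail).
#' @export
verify_result <- function(result) {
  stopifnot(inherits(result, "codon_opt"))
  cfg <- result$config
  out <- result$output_cds
  checks <- list()
  add <- function(name, ok, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(check = name, ok = ok,
                                                 detail = detail,
                                                 stringsAsFactors = FALSE)
  }
  pi <- translate_cds(out) == translate_cds(result$input_cds)
  mism <- if (!pi) {
    a <- split_bases(translate_cds(out))
    b <- split_bases(translate_cds(result$input_cds))
    which(a != b)[1L]
  } else NA
  add("protein_identity", pi,
      if (!pi) paste("first mismatch at residue", mism) else "")

  target <- harmonize(result$table, cfg$rare_threshold)
  n_sense <- if (out$has_terminal_stop) out$codon_count - 1L else
    out$codon_count
  unlocked <- setdiff(seq_len(n_sense), result$locked)
  zero <- names(target$target_fraction)[target$target_fraction == 0 &
                                          GENCODE[ALL_CODONS] != "*"]
  nrare <- sum(out$codons[unlocked] %in% zero)
  add("rare_codon_exclusion", nrare == 0L,
      if (nrare > 0L) paste(nrare, "zero-target codon(s) present") else "")

  gp <- gc_window_profile(out$record$seq, cfg$gc_window, cfg$gc_target,
                          cfg$gc_tolerance)
  add("gc_windows", length(gp$violations) == 0L,
      if (length(gp$violations) > 0L)
        paste(length(gp$violations), "window(s) out of band") else "")

  ok_f <- TRUE
  for (m in cfg$forbidden_motifs) {
    if (length(iupac_match_positions(out$record$seq, m)) > 0L) ok_f <- FALSE
  }
  add("forbidden_motifs", ok_f)

  ok_u <- TRUE
  detail_u <- ""
  if (nrow(result$sites) > 0L) {
    for (i in seq_len(nrow(result$sites))) {
      pos <- iupac_match_positions(out$record$seq, result$sites$motif[i])
      if (!identical(pos, result$sites$start[i])) {
        ok_u <- FALSE
        detail_u <- paste0(result$sites$enzyme[i], " at ",
                           paste(pos, collapse = ","), " expected ",
                           result$sites$start[i])
      }
    }
  }
  add("required_site_uniqueness", ok_u, detail_u)

  fresh <- diagnose(out, result$table, cfg)
  same <- identical(summary(fresh), summary(result$report_after))
  add("report_recomputation", same,
      if (!same) "fresh diagnose() differs from recorded report" else "")

  checks <- do.call(rbind, checks)
  structure(list(pass = all(checks$ok), checks = checks),
            class = "codon_opt_verification")
}

#' @export
print.codon_opt_verification <- function(x, ...) {
  cat(sprintf("<verification> %s\n", if (x$pass) "PASS" else "FAIL"))
  for (i in seq_len(nrow(x$checks))) {
    cat(sprintf("  [%s] %s %s\n", if (x$checks$ok[i]) "ok" else "FAIL",
                x$checks$check[i], x$checks$detail[i]))
  }
  invisible(x)
}
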