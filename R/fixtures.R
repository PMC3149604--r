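# Synthetic-data generators: biased CDS sets with known codon usage,
# planted-flaw sequences with exact ground truth, a reference host usage
# table for highly expressed P. pastoris-like genes, and a synthetic
# mammalian-style surrogate gene.  Everything is deterministic under the
# given seed.

with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# reference within-family codon fractions for highly expressed
# P. pastoris-like genes.  Printed family ratios (Ala, His, Phe, Asp, the
# strong Lys/Asn/Tyr preferences) are taken as published for this host
# class; the remaining families are the package's own fixed, plausible
# choices.  19 codons sit strictly below 0.08 and three more (GCA, ACA,
# GTG) in [0.08, 0.10).
host_reference_fractions <- function() {
  f <- c(
    GCT = .59, GCC = .31, GCA = .09, GCG = .01,                      # Ala
    AGA = .65, CGT = .20, AGG = .06, CGA = .04, CGG = .03, CGC = .02,# Arg
    AAC = .70, AAT = .30,                                            # Asn
    GAC = .59, GAT = .41,                                            # Asp
    TGT = .62, TGC = .38,                                            # Cys
    CAA = .62, CAG = .38,                                            # Gln
    GAA = .60, GAG = .40,                                            # Glu
    GGT = .70, GGA = .24, GGC = .04, GGG = .02,                      # Gly
    CAC = .73, CAT = .27,                                            # His
    ATT = .55, ATC = .40, ATA = .05,                                 # Ile
    TTG = .55, CTT = .18, CTG = .15, TTA = .05, CTC = .04, CTA = .03,# Leu
    AAG = .78, AAA = .22,                                            # Lys
    ATG = 1,                                                         # Met
    TTC = .67, TTT = .33,                                            # Phe
    CCA = .60, CCT = .32, CCC = .05, CCG = .03,                      # Pro
    TCT = .44, TCC = .33, TCA = .06, AGT = .05, AGC = .06, TCG = .06,# Ser
    ACT = .48, ACC = .38, ACA = .09, ACG = .05,                      # Thr
    TGG = 1,                                                         # Trp
    TAC = .70, TAT = .30,                                            # Tyr
    GTT = .45, GTC = .43, GTG = .09, GTA = .03,                      # Val
    TAA = .50, TAG = .20, TGA = .30                                  # stop
  )
  f[ALL_CODONS]
}

#' Reference host codon-usage table (synthetic)
#'
#' A `codon_usage_table` representing the within-family codon preferences
#' of highly expressed *P. pastoris* genes.  Published family ratios for
#' this host class (Ala GCU 59/GCC 31/GCA 9, His CAC 73:27, Phe UUC 67:33,
#' Asp GAC 59:41 and the strong AAG/AAC/UAC preferences) are encoded
#' directly; the remaining family fractions are fixed plausible values
#' chosen once, yielding 19 codons strictly below 8% within their family.
#' Counts are apportioned by largest remainder from a uniform amino-acid
#' composition over `n_codons` total codons.  This is a constructed
#' reference, not a tally of real sequences.
#'
#' @param n_codons total sense-codon count to apportion (default 15863).
#' @return a `codon_usage_table`.
#' @export
host_reference_table <- function(n_codons = 15863L) {
  f <- host_reference_fractions()
  aas <- setdiff(names(AA_FAMILIES), "*")
  aa_tot <- largest_remainder(as.integer(n_codons),
                              stats::setNames(rep(1, length(aas)), aas))
  counts <- stats::setNames(integer(64L), ALL_CODONS)
  for (aa in aas) {
    fam <- AA_FAMILIES[[aa]]
    counts[fam] <- largest_remainder(aa_tot[[aa]],
                                     stats::setNames(f[fam], fam))
  }
  new_usage_table(counts, source_ids = "host_reference_synthetic")
}

# approximate mammalian (mouse-like) codon fractions: GC3-leaning, used to
# emulate a native mammalian gene before host harmonization
mammalian_fractions <- function() {
  f <- c(
    GCC = .38, GCT = .29, GCA = .23, GCG = .10,
    AGA = .21, AGG = .22, CGG = .19, CGC = .17, CGA = .12, CGT = .09,
    AAC = .57, AAT = .43,
    GAC = .56, GAT = .44,
    TGC = .52, TGT = .48,
    CAG = .75, CAA = .25,
    GAG = .60, GAA = .40,
    GGC = .33, GGA = .26, GGG = .23, GGT = .18,
    CAC = .60, CAT = .40,
    ATC = .50, ATT = .34, ATA = .16,
    CTG = .39, CTC = .20, CTT = .13, TTG = .13, CTA = .08, TTA = .07,
    AAG = .61, AAA = .39,
    ATG = 1,
    TTC = .56, TTT = .44,
    CCC = .31, CCT = .31, CCA = .28, CCG = .10,
    AGC = .24, TCC = .22, TCT = .19, TCA = .14, AGT = .15, TCG = .06,
    ACC = .35, ACA = .29, ACT = .25, ACG = .11,
    TGG = 1,
    TAC = .56, TAT = .44,
    GTG = .46, GTC = .25, GTT = .17, GTA = .12,
    TAA = .30, TAG = .24, TGA = .46
  )
  f[ALL_CODONS]
}

# typical globular-protein amino-acid composition (fractions sum to 1)
typical_aa_composition <- function() {
  w <- c(A = .074, R = .052, N = .045, D = .053, C = .018, Q = .040,
         E = .062, G = .068, H = .024, I = .052, L = .096, K = .058,
         M = .023, F = .040, P = .050, S = .071, T = .055, W = .012,
         Y = .032, V = .066)
  w / sum(w)
}

sample_codon <- function(aa, fractions) {
  fam <- AA_FAMILIES[[aa]]
  p <- fractions[fam]
  if (sum(p) <= 0) stop("degenerate table: family '", aa,
                        "' has all-zero fractions", call. = FALSE)
  if (length(fam) == 1L) fam else sample(fam, 1L, prob = p)
}

#' Generate coding sequences with a known codon-usage bias
#'
#' Amino acids are drawn uniformly over the 20 (or from `composition`) and
#' each codon independently from the table's within-family fractions; a
#' terminal TAA stop is appended.  Rebuilding a usage table from the output
#' recovers the input fractions up to binomial sampling error.
#'
#' @param table a `codon_usage_table` supplying the fractions.
#' @param n_genes number of sequences.
#' @param codons_per_gene sense codons per sequence; either a scalar or a
#'   vector of length `n_genes`.
#' @param seed integer seed.
#' @param composition optional named amino-acid sampling weights.
#' @return list of `validated_cds`.
#' @export
biased_cds_set <- function(table, n_genes, codons_per_gene, seed,
                           composition = NULL) {
  stopifnot(inherits(table, "codon_usage_table"), n_genes >= 1L,
            all(codons_per_gene >= 1L))
  sizes <- rep_len(as.integer(codons_per_gene), n_genes)
  aas <- setdiff(names(AA_FAMILIES), "*")
  prob <- if (is.null(composition)) {
    rep(1, length(aas))
  } else {
    p <- composition[aas]           # amino acids absent from the
    p[is.na(p)] <- 0                # composition are never drawn
    if (sum(p) <= 0) stop("composition assigns no mass to any amino acid",
                          call. = FALSE)
    as.numeric(p)
  }
  f <- table$family_fraction
  with_seed(seed, {
    lapply(seq_len(n_genes), function(g) {
      aa_seq <- sample(aas, sizes[g], replace = TRUE, prob = prob)
      codons <- vapply(aa_seq, sample_codon, character(1L), fractions = f,
                       USE.NAMES = FALSE)
      validate_cds(seq_record(sprintf("synth_gene_%03d", g),
                              paste(c(codons, "TAA"), collapse = "")))
    })
  })
}

#' Synthetic host gene set at published scale
#'
#' Thirty sequences totalling `total_codons` sense codons drawn from
#' [host_reference_table()], emulating a curated set of highly expressed
#' host genes.
#'
#' @param table usage table to sample from.
#' @param n_genes number of genes (default 30).
#' @param total_codons total sense codons over the set (default 15863).
#' @param seed integer seed.
#' @return list of `validated_cds`.
#' @export
synthetic_host_genes <- function(table = host_reference_table(),
                                 n_genes = 30L, total_codons = 15863L,
                                 seed = 1L) {
  base <- total_codons %/% n_genes
  sizes <- rep(base, n_genes)
  extra <- total_codons - sum(sizes)
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  biased_cds_set(table, n_genes, sizes, seed)
}

#' Planted-flaw specification
#'
#' @param n_repeats,n_hairpins,n_rich_runs requested flaw counts.
#' @param hairpin_stem,hairpin_loop planted hairpin geometry in nt
#'   (defaults 12 and 6; both multiples of 3 keep planting codon-aligned).
#' @param rich_len planted rich-run length in nt (default 9).
#' @param seed integer seed.
#' @return object of class `flaw_spec`.
#' @export
flaw_spec <- function(n_repeats = 0L, n_hairpins = 0L, n_rich_runs = 0L,
                      hairpin_stem = 12L, hairpin_loop = 6L, rich_len = 9L,
                      seed = 1L) {
  stopifnot(n_repeats >= 0L, n_hairpins >= 0L, n_rich_runs >= 0L,
            hairpin_stem %% 3L == 0L, hairpin_loop %% 3L == 0L,
            rich_len %% 3L == 0L, rich_len >= 9L)
  structure(list(n_repeats = as.integer(n_repeats),
                 n_hairpins = as.integer(n_hairpins),
                 n_rich_runs = as.integer(n_rich_runs),
                 hairpin_stem = as.integer(hairpin_stem),
                 hairpin_loop = as.integer(hairpin_loop),
                 rich_len = as.integer(rich_len), seed = as.integer(seed)),
            class = "flaw_spec")
}

# codons with mixed AT/GC content, used for flaw-resistant backgrounds
.BALANCED_CODONS <- c("GCT", "GCA", "TGT", "GAT", "GAA", "CAT", "ATC",
                      "AAG", "TTG", "CTT", "TCC", "ACT", "GTC", "TAC",
                      "CAA", "AGA", "GGT", "CCA", "TTC", "AAC")

#' Generate a sequence with an exactly known flaw census
#'
#' Builds a flaw-free background (verified against the same detectors used
#' for diagnosis, with repeated local repair), then plants the requested
#' tandem repeats, hairpins and AT-rich runs at well-separated positions.
#' The generator re-runs the detectors and only returns when the observed
#' census equals the planted one, so the returned ground truth is exact.
#'
#' @param spec a [flaw_spec()].
#' @param length_codons total sense codons of the output.
#' @param config detector parameters (an [opt_config()]).
#' @return list with `cds` (a `validated_cds`, terminal TAA appended) and
#'   `truth` (list of planted counts and intervals).
#' @export
planted_flaw_sequence <- function(spec, length_codons,
                                  config = opt_config()) {
  stopifnot(inherits(spec, "flaw_spec"), length_codons >= 4L)
  hp_codons <- (2L * spec$hairpin_stem + spec$hairpin_loop) %/% 3L
  need <- spec$n_repeats * 2L + spec$n_hairpins * hp_codons +
    spec$n_rich_runs * (spec$rich_len %/% 3L)
  n_flaws <- spec$n_repeats + spec$n_hairpins + spec$n_rich_runs
  if (need + 2L * (n_flaws + 1L) > length_codons) {
    stop("infeasible spec: ", need, " flaw codons plus spacing exceed ",
         length_codons, " codons", call. = FALSE)
  }
  with_seed(spec$seed, {
    for (attempt in 1:60) {
      out <- try(plant_once(spec, length_codons, config), silent = TRUE)
      if (!inherits(out, "try-error")) return(out)
    }
    stop("could not realize the requested flaw spec in 60 attempts",
         call. = FALSE)
  })
}

# resample codons covering detector hits until the sequence is flaw-free
# for repeats, hairpins and rich runs; protected codons are never touched
background_repair <- function(codons, config, protected = integer(0),
                              max_rounds = 400L) {
  n <- length(codons)
  for (round in seq_len(max_rounds)) {
    seq <- paste(c(codons, "TAA"), collapse = "")
    cover <- integer(0)
    r <- rle(codons)
    if (any(r$lengths >= 2L)) {
      ends <- cumsum(r$lengths)
      i <- which(r$lengths >= 2L)[1L]
      cover <- (ends[i] - r$lengths[i] + 1L):ends[i]
    } else {
      hp <- find_hairpins(seq, config$min_stem, config$max_mismatch_frac,
                          config$min_loop, config$max_stem)
      if (nrow(hp) > 0L) {
        nt <- c(hp[1L, "a1_start"]:hp[1L, "a1_end"],
                hp[1L, "a2_start"]:hp[1L, "a2_end"])
        cover <- unique(pmin((nt - 1L) %/% 3L + 1L, n))
      } else {
        rich <- find_rich_runs(seq, config$rich_min_len)
        if (nrow(rich) == 0L) return(codons)
        nt <- rich$start[1L]:rich$end[1L]
        cover <- unique(pmin((nt - 1L) %/% 3L + 1L, n))
      }
    }
    cover <- setdiff(cover, protected)
    if (length(cover) == 0L) stop("background flaw inside protected block")
    for (p in cover) {
      nb <- codons[c(max(p - 1L, 1L), min(p + 1L, n))]
      codons[p] <- sample(setdiff(.BALANCED_CODONS, nb), 1L)
    }
  }
  stop("background repair did not converge")
}

plant_once <- function(spec, length_codons, config) {
  # background: balanced codons, no two equal in a row, then repaired to be
  # free of repeats, hairpins and rich runs
  codons <- character(length_codons)
  codons[1L] <- sample(.BALANCED_CODONS, 1L)
  for (i in 2L:length_codons) {
    codons[i] <- sample(setdiff(.BALANCED_CODONS, codons[i - 1L]), 1L)
  }
  codons <- background_repair(codons, config)
  hp_codons <- (2L * spec$hairpin_stem + spec$hairpin_loop) %/% 3L
  blocks <- c(rep(2L, spec$n_repeats), rep(hp_codons, spec$n_hairpins),
              rep(spec$rich_len %/% 3L, spec$n_rich_runs))
  kinds <- c(rep("repeat", spec$n_repeats), rep("hairpin", spec$n_hairpins),
             rep("rich", spec$n_rich_runs))
  # random well-separated starts (2 codon gaps)
  slack <- length_codons - sum(blocks) - 2L * (length(blocks) + 1L)
  gaps <- if (length(blocks) > 0L) {
    g <- stats::rmultinom(1L, slack, rep(1, length(blocks) + 1L))[, 1L]
    g + 2L
  } else integer(0)
  ord <- if (length(kinds) > 0L) sample(seq_along(kinds)) else integer(0)
  truth <- list(repeats = integer(0), hairpins = integer(0),
                rich = integer(0))
  pos <- 0L
  for (j in seq_along(ord)) {
    pos <- pos + gaps[j]
    k <- ord[j]
    start <- pos + 1L
    if (kinds[k] == "repeat") {
      cd <- sample(setdiff(.BALANCED_CODONS,
                           c(codons[start - 1L],
                             codons[min(start + 2L, length_codons)])), 1L)
      codons[start + 0:1] <- cd
      truth$repeats <- c(truth$repeats, start)
    } else if (kinds[k] == "hairpin") {
      arm_cod <- spec$hairpin_stem %/% 3L
      block <- NULL
      for (try_block in 1:50) {  # draw until stop- and repeat-free
        arm1 <- sample(.BALANCED_CODONS, arm_cod, replace = TRUE)
        arm2 <- split_codons(revcomp(paste(arm1, collapse = "")))
        loop <- sample(.BALANCED_CODONS, spec$hairpin_loop %/% 3L,
                       replace = TRUE)
        cand_block <- c(arm1, loop, arm2)
        edge <- c(codons[start - 1L], cand_block,
                  codons[min(start + hp_codons, length_codons)])
        if (any(cand_block %in% STOP_CODONS)) next
        if (any(edge[-1L] == edge[-length(edge)])) next
        block <- cand_block
        break
      }
      if (is.null(block)) stop("hairpin block not realizable")
      codons[start:(start + hp_codons - 1L)] <- block
      truth$hairpins <- c(truth$hairpins, 3L * (start - 1L) + 1L)
    } else {
      nc <- spec$rich_len %/% 3L
      # A-dominant AT-only codons: their reverse complement is T-rich and
      # cannot pair with another planted (A-rich) run as an inverted repeat
      at_pool <- c("AAA", "AAT", "ATA")
      repeat {
        block <- sample(at_pool, nc, replace = TRUE)
        if (!any(block[-1L] == block[-length(block)])) break
      }
      codons[start:(start + nc - 1L)] <- block
      truth$rich <- c(truth$rich, 3L * (start - 1L) + 1L)
    }
    pos <- pos + blocks[k]
  }
  cds <- validate_cds(seq_record("planted_synthetic",
                                 paste(c(codons, "TAA"), collapse = "")))
  rep_found <- find_tandem_codon_repeats(cds)
  hp_found <- find_hairpins(cds$record$seq, config$min_stem,
                            config$max_mismatch_frac, config$min_loop,
                            config$max_stem)
  rich_found <- find_rich_runs(cds$record$seq, config$rich_min_len)
  if (nrow(rep_found) != spec$n_repeats ||
      nrow(hp_found) != spec$n_hairpins ||
      nrow(rich_found) != spec$n_rich_runs) {
    stop("planted census mismatch")
  }
  list(cds = cds,
       truth = list(n_repeats = spec$n_repeats,
                    n_hairpins = spec$n_hairpins,
                    n_rich_runs = spec$n_rich_runs,
                    repeat_starts = sort(truth$repeats),
                    hairpin_arm1_starts = sort(truth$hairpins),
                    rich_starts = sort(truth$rich)))
}

#' Synthetic surrogate for a native mammalian transporter gene
#'
#' A 3828 bp (1275 sense codons + TAA) coding sequence emulating the
#' hallmark flaws of a native mammalian gene expressed in yeast: codons
#' drawn from a mammalian-style GC3-leaning usage profile over a typical
#' protein composition, exactly `n_repeats` tandem codon repeats, and an
#' overall GC content calibrated to `gc_target` by synonymous swaps.  This
#' is a synthetic stand-in generated in code, not a natural sequence.
#'
#' @param seed integer seed.
#' @param n_codons total codons including the terminal stop (default 1276,
#'   i.e. 3828 bp).
#' @param n_repeats tandem-repeat census of the output (default 38).
#' @param gc_target overall GC fraction, matched to within `gc_tol`
#'   (defaults 0.48 and 0.004, i.e. the integer percentage is exact).
#' @return a `validated_cds`.
#' @export
synthetic_wt_gene <- function(seed = 1L, n_codons = 1276L, n_repeats = 38L,
                              gc_target = 0.48, gc_tol = 0.004) {
  n_sense <- n_codons - 1L
  f <- mammalian_fractions()
  comp <- typical_aa_composition()
  with_seed(seed, {
    for (attempt in 1:40) {
      aa_seq <- sample(names(comp), n_sense, replace = TRUE, prob = comp)
      codons <- character(n_sense)
      for (i in seq_len(n_sense)) {
        repeat {
          cd <- sample_codon(aa_seq[i], f)
          if (i == 1L || cd != codons[i - 1L]) break
          # single-codon family equal to predecessor: re-draw the aa
          if (length(AA_FAMILIES[[aa_seq[i]]]) == 1L) {
            aa_seq[i] <- sample(names(comp), 1L, prob = comp)
          }
        }
        codons[i] <- cd
      }
      # plant exactly n_repeats doubled codons, well separated
      starts <- sort(sample(seq(5L, n_sense - 5L), n_repeats * 3L))
      starts <- starts[c(TRUE, diff(starts) >= 4L)][seq_len(n_repeats)]
      if (anyNA(starts)) next
      protected <- integer(0)
      for (s in starts) {
        codons[s + 1L] <- codons[s]
        protected <- c(protected, s - 1L, s, s + 1L, s + 2L)
      }
      codons <- calibrate_seq_gc(codons, gc_target, gc_tol, protected)
      if (is.null(codons)) next
      cds <- validate_cds(seq_record("synthetic_wt_gene",
                                     paste(c(codons, "TAA"), collapse = ""),
                                     "synthetic mammalian-style surrogate"))
      if (nrow(find_tandem_codon_repeats(cds)) == n_repeats &&
          abs(gc_content(cds) - gc_target) <= gc_tol) {
        return(cds)
      }
    }
    stop("could not realize the surrogate within 40 attempts", call. = FALSE)
  })
}

# synonymous swaps toward an overall GC target without touching protected
# positions or creating/removing tandem repeats; NULL when unreachable
calibrate_seq_gc <- function(codons, goal, tol, protected) {
  n <- length(codons)
  gc_cnt <- sum(CODON_GC[codons])
  order_pos <- sample(setdiff(seq_len(n), protected))
  for (p in order_pos) {
    dev <- gc_cnt / (3L * (n + 1L)) - goal  # denominator includes stop TAA
    if (abs(dev) <= tol) return(codons)
    fam <- AA_FAMILIES[[GENCODE[[codons[p]]]]]
    cands <- setdiff(fam, codons[p])
    cands <- cands[(CODON_GC[cands] - CODON_GC[codons[p]]) *
                     sign(dev) < 0]
    nb <- codons[c(max(p - 1L, 1L), min(p + 1L, n))]
    cands <- setdiff(cands, nb)
    if (length(cands) == 0L) next
    pick <- cands[order(abs(CODON_GC[cands] - CODON_GC[codons[p]]),
                        cands)][1L]
    gc_cnt <- gc_cnt + CODON_GC[[pick]] - CODON_GC[[codons[p]]]
    codons[p] <- pick
  }
  if (abs(gc_cnt / (3L * (n + 1L)) - goal) <= tol) codons else NULL
}
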