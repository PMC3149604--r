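---
title: "Codon harmonization and constraint-aware coding-sequence design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon harmonization and constraint-aware coding-sequence design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonharmony)
```

## The problem

Heterologous genes often express poorly because their synonymous-codon
usage, mRNA secondary-structure propensity and base composition differ from
what the host's translation machinery is tuned to.  A mammalian membrane
transporter gene expressed in the methylotrophic yeast *Pichia pastoris* is
a classic instance: the native sequence over-uses codons that are rare in
highly expressed yeast genes, carries tandem codon repeats, inverted
repeats that can fold into mRNA hairpins, AT- and GC-rich stretches,
sequences resembling yeast splice signals, and an overall GC content above
the host's preferred level.

`codonharmony` implements the redesign strategy of *harmonization*: rather
than replacing every codon by the host's single favourite (which distorts
the translational rhythm of the host's own highly expressed genes), the
gene's within-family codon frequencies are matched to those of a reference
set of highly expressed host genes, after excluding codons that those genes
use rarely.

## The model

### Usage tables and the harmonized target

For a set of host coding sequences, `build_usage_table()` tallies all
codons and computes, for each amino-acid family, the relative frequency of
each codon within its family (the six-codon Ser/Leu/Arg families are kept
whole; stop codons form a separate family and are excluded from the codon
total by default, since host tallies are taken over open reading frames).

`harmonize(table, threshold)` derives the optimizer's target distribution:
every codon whose family frequency is strictly below the threshold
(default 0.08) is zeroed and the remaining codons of the family are
renormalized, preserving their proportions.  The comparison is strict so
that a codon sitting exactly at the threshold is retained — consistent
with retaining a 9% codon under an 8% rule.  A family whose members are
all below the threshold is an error rather than a silent choice.

### The flaw census

`diagnose()` aggregates seven detectors, all reporting 1-based closed
intervals on the forward strand:

* **Rare codons** — occurrences of codons below the threshold in the host
  table.
* **Tandem codon repeats** — maximal runs of two or more identical codons
  in frame, counted once per run (an overlapping-pair count is exposed as
  an attribute, since either convention appears in the literature).
* **AT/GC-rich runs** — maximal single-class stretches of at least
  `rich_min_len` bases (default 8 nt).  The source strategy reports such
  regions "up to 10 bases" without a formal detector definition, so this
  run-based definition is ours and its counts are not comparable to
  counts from other tools.
* **Inverted repeats (hairpins)** — two equal-length arms, the downstream
  arm reverse-complementary to the upstream arm up to a mismatch budget of
  `floor(0.10 × stem)`, separated by a loop of at least 4 nt.  The
  mismatch fraction and loop minimum follow the published rule; a minimum
  stem of 10 nt (configurable) is our choice, because shorter inverted
  repeats are ubiquitous in random sequence and would flood the report.
  Hits are *maximal*: neither the outward nor the inward one-base
  extension is itself valid.  A stem cap (default 60 nt) bounds the
  search; hits at the cap are reported as capped.  The scanner works on
  anti-diagonals of the sequence-versus-reverse-complement matching
  matrix, seeded at pure complementary runs that any valid window must
  contain (a window of length L with k mismatches contains a pure run of
  at least ceiling((L−k)/(k+1))); the test suite checks it against an
  exhaustive all-substring oracle.
* **Cryptic splice sites** — independent position-weight matrices for the
  yeast donor (GTATGT), branch (TACTAAC) and acceptor (YAG) signals,
  scored as log-odds sums against background; a position scoring at least
  `threshold_frac` (default 0.8) of the consensus self-score is a hit.
  The published tool used a hidden Markov model whose topology is not
  public; independent PWMs are a degenerate HMM and are the transparent,
  reproducible choice here.  The default model is trained on small
  consensus-derived motif sets defined in code — consensus variants, not
  a genomic training corpus — and `train_splice_model()` accepts real
  training sequences when available.
* **Restriction sites** — forward-strand IUPAC motif matches.
* **GC windows** — GC fraction in every 40 bp window (sliding by 1 nt,
  centered; windows truncated at the ends are excluded rather than
  padded), flagged when outside `gc_target ± gc_tolerance`
  (default 45% ± 10%).

### The redesign pipeline

`optimize_cds()` proceeds in five deterministic-then-stochastic stages,
all driven by one seed:

1. **Harmonize** the host table at the rare threshold.
2. **Carve required restriction sites.**  For each requested motif the
   pipeline enumerates every placement realizable purely by synonymous
   substitution, preferring an occurrence that already exists, then the
   placement whose codons have the highest target frequencies.  Covered
   codons are locked.  Any other occurrence of a required motif is treated
   as a hard violation, so uniqueness is enforced by the repair stage.
3. **Allocate** each amino acid's occurrence count over its retained
   codons by largest-remainder apportionment (floors first, leftovers by
   descending remainder, ties by codon order), so realized frequencies
   deviate from the target by less than 1/n per codon.
4. **Calibrate overall GC.**  Because the repair stage's default moves
   preserve the allocation, the overall GC fraction is decided here: unit
   counts are shifted between retained codons of a family, choosing at
   each step the shift with the least increase in frequency divergence
   per base of GC gained, until the overall GC is within
   `gc_overall_tol` (default 0.004) of the target.  This is the package's
   mechanism for "adjusting GC to 45%" while staying as close as possible
   to the harmonized frequencies.
5. **Place and repair.**  Allocated codons are placed by a seeded shuffle
   and repaired by simulated annealing.  Moves either swap the codons of
   two same-amino-acid positions (allocation-preserving; the default) or,
   when no move has been accepted for `stall` proposals, resample one
   position from the target distribution.  Proposals are biased (90%)
   toward positions covered by a current violation.  The penalty is a
   weighted sum of the per-class violation counts plus the
   occurrence-weighted total-variation distance between realized and
   target family frequencies; all weights default to 1 and are
   configurable.

Hard constraints at termination — protein identity, no zero-target codon
outside locked positions, no forbidden motif, each required site present
exactly once, every GC window in band — follow the published strategy's
claims of achievement; hairpins, repeats, rich runs and splice hits remain
soft weighted terms because the strategy reports them as "avoided" rather
than provably zero.  If the hard constraints cannot be met within the
iteration budget the run returns `success = FALSE` with the best-found
sequence and its residual violations rather than failing silently.

The annealer records the best-so-far penalty at each accepted move, so the
reported trace is non-increasing even though Metropolis acceptance allows
uphill moves; the returned sequence is the recorded best, and
`verify_result()` re-derives every hard-constraint check from the
sequences alone, without trusting the optimizer's bookkeeping.

Cooling uses `T ← 0.995 · T` per accepted move from `T0 = 1`, with a
proposal budget of 200,000 by default.  Runs stop early once the penalty
reaches zero, or once hard constraints hold and the best penalty has not
improved for `patience` proposals (default 3,000).  A terminal stop codon
is never modified: in the motivating constructs the stop and tag context
are vector-supplied.

## Synthetic data and what it does (not) show

No sequence data ships with the package; everything is generated in code.

* `biased_cds_set()` draws amino acids uniformly (or from a supplied
  composition) and codons independently from a table's family fractions —
  the generative model whose parameters `build_usage_table()` recovers.
  At 25,000 sampled codons the recovery error is below 0.05 per codon.
* `host_reference_table()` is a *constructed* reference for highly
  expressed *P. pastoris* genes: the family ratios that are published for
  this host class (Ala GCU 59/GCC 31/GCA 9, His CAC 73:27, Phe UUC 67:33,
  Asp GAC 59:41, and strong AAG/AAC/UAC preferences) are encoded exactly;
  the remaining families are fixed plausible choices made once, arranged
  so that 19 codons fall strictly below 8% and three more lie in
  [8%, 10%).  The Glu ratio is reported inconsistently across published
  summaries (58:42 vs 61:39 in the two directions), so this table uses
  60:40 and no test asserts Glu.  Counts are apportioned from a uniform
  amino-acid composition over 15,863 codons.
* `planted_flaw_sequence()` builds a background that is verified
  flaw-free against the same detectors used for diagnosis (with local
  repair), then plants the requested repeats, hairpins and AT-rich runs
  at well-separated positions; it re-runs the detectors and only returns
  when the observed census equals the planted one, so its ground truth is
  exact, not probabilistic.
* `synthetic_wt_gene()` is a surrogate for a native mammalian transporter
  gene: 3,828 bp, codons drawn from a GC3-leaning mammalian-style usage
  profile over a typical protein composition, exactly 38 tandem codon
  repeats, and overall GC calibrated to 48% by synonymous swaps.  It
  reproduces the *documented headline statistics* of such a gene — it is
  not the gene, and analyses of it say nothing about positions or local
  structure of any real sequence.  Consequently, tests passing on these
  fixtures demonstrate the correctness of the detectors, the allocator
  and the optimizer contracts; they do not validate expression outcomes,
  which are outside the scope of software.

## Numerical choices

* Threshold comparisons are strict (`<`); GC-window tolerance uses a
  `1e-12` guard against floating-point ties.
* Largest-remainder ties break by codon order; preferred-codon ties in
  table comparisons break lexicographically; all outputs are ordered by
  codon or coordinate so equal inputs give byte-equal outputs.
* All randomness flows from the configuration seed; the generator state
  of the caller is saved and restored.
* Problem sizes used by the tests and the acceptance script — a 3,828 bp
  surrogate redesign at up to 30,000 proposals, a 300-codon end-to-end
  run at up to 20,000, 200 oracle comparisons at ≤ 60 nt, 25,000-codon
  recovery — were chosen as the smallest sizes that exercise every stage
  at the documented study scale.

## Known limitations

* Hairpin detection is purely string-based inverted-repeat matching, not
  thermodynamic folding; no minimum-free-energy structure is computed.
* The rich-run and minimum-stem definitions are this package's own
  defaults where the published strategy gives no formal detector; counts
  are reference points, not cross-tool comparables.
* The splice model is a PWM approximation with consensus-derived default
  training data; supply real confirmed splice sites for serious use.
* Only the standard genetic code ships in v1.
* GenBank parsing covers single-interval and `join()` CDS locations on
  the forward strand — enough for CDS extraction, not a general feature
  parser.
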