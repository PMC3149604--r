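# Genetic-code constants and low-level DNA string helpers shared by all
# modules.  Everything is keyed by DNA codons (T, not U); U is accepted on
# input and rendered back only for display.

#' @importFrom Biostrings GENETIC_CODE IUPAC_CODE_MAP
NULL

# standard genetic code, DNA alphabet
GENCODE <- Biostrings::GENETIC_CODE

# all 64 codons in lexicographic order (stable output ordering everywhere)
ALL_CODONS <- sort(names(GENCODE))

STOP_CODONS <- names(GENCODE)[GENCODE == "*"]

# synonymous families: amino acid -> sorted codon vector.  Six-codon Ser/Leu/
# Arg families are kept whole; stops form their own "*" family.
AA_FAMILIES <- split(ALL_CODONS, GENCODE[ALL_CODONS])

SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

codon_aa <- function(codon) unname(GENCODE[codon])

#' Normalize a raw nucleotide string to the DNA alphabet
#'
#' Upper-cases, converts U to T and checks that only A/C/G/T remain.
#' Whitespace and digits (e.g. from GenBank ORIGIN blocks) are stripped.
#'
#' @param x character scalar, raw sequence text.
#' @return normalized DNA string over A/C/G/T.
#' @keywords internal
normalize_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- gsub("[0-9[:space:]/]", "", x)
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  bad <- gsub("[ACGT]", "", x)
  if (nzchar(bad)) {
    stop("sequence contains non-ACGT characters after normalization: '",
         substr(bad, 1L, 10L), "'", call. = FALSE)
  }
  if (!nzchar(x)) stop("empty sequence", call. = FALSE)
  x
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE))
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3L == 0L)
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

split_bases <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# display helper: DNA codon -> RNA spelling (parity with printed usage tables)
codon_as_rna <- function(codon) chartr("T", "U", codon)

# IUPAC degenerate motif -> regular expression character classes
iupac_to_regex <- function(motif) {
  motif <- chartr("u", "U", toupper(motif))
  motif <- chartr("U", "T", motif)
  bases <- split_bases(motif)
  map <- Biostrings::IUPAC_CODE_MAP
  bad <- setdiff(bases, names(map))
  if (length(bad) > 0L) {
    stop("invalid IUPAC character(s) in motif '", motif, "': ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  paste(vapply(bases, function(b) {
    expand <- map[[b]]
    if (nchar(expand) == 1L) expand else paste0("[", expand, "]")
  }, character(1L)), collapse = "")
}

# all 1-based start positions of an IUPAC motif on the forward strand
iupac_match_positions <- function(seq, motif) {
  re <- iupac_to_regex(motif)
  m <- gregexpr(paste0("(?=", re, ")"), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}
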