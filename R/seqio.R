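# Sequence I/O: FASTA and (minimal) GenBank flat-file reading, FASTA
# writing, CDS validation and translation under the standard genetic code.
#
# Coordinates in every report produced by this package are 1-based closed
# intervals.

#' Construct a sequence record
#'
#' A lightweight container for one DNA sequence.  Input is normalized:
#' upper-cased, U converted to T; characters outside A/C/G/T are rejected
#' (ambiguity codes are not meaningful for synonymous redesign).
#'
#' @param id character scalar label.
#' @param seq character scalar DNA (or RNA) sequence.
#' @param desc free-text description.
#' @return an object of class `seq_record` with elements `id`, `desc`, `seq`.
#' @examples
#' seq_record("g1", "auggcu")$seq  # "ATGGCT"
#' @export
seq_record <- function(id, seq, desc = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, desc = desc, seq = normalize_dna(seq)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s  (%d bp)%s\n", x$id, nchar(x$seq),
              if (nzchar(x$desc)) paste0("  ", x$desc) else ""))
  invisible(x)
}

#' Read sequence records from FASTA or GenBank
#'
#' FASTA parsing is delegated to [Biostrings::readBStringSet()]; GenBank
#' flat files are handled by a minimal built-in parser that extracts the
#' CDS feature (single-interval or `join()` locations) when one is
#' annotated, and the full ORIGIN sequence otherwise.
#'
#' @param file path to the input file; ignored when `text` is given.
#' @param format `"fasta"` or `"genbank"`.
#' @param text optional character scalar holding the file contents directly.
#' @return list of [seq_record] objects, in file order.
#' @export
read_seqs <- function(file, format = c("fasta", "genbank"), text = NULL) {
  format <- match.arg(format)
  if (!is.null(text)) {
    file <- tempfile(fileext = paste0(".", format))
    on.exit(unlink(file), add = TRUE)
    writeLines(text, file)
  }
  if (!file.exists(file)) stop("input file not found: ", file, call. = FALSE)
  recs <- if (format == "fasta") read_fasta_records(file) else
    read_genbank_records(file)
  if (length(recs) == 0L) stop("no records", call. = FALSE)
  recs
}

read_fasta_records <- function(file) {
  raw <- readLines(file, warn = FALSE)
  if (!any(grepl("^>", raw))) {
    if (all(!nzchar(trimws(raw)))) return(list())
    stop("FASTA parse error: no '>' header before sequence at line 1",
         call. = FALSE)
  }
  set <- Biostrings::readBStringSet(file, format = "fasta")
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    header <- names(set)[i]
    id <- sub("\\s.*$", "", header)
    desc <- sub("^\\S+\\s*", "", header)
    out[[i]] <- seq_record(id, as.character(set[[i]]), desc)
  }
  out
}

# --- minimal GenBank flat-file reader -------------------------------------

read_genbank_records <- function(file) {
  lines <- readLines(file, warn = FALSE)
  ends <- grep("^//", lines)
  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0L) {
    if (all(!nzchar(trimws(lines)))) return(list())
    stop("GenBank parse error: no LOCUS line (line 1)", call. = FALSE)
  }
  if (length(ends) < length(starts)) {
    stop("GenBank parse error: record starting at line ", starts[length(starts)],
         " has no terminating '//'", call. = FALSE)
  }
  lapply(seq_along(starts), function(i) {
    parse_genbank_record(lines[starts[i]:ends[i]], starts[i])
  })
}

parse_genbank_record <- function(lines, offset) {
  id <- strsplit(trimws(sub("^LOCUS", "", lines[1L])), "\\s+")[[1L]][1L]
  defn <- grep("^DEFINITION", lines)
  desc <- if (length(defn) > 0L)
    trimws(sub("^DEFINITION", "", lines[defn[1L]])) else ""
  oi <- grep("^ORIGIN", lines)
  if (length(oi) == 0L) {
    stop("GenBank parse error: record at line ", offset, " has no ORIGIN block",
         call. = FALSE)
  }
  seq_lines <- lines[(oi[1L] + 1L):(length(lines) - 1L)]
  full <- normalize_dna(paste(seq_lines, collapse = ""))
  loc <- genbank_cds_location(lines, offset)
  if (is.null(loc)) return(seq_record(id, full, desc))
  pieces <- vapply(seq_len(nrow(loc)), function(k) {
    if (loc[k, 2L] > nchar(full)) {
      stop("GenBank parse error: CDS location exceeds sequence length ",
           "(record at line ", offset, ")", call. = FALSE)
    }
    substr(full, loc[k, 1L], loc[k, 2L])
  }, character(1L))
  seq_record(id, paste(pieces, collapse = ""), desc)
}

# first CDS feature location as a matrix of (start, end) rows, or NULL
genbank_cds_location <- function(lines, offset) {
  ci <- grep("^     CDS\\s", lines)
  if (length(ci) == 0L) return(NULL)
  loc <- trimws(sub("^     CDS", "", lines[ci[1L]]))
  j <- ci[1L] + 1L
  while (j <= length(lines) && grepl("^\\s{21}[^/]", lines[j]) &&
         !grepl("^\\s{21}/", lines[j])) {
    loc <- paste0(loc, trimws(lines[j]))
    j <- j + 1L
  }
  loc <- gsub("join\\(|\\)|<|>", "", loc)
  parts <- strsplit(loc, ",")[[1L]]
  m <- t(vapply(parts, function(p) {
    nums <- suppressWarnings(as.integer(strsplit(p, "\\.\\.")[[1L]]))
    if (anyNA(nums)) {
      stop("GenBank parse error: unsupported CDS location '", p,
           "' (record at line ", offset, ")", call. = FALSE)
    }
    if (length(nums) == 1L) nums <- c(nums, nums)
    nums
  }, integer(2L)))
  unname(m)
}

#' Write records as wrapped FASTA
#'
#' @param records list of [seq_record] (or a single one).
#' @param file output path.
#' @param width line-wrap width (default 60 columns).
#' @return `file`, invisibly.
#' @export
write_fasta <- function(records, file, width = 60L) {
  if (inherits(records, "seq_record")) records <- list(records)
  seqs <- Biostrings::DNAStringSet(vapply(records, `[[`, character(1L), "seq"))
  names(seqs) <- vapply(records, function(r) {
    if (nzchar(r$desc)) paste(r$id, r$desc) else r$id
  }, character(1L))
  Biostrings::writeXStringSet(seqs, file, width = width)
  invisible(file)
}

#' Validate a coding sequence
#'
#' Checks reading-frame integrity: length divisible by 3 and no internal
#' stop codon.  A terminal stop codon, if present, is flagged and retained.
#'
#' @param record a [seq_record], or anything `seq_record()` accepts as `seq`
#'   (then an id of `"cds"` is used).
#' @param require_atg error unless the first codon is ATG.
#' @return object of class `validated_cds`: elements `record`, `codon_count`,
#'   `has_terminal_stop`, `codons` (character vector of codons).
#' @export
validate_cds <- function(record, require_atg = FALSE) {
  if (!inherits(record, "seq_record")) record <- seq_record("cds", record)
  n <- nchar(record$seq)
  if (n %% 3L != 0L) {
    stop("length not multiple of 3 (", n, " bp) for '", record$id, "'",
         call. = FALSE)
  }
  codons <- split_codons(record$seq)
  k <- length(codons)
  internal <- which(codons[-k] %in% STOP_CODONS)
  if (length(internal) > 0L) {
    stop("internal stop at codon ", internal[1L], " in '", record$id, "'",
         call. = FALSE)
  }
  if (require_atg && codons[1L] != "ATG") {
    stop("missing ATG start codon in '", record$id, "'", call. = FALSE)
  }
  structure(list(record = record, codon_count = k,
                 has_terminal_stop = codons[k] %in% STOP_CODONS,
                 codons = codons),
            class = "validated_cds")
}

#' @export
print.validated_cds <- function(x, ...) {
  cat(sprintf("<validated_cds> %s: %d codons (%d bp)%s\n", x$record$id,
              x$codon_count, nchar(x$record$seq),
              if (x$has_terminal_stop) ", terminal stop" else ""))
  invisible(x)
}

#' Translate a validated CDS
#'
#' Standard genetic code; the terminal stop is rendered as `"*"` only when
#' present in the input.
#'
#' @param cds a `validated_cds`.
#' @return protein string, one letter per codon.
#' @export
translate_cds <- function(cds) {
  stopifnot(inherits(cds, "validated_cds"))
  paste(GENCODE[cds$codons], collapse = "")
}

# codons of a CDS excluding the terminal stop (the optimizer's work list)
sense_codons_of <- function(cds) {
  if (cds$has_terminal_stop) cds$codons[-cds$codon_count] else cds$codons
}

# rebuild a validated_cds from a codon vector, keeping id/description
cds_from_codons <- function(codons, template) {
  rec <- seq_record(template$record$id, paste(codons, collapse = ""),
                    template$record$desc)
  validate_cds(rec)
}
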