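DNA_BASES <- c("A", "C", "G", "T")
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "K", "L",
                 "M", "F", "P", "S", "T", "W", "Y", "V")

#' Pipeline logging
#'
#' Every pipeline stage logs input counts, thresholds and output counts so
#' that filter attrition is auditable. Logging goes through [message()] and
#' can be silenced with `options(gcrescue.verbose = FALSE)`.
#'
#' @param stage short stage name
#' @param fmt,... `sprintf()` format and arguments
#' @return invisibly, the formatted line
#' @export
pipeline_log <- function(stage, fmt, ...) {
  line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
  if (isTRUE(getOption("gcrescue.verbose", TRUE))) message("INFO ", line)
  invisible(line)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N)
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  revcomp_cpp(as.character(x))
}

#' Construct a set of sequence records
#'
#' A `seq_set` is the package's carrier for named nucleotide or protein
#' sequences: a data frame with columns `id`, `description`, `residues`
#' and an `alphabet` attribute (`"DNA"` or `"PROTEIN"`). Residues are
#' uppercased; ids must be unique and non-empty.
#'
#' @param id character vector of unique ids
#' @param residues character vector of sequences
#' @param description free-text descriptions (recycled)
#' @param alphabet `"DNA"`, `"PROTEIN"` or `"auto"` (detect: a set whose
#'   residues are all in A/C/G/T/N is DNA, otherwise protein)
#' @return a `seq_set` data frame
#' @export
seq_set <- function(id, residues, description = "", alphabet = "auto") {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) != length(residues))
    stop("id and residues must have the same length")
  if (any(duplicated(id)))
    stop("duplicate id: ", id[duplicated(id)][1L])
  if (any(nchar(residues) < 1L))
    stop("empty sequence for record ", id[nchar(residues) < 1L][1L])
  if (identical(alphabet, "auto")) {
    alphabet <- if (all(!grepl("[^ACGTN]", residues))) "DNA" else "PROTEIN"
  }
  alphabet <- match.arg(alphabet, c("DNA", "PROTEIN"))
  validate_residues(residues, alphabet, id)
  out <- data.frame(id = id, description = rep_len(as.character(description),
                                                   length(id)),
                    residues = residues, stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  class(out) <- c("seq_set", "data.frame")
  out
}

# error names the offending record and 1-based position of the first
# illegal residue
validate_residues <- function(residues, alphabet, ids) {
  pat <- if (alphabet == "DNA") "[^ACGTN]" else
    paste0("[^", paste(AA_STANDARD, collapse = ""), "X]")
  hit <- regexpr(pat, residues)
  bad <- which(hit > 0L)
  if (length(bad)) {
    i <- bad[1L]
    stop(sprintf("illegal %s residue '%s' in record '%s' at position %d",
                 alphabet, substr(residues[i], hit[i], hit[i]), ids[i],
                 hit[i]))
  }
  invisible(TRUE)
}

#' Construct a set of sequencing reads
#'
#' A `read_set` is a data frame with columns `id`, `residues`, `qualities`
#' (Phred+33 encoded string, or `NA`) and `source` (tissue/dataset label).
#'
#' @param id character vector of read ids
#' @param residues DNA sequences
#' @param qualities Phred+33 quality strings (optional)
#' @param source tissue or dataset label (recycled)
#' @return a `read_set` data frame
#' @export
read_set <- function(id, residues, qualities = NA_character_, source = "") {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  qualities <- rep_len(as.character(qualities), length(id))
  ok <- !is.na(qualities)
  if (any(nchar(qualities[ok]) != nchar(residues[ok]))) {
    i <- which(ok & nchar(qualities) != nchar(residues))[1L]
    stop("quality length differs from sequence length for read '", id[i], "'")
  }
  qv <- unlist(lapply(qualities[ok], function(q) utf8ToInt(q) - 33L))
  if (length(qv) && (min(qv) < 0L || max(qv) > 60L))
    stop("Phred qualities outside [0, 60]")
  out <- data.frame(id = id, residues = residues, qualities = qualities,
                    source = rep_len(as.character(source), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("read_set", "data.frame")
  out
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param q character vector of quality strings
#' @return list of integer vectors, `q = ord(char) - 33`
#' @export
decode_qualities <- function(q) {
  lapply(q, function(s) if (is.na(s)) integer(0) else utf8ToInt(s) - 33L)
}

#' Translate DNA to protein (standard genetic code)
#'
#' Thin wrapper around [Biostrings::translate()]; trailing partial codons
#' are dropped and stop codons appear as `*`.
#'
#' @param dna character vector of DNA sequences
#' @return character vector of protein sequences
#' @export
translate_dna <- function(dna) {
  vapply(dna, function(s) {
    s <- substr(s, 1L, 3L * (nchar(s) %/% 3L))
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       if.fuzzy.codon = "X"))
  }, character(1), USE.NAMES = FALSE)
}

# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}
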