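#' Recruitment scoring scheme
#'
#' A self-contained BLASTN-like scoring scheme for read recruitment:
#' +1/-2 match/mismatch with affine gaps, ungapped Karlin-Altschul
#' constants for the bit-score conversion
#' `bits = (lambda * raw - ln K) / ln 2`, a bit-score recruitment
#' threshold (default 100), and the seed word size. A gap of length L
#' costs `|gap_open| + L * |gap_extend|`.
#'
#' @param match match reward (> 0, default +1)
#' @param mismatch mismatch penalty (< 0, default -2)
#' @param gap_open gap opening penalty (default -5)
#' @param gap_extend gap extension penalty per base (default -2)
#' @param lambda Karlin-Altschul lambda (default 1.28)
#' @param K Karlin-Altschul K (default 0.46)
#' @param bit_threshold recruitment bit-score threshold (default 100)
#' @param word_size seed k-mer size (default 11)
#' @param band band half-width for seeded extension (default 15)
#' @return a validated `scoring_scheme` list
#' @export
scoring_scheme <- function(match = 1L, mismatch = -2L, gap_open = -5L,
                           gap_extend = -2L, lambda = 1.28, K = 0.46,
                           bit_threshold = 100, word_size = 11L,
                           band = 15L) {
  stopifnot(match > 0, mismatch < 0, lambda > 0, K > 0, bit_threshold > 0,
            word_size >= 1L, word_size <= 31L, band >= 1L)
  s <- list(match = as.integer(match), mismatch = as.integer(mismatch),
            gap_open = as.integer(gap_open),
            gap_extend = as.integer(gap_extend),
            lambda = lambda, K = K, bit_threshold = bit_threshold,
            word_size = as.integer(word_size), band = as.integer(band))
  class(s) <- "scoring_scheme"
  s
}

#' Convert a raw alignment score to a bit score
#'
#' `bits = (lambda * raw - ln K) / ln 2`.
#'
#' @param raw raw alignment score(s)
#' @param scheme a [scoring_scheme()]
#' @return bit score(s)
#' @export
bit_score <- function(raw, scheme = scoring_scheme()) {
  (scheme$lambda * raw - log(scheme$K)) / log(2)
}

#' Build a seed index of a bait sequence
#'
#' Exact-match lookup from every k-mer of the bait and of its reverse
#' complement to 0-based positions and strand. k-mers containing non-ACGT
#' bases are skipped.
#'
#' @param bait a single DNA string
#' @param k word size
#' @return data frame with `kmer`, `pos` (0-based, on the indexed strand)
#'   and `strand`
#' @export
build_seed_index <- function(bait, k = 11L) {
  bait <- toupper(bait)
  stopifnot(k <= nchar(bait))
  one <- function(s, strand) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(NULL)
    km <- substring(s, 1:n, k:nchar(s))
    keep <- !grepl("[^ACGT]", km)
    data.frame(kmer = km[keep], pos = (0:(n - 1L))[keep], strand = strand,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(bait, "+"), one(revcomp(bait), "-"))
  rownames(out) <- NULL
  out
}

# shared C++ scan; returns one row per read (NA rows = no seed / no score)
recruit_scan <- function(reads_chr, bait, scheme) {
  recruit_scan_cpp(reads_chr, toupper(bait), scheme$word_size,
                   scheme$match, scheme$mismatch,
                   abs(scheme$gap_open), abs(scheme$gap_extend),
                   scheme$band, 64L)
}

#' Score one read against a bait
#'
#' Seeded, banded local (Smith-Waterman) alignment with affine gaps: every
#' shared k-mer seeds a banded extension (band half-width
#' `scheme$band`), and the maximal raw score over all seeds and strands is
#' returned with its bit score. Returns `NULL` when read and bait share no
#' seed word.
#'
#' @param read a single DNA string
#' @param bait a single DNA string
#' @param scheme a [scoring_scheme()]
#' @return one-row data frame (`read_id`, `strand`, `raw_score`,
#'   `bit_score`, `bait_start`, `bait_end`, `read_start`, `read_end`;
#'   intervals 0-based half-open on the forward bait) or `NULL`
#' @export
score_read <- function(read, bait, scheme = scoring_scheme()) {
  stopifnot(nchar(read) >= scheme$word_size)
  h <- recruit_scan(toupper(read), bait, scheme)
  if (is.na(h$raw[1L])) return(NULL)
  data.frame(read_id = "read", strand = h$strand[1L], raw_score = h$raw[1L],
             bit_score = bit_score(h$raw[1L], scheme),
             bait_start = h$bait_start[1L], bait_end = h$bait_end[1L],
             read_start = h$read_start[1L], read_end = h$read_end[1L],
             stringsAsFactors = FALSE)
}

#' Recruit reads matching a bait
#'
#' Applies [score_read()] to every read and keeps the hits whose bit
#' score reaches `scheme$bit_threshold` (one best hit per read; equal-score
#' alignments within a read prefer the lower bait start). Hits are
#' returned ordered by (bait_start, read_id).
#'
#' @param reads a [read_set()] (or data frame with `id`, `residues`)
#' @param bait a single DNA string or one-record DNA [seq_set()]
#' @param scheme a [scoring_scheme()]
#' @return data frame of recruitment hits: `read_id`, `strand`,
#'   `raw_score`, `bit_score`, `bait_start`, `bait_end`, `read_start`,
#'   `read_end`
#' @export
recruit <- function(reads, bait, scheme = scoring_scheme()) {
  if (inherits(bait, "seq_set") || is.data.frame(bait))
    bait <- bait$residues[1L]
  h <- recruit_scan(reads$residues, bait, scheme)
  bits <- bit_score(h$raw, scheme)
  keep <- which(!is.na(h$raw) & bits >= scheme$bit_threshold)
  out <- data.frame(read_id = reads$id[keep], strand = h$strand[keep],
                    raw_score = h$raw[keep], bit_score = bits[keep],
                    bait_start = h$bait_start[keep],
                    bait_end = h$bait_end[keep],
                    read_start = h$read_start[keep],
                    read_end = h$read_end[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$bait_start, out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  pipeline_log("recruit",
               "%d reads in, %d recruited at >= %.0f bits (word %d)",
               nrow(reads), nrow(out), scheme$bit_threshold,
               scheme$word_size)
  out
}
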