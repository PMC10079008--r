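#' GC fraction of a DNA sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`. `N` bases are excluded from both
#' numerator and denominator, so they never inflate the statistic; an
#' all-N sequence has no defined GC fraction and is an error.
#'
#' @param seq a single DNA string
#' @return fraction in `[0, 1]`
#' @export
gc_fraction <- function(seq) {
  stopifnot(length(seq) == 1L, nchar(seq) >= 1L)
  seq <- toupper(seq)
  gc <- nchar(gsub("[^GC]", "", seq))
  acgt <- nchar(gsub("[^ACGT]", "", seq))
  if (acgt == 0L) stop("no A/C/G/T bases; GC fraction undefined")
  gc / acgt
}

#' Maximal G/C runs of a DNA sequence
#'
#' A G/C stretch is an undisrupted run of consecutive G or C nucleotides of
#' at least `min_len` bases. Runs are maximal (flanked by a non-G/C base or
#' the sequence end); `N` terminates a run. Intervals are 0-based
#' half-open and sorted.
#'
#' @param seq a single DNA string
#' @param min_len minimum run length (default 3)
#' @return integer matrix with columns `start`, `end` (0-based half-open)
#' @export
gc_stretches <- function(seq, min_len = 3L) {
  stopifnot(length(seq) == 1L, min_len >= 1L)
  seq <- toupper(seq)
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1L]] %in% c("G", "C"))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_len
  cbind(start = starts[keep], end = ends[keep])
}

#' GC and G/C-stretch summary for one CDS
#'
#' Combines [gc_fraction()] and [gc_stretches()]. The mean stretch length
#' averages over qualifying stretches only (runs shorter than `min_len`
#' contribute neither to the count nor to the mean) and is 0 when no
#' stretch qualifies.
#'
#' @param seq a single DNA string
#' @param min_len minimum stretch length
#' @param id sequence id carried into the profile
#' @return a `stretch_profile` list: `sequence_id`, `length_nt`,
#'   `gc_fraction`, `stretches`, `stretch_count`, `mean_stretch_length`,
#'   `min_stretch_length`
#' @export
stretch_summary <- function(seq, min_len = 3L, id = "seq") {
  s <- gc_stretches(seq, min_len)
  n <- nrow(s)
  out <- list(sequence_id = id,
              length_nt = nchar(seq),
              gc_fraction = gc_fraction(seq),
              stretches = s,
              stretch_count = n,
              mean_stretch_length = if (n > 0L) sum(s[, 2L] - s[, 1L]) / n
                                    else 0,
              min_stretch_length = as.integer(min_len))
  class(out) <- "stretch_profile"
  out
}

#' @export
print.stretch_profile <- function(x, ...) {
  cat(sprintf("<stretch_profile> %s: %d nt, GC %.3f, %d stretches (>= %d), mean length %.2f\n",
              x$sequence_id, x$length_nt, x$gc_fraction, x$stretch_count,
              x$min_stretch_length, x$mean_stretch_length))
  invisible(x)
}

#' Profile a gene set for G/C-stretch statistics
#'
#' Filters out CDSs shorter than `min_cds_length` (the filtered count is
#' logged), profiles the remainder with [stretch_summary()], and builds a
#' histogram of mean stretch length (bin width 0.1). Optionally reports
#' the percentile rank of a designated query gene (for example a rescued
#' CDS) within the background distribution.
#'
#' @param cds_set a DNA [seq_set()]
#' @param min_len minimum stretch length
#' @param min_cds_length minimum CDS length kept (default 300 nt,
#'   i.e. sequences longer than 299 nt)
#' @param query optional: id of a profiled gene, or a separate
#'   `stretch_profile`, whose percentile rank is reported
#' @return a `gene_set_profile` list: per-gene `table`, `histogram`
#'   (`bin_start`, `count`), `n_filtered`, `min_cds_length`, and
#'   `query_percentile` when a query is given
#' @export
gene_set_profile <- function(cds_set, min_len = 3L, min_cds_length = 300L,
                             query = NULL) {
  len <- nchar(cds_set$residues)
  keep <- len >= min_cds_length
  pipeline_log("gene_set_profile",
               "%d input CDS, %d filtered (< %d nt), %d profiled",
               length(len), sum(!keep), min_cds_length, sum(keep))
  if (!any(keep)) stop("no CDS left after length filter")
  kept <- cds_set[keep, , drop = FALSE]
  profs <- mapply(stretch_summary, kept$residues, id = kept$id,
                  MoreArgs = list(min_len = min_len), SIMPLIFY = FALSE)
  tab <- data.frame(
    id = kept$id,
    length_nt = vapply(profs, `[[`, numeric(1), "length_nt"),
    gc_fraction = vapply(profs, `[[`, numeric(1), "gc_fraction"),
    stretch_count = vapply(profs, `[[`, numeric(1), "stretch_count"),
    mean_stretch_length = vapply(profs, `[[`, numeric(1),
                                 "mean_stretch_length"),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  bin <- floor(tab$mean_stretch_length / 0.1 + 1e-9)
  cnt <- table(bin)
  hist <- data.frame(bin_start = as.numeric(names(cnt)) * 0.1,
                     count = as.integer(cnt))
  out <- list(table = tab, histogram = hist, n_filtered = sum(!keep),
              min_cds_length = as.integer(min_cds_length),
              min_stretch_length = as.integer(min_len))
  if (!is.null(query)) {
    qval <- if (inherits(query, "stretch_profile")) query$mean_stretch_length
            else {
              if (!query %in% tab$id) stop("query id not in profiled set")
              tab$mean_stretch_length[tab$id == query]
            }
    out$query_mean_stretch_length <- qval
    out$query_percentile <- 100 * mean(tab$mean_stretch_length <= qval)
  }
  class(out) <- "gene_set_profile"
  out
}

#' @export
print.gene_set_profile <- function(x, ...) {
  cat(sprintf("<gene_set_profile> %d genes profiled (%d filtered at < %d nt)\n",
              nrow(x$table), x$n_filtered, x$min_cds_length))
  if (!is.null(x$query_percentile))
    cat(sprintf("  query mean stretch length %.2f, percentile %.1f\n",
                x$query_mean_stretch_length, x$query_percentile))
  invisible(x)
}
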