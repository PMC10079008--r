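#' Count bait-recruited reads per tissue
#'
#' Applies [recruit()] to each tissue's read set independently; the
#' library size is the total number of reads in the dataset (not "mapped"
#' reads — recruitment operates on whole datasets where genome-wide
#' mapping never happens, so total-read normalization is the only
#' computable reading; this is logged). An empty read set yields count 0
#' with a warning, not an error.
#'
#' @param tissue_read_sets named list of [read_set()]s, one per tissue
#' @param bait DNA string or one-record DNA [seq_set()]
#' @param scheme a [scoring_scheme()]
#' @return data frame with `tissue`, `count`, `library_size`
#' @export
count_recruited <- function(tissue_read_sets, bait,
                            scheme = scoring_scheme()) {
  stopifnot(length(tissue_read_sets) >= 1L,
            !is.null(names(tissue_read_sets)))
  rows <- lapply(names(tissue_read_sets), function(t) {
    rs <- tissue_read_sets[[t]]
    if (nrow(rs) == 0L) {
      warning("empty read set for tissue '", t, "'; count 0")
      return(data.frame(tissue = t, count = 0L, library_size = 0L,
                        stringsAsFactors = FALSE))
    }
    hits <- recruit(rs, bait, scheme)
    pipeline_log("count_recruited",
                 "%s: %d / %d reads recruited (library normalized on total reads)",
                 t, nrow(hits), nrow(rs))
    data.frame(tissue = t, count = nrow(hits), library_size = nrow(rs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reads per kilobase per million (RPKM)
#'
#' `count / ((gene_length / 1000) * (library_size / 1e6))`.
#'
#' @param count recruited read count
#' @param gene_length_nt gene length in nucleotides (>= 1)
#' @param library_size total reads in the dataset (>= 1)
#' @return RPKM value(s)
#' @export
rpkm <- function(count, gene_length_nt, library_size) {
  stopifnot(all(gene_length_nt >= 1), all(library_size >= 1))
  count / ((gene_length_nt / 1000) * (library_size / 1e6))
}

#' Immune-organ enrichment report
#'
#' Formalizes "enriched in immune-related organs" as an explicit,
#' artifact-defined score: records are sorted by RPKM (ties by tissue
#' label); the report carries the immune and non-immune median RPKMs and
#' their ratio (reported as undefined when the non-immune median is 0),
#' and the `enriched` flag is true iff every immune tissue's RPKM exceeds
#' the median RPKM of the non-immune tissues.
#'
#' @param records data frame with `tissue` and `rpkm` columns
#' @param immune_flags named logical vector, tissue -> immune flag
#' @return an `enrichment_report` list: `records` (sorted, with
#'   `immune_flag`), `immune_median`, `non_immune_median`, `ratio`,
#'   `enriched`
#' @export
enrichment_report <- function(records, immune_flags) {
  stopifnot(all(c("tissue", "rpkm") %in% names(records)))
  missing <- setdiff(records$tissue, names(immune_flags))
  if (length(missing))
    stop("immune flag missing for tissue '", missing[1L], "'")
  flags <- immune_flags[records$tissue]
  if (!any(flags) || all(flags))
    stop("need at least one immune and one non-immune tissue")
  records$immune_flag <- unname(flags)
  ord <- order(-records$rpkm, records$tissue)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  med_i <- median(records$rpkm[records$immune_flag])
  med_n <- median(records$rpkm[!records$immune_flag])
  ratio <- if (med_n == 0) NA_real_ else med_i / med_n
  enriched <- all(records$rpkm[records$immune_flag] > med_n)
  out <- list(records = records, immune_median = med_i,
              non_immune_median = med_n, ratio = ratio,
              ratio_defined = med_n != 0, enriched = enriched)
  class(out) <- "enrichment_report"
  out
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("<enrichment_report> (artifact-defined score)\n")
  print(x$records, row.names = FALSE)
  cat(sprintf("  immune median RPKM %.2f, non-immune median %.2f, ratio %s\n",
              x$immune_median, x$non_immune_median,
              if (x$ratio_defined) sprintf("%.2f", x$ratio) else
                "undefined (non-immune median 0)"))
  cat(sprintf("  enriched: %s\n", x$enriched))
  invisible(x)
}

#' Tissue expression profile of a gene
#'
#' Convenience wrapper: [count_recruited()] per tissue, [rpkm()]
#' normalization by the bait length, and [enrichment_report()].
#'
#' @param tissue_read_sets named list of [read_set()]s
#' @param bait one-record DNA [seq_set()] or DNA string (the gene CDS)
#' @param immune_flags named logical vector, tissue -> immune flag
#' @param scheme a [scoring_scheme()]
#' @return list with `table` (tissue, count, library_size, rpkm,
#'   immune_flag) and `enrichment` (an `enrichment_report`)
#' @export
quantify_expression <- function(tissue_read_sets, bait, immune_flags,
                                scheme = scoring_scheme()) {
  gene_len <- if (inherits(bait, "seq_set") || is.data.frame(bait))
    nchar(bait$residues[1L]) else nchar(bait)
  counts <- count_recruited(tissue_read_sets, bait, scheme)
  counts$rpkm <- rpkm(counts$count, gene_len,
                      pmax(counts$library_size, 1L))
  enr <- enrichment_report(counts, immune_flags)
  list(table = enr$records, enrichment = enr)
}
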