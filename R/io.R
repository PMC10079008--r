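#' Read a FASTA file
#'
#' Records are returned in file order with lowercase residues uppercased.
#' `*` stop symbols are stripped from protein records with a warning.
#' Duplicate ids and illegal residues are rejected.
#'
#' @param path FASTA file
#' @param alphabet `"auto"` (default), `"DNA"` or `"PROTEIN"`
#' @return a [seq_set()]
#' @export
read_fasta <- function(path, alphabet = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no records in ", path)
  headers <- names(x)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  res <- toupper(as.character(x))
  if (any(duplicated(id)))
    stop("duplicate id in ", path, ": ", id[duplicated(id)][1L])
  if (identical(alphabet, "auto"))
    alphabet <- if (all(!grepl("[^ACGTN]", res))) "DNA" else "PROTEIN"
  if (alphabet == "PROTEIN" && any(grepl("\\*", res))) {
    warning("stripping '*' stop symbols from protein records")
    res <- gsub("\\*", "", res)
  }
  pipeline_log("read_fasta", "%d records from %s (%s)", length(id), path,
               alphabet)
  seq_set(id, res, desc, alphabet)
}

#' Write a FASTA file (60-column wrap)
#'
#' @param records a [seq_set()] or data frame with `id`, `residues` and
#'   optionally `description`
#' @param path output file
#' @param width line wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(records, path, width = 60L) {
  desc <- if ("description" %in% names(records)) records$description else ""
  hdr <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  x <- Biostrings::BStringSet(records$residues)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' Strict 4-line records; qualities are decoded as `q = ord(char) - 33`.
#' Other quality encodings are rejected rather than guessed. A truncated
#' final record or a sequence/quality length mismatch is an error.
#'
#' @param path FASTQ file
#' @param source source (tissue/dataset) label attached to every read
#' @return a [read_set()]
#' @export
read_fastq <- function(path, source = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("no records in ", path)
  if (length(lines) %% 4L != 0L) stop("truncated record at end of ", path)
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  plus <- lines[seq(3L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]
  if (any(substr(hdr, 1L, 1L) != "@") || any(substr(plus, 1L, 1L) != "+"))
    stop("malformed FASTQ record structure in ", path)
  id <- sub("\\s.*$", "", substring(hdr, 2L))
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad))
    stop("sequence/quality length mismatch for read '", id[bad[1L]], "'")
  pipeline_log("read_fastq", "%d reads from %s", length(id), path)
  read_set(id, seqs, qual, source)
}

#' Write a FASTQ file (Phred+33)
#'
#' Reads without qualities are written with a constant Q30 string.
#'
#' @param reads a [read_set()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qualities
  miss <- is.na(qual)
  if (any(miss)) qual[miss] <- strrep(rawToChar(as.raw(63L)),
                                      nchar(reads$residues[miss]))
  out <- character(4L * nrow(reads))
  out[seq(1L, length(out), by = 4L)] <- paste0("@", reads$id)
  out[seq(2L, length(out), by = 4L)] <- reads$residues
  out[seq(3L, length(out), by = 4L)] <- "+"
  out[seq(4L, length(out), by = 4L)] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Write a tree to Newick format
#'
#' Branch lengths are written with 6 significant digits and internal-node
#' bootstrap supports (the tree's `node.label`) as node labels. All leaves
#' must be named.
#'
#' @param tree an [ape::phylo] tree with non-negative branch lengths
#' @param path output file, or `NULL` to return the string
#' @return the Newick string, invisibly when written to a file
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$tip.label) || any(is.na(tree$tip.label)) ||
      any(!nzchar(tree$tip.label)))
    stop("unnamed leaf in tree")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch length")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt <- function(x) formatC(x, digits = 6L, format = "fg", flag = "#")
  lab <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    if (!is.null(tree$node.label)) {
      l <- tree$node.label[node - ntip]
      if (!is.na(l) && nzchar(l)) return(as.character(l))
    }
    ""
  }
  rec <- function(node) {
    ke <- kids[[as.character(node)]]
    if (is.null(ke)) return(lab(node))
    parts <- vapply(ke, function(e) {
      child <- tree$edge[e, 2L]
      s <- rec(child)
      if (!is.null(tree$edge.length))
        s <- paste0(s, ":", fmt(tree$edge.length[e]))
      s
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")", lab(node))
  }
  nwk <- paste0(rec(root), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Read a Newick tree
#'
#' @param path file, or a literal Newick string via `text`
#' @param text Newick string
#' @return an [ape::phylo] tree
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
}
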