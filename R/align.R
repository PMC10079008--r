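## Protein pairwise and progressive multiple alignment.

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Global pairwise protein alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment under a substitution matrix with affine gap
#' costs: a gap of length L costs `|gap_open| + L * |gap_extend|`.
#' Traceback ties prefer the diagonal, then up (a gap in `p2`), then left,
#' so the result is deterministic.
#'
#' @param p1,p2 protein strings (or one-record protein [seq_set()]s)
#' @param matrix substitution matrix (default BLOSUM62 from Biostrings)
#' @param gap_open gap opening penalty (default -10)
#' @param gap_extend gap extension penalty per residue (default -1)
#' @return list with `aligned1`, `aligned2` (gapped strings), `score`,
#'   and `identity` (matches / alignment columns)
#' @export
nw_align <- function(p1, p2, matrix = NULL, gap_open = -10, gap_extend = -1) {
  if (inherits(p1, "seq_set") || is.data.frame(p1)) p1 <- p1$residues[1L]
  if (inherits(p2, "seq_set") || is.data.frame(p2)) p2 <- p2$residues[1L]
  stopifnot(nchar(p1) >= 1L, nchar(p2) >= 1L)
  if (is.null(matrix)) matrix <- blosum62()
  a <- strsplit(p1, "", fixed = TRUE)[[1L]]
  b <- strsplit(p2, "", fixed = TRUE)[[1L]]
  bad <- setdiff(c(a, b), rownames(matrix))
  if (length(bad)) stop("residue not in substitution matrix: ", bad[1L])
  S <- matrix[a, b, drop = FALSE]
  dp <- nw_dp_cpp(unname(S), abs(gap_open), abs(gap_extend))
  al1 <- ifelse(dp$i == 0L, "-", a[pmax(dp$i, 1L)])
  al2 <- ifelse(dp$j == 0L, "-", b[pmax(dp$j, 1L)])
  list(aligned1 = paste(al1, collapse = ""),
       aligned2 = paste(al2, collapse = ""),
       score = dp$score,
       identity = mean(al1 == al2 & al1 != "-"))
}

#' Construct a multiple sequence alignment object
#'
#' @param ids sequence ids (unique)
#' @param aligned equal-length gapped sequences (`-` for gaps)
#' @return an `msa` object
#' @export
msa <- function(ids, aligned) {
  stopifnot(length(ids) == length(aligned))
  if (any(duplicated(ids))) stop("duplicate id: ", ids[duplicated(ids)][1L])
  if (length(unique(nchar(aligned))) != 1L)
    stop("alignment rows differ in length")
  m <- list(ids = as.character(ids), aligned = toupper(aligned),
            n_col = nchar(aligned[1L]))
  class(m) <- "msa"
  m
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", length(x$ids), x$n_col))
  invisible(x)
}

#' @method as.matrix msa
#' @export
as.matrix.msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$aligned, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

#' Remove gaps from an alignment row
#'
#' @param x gapped sequence string(s)
#' @return ungapped string(s)
#' @export
ungap <- function(x) gsub("-", "", x, fixed = TRUE)

# column-average profile-profile score matrix; gap-vs-residue scores 0
profile_score_matrix <- function(profA, profB, matrix) {
  residues <- rownames(matrix)
  countcol <- function(prof) {
    m <- do.call(rbind, strsplit(prof, "", fixed = TRUE))
    vapply(seq_len(ncol(m)), function(j) {
      tab <- table(factor(m[, j], levels = residues))
      as.numeric(tab)
    }, numeric(length(residues)))
  }
  ca <- countcol(profA)  # residues x ncolA
  cb <- countcol(profB)
  nA <- length(profA); nB <- length(profB)
  t(ca) %*% matrix %*% cb / (nA * nB)
}

# insert new gap columns into profile rows according to a DP path
apply_path <- function(prof, idx) {
  chars <- strsplit(prof, "", fixed = TRUE)
  vapply(chars, function(ch) {
    paste(ifelse(idx == 0L, "-", ch[pmax(idx, 1L)]), collapse = "")
  }, character(1))
}

#' Progressive multiple protein alignment
#'
#' Builds a guide tree by neighbor joining on pairwise
#' `1 - identity` distances from [nw_align()], then merges profiles in
#' guide-tree agglomeration order by profile-profile Needleman-Wunsch with
#' column-average substitution scoring (gap-vs-residue column scores are
#' 0). Row order in the result follows the input order, and removing gaps
#' from any row reproduces the input sequence exactly.
#'
#' @param proteins protein [seq_set()] with at least 2 records
#' @param matrix substitution matrix (default BLOSUM62)
#' @param gap_open,gap_extend affine gap penalties
#' @return an [msa()]
#' @export
progressive_msa <- function(proteins, matrix = NULL, gap_open = -10,
                            gap_extend = -1) {
  stopifnot(nrow(proteins) >= 2L)
  if (any(duplicated(proteins$id)))
    stop("duplicate id: ", proteins$id[duplicated(proteins$id)][1L])
  if (is.null(matrix)) matrix <- blosum62()
  n <- nrow(proteins)
  ids <- proteins$id
  if (n == 2L) {
    al <- nw_align(proteins$residues[1L], proteins$residues[2L], matrix,
                   gap_open, gap_extend)
    return(msa(ids, c(al$aligned1, al$aligned2)))
  }
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    al <- nw_align(proteins$residues[i], proteins$residues[j], matrix,
                   gap_open, gap_extend)
    D[i, j] <- D[j, i] <- 1 - al$identity
  }
  tr <- nj_tree(D)
  merges <- attr(tr, "join_order")
  # profiles keyed by cluster signature (sorted member ids)
  sig <- function(members) paste(sort(members), collapse = "\r")
  profs <- setNames(lapply(seq_len(n), function(i) {
    list(ids = ids[i], rows = proteins$residues[i])
  }), vapply(ids, sig, character(1)))
  for (m in merges) {
    a <- profs[[sig(m$left)]]
    b <- profs[[sig(m$right)]]
    S <- profile_score_matrix(a$rows, b$rows, matrix)
    dp <- nw_dp_cpp(unname(S), abs(gap_open), abs(gap_extend))
    rowsA <- apply_path(a$rows, dp$i)
    rowsB <- apply_path(b$rows, dp$j)
    merged <- list(ids = c(a$ids, b$ids), rows = c(rowsA, rowsB))
    profs[[sig(c(m$left, m$right))]] <- merged
  }
  final <- profs[[sig(ids)]]
  ord <- match(ids, final$ids)
  msa(ids, final$rows[ord])
}

#' Write a multiple alignment to FASTA
#'
#' @param aln an [msa()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_msa <- function(aln, path) {
  stopifnot(inherits(aln, "msa"))
  x <- Biostrings::BStringSet(aln$aligned)
  names(x) <- aln$ids
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Map a reference position across an alignment
#'
#' Finds the alignment column holding residue `ref_pos` (1-based,
#' ungapped) of the reference row and reports, for every row, the residue
#' in that column and its 1-based ungapped position (NA for a gap). This
#' implements reference-based numbering (for example "Y132, numbering
#' according to human LAT").
#'
#' @param aln an [msa()]
#' @param ref_id id of the reference row
#' @param ref_pos 1-based position in the ungapped reference sequence
#' @return data frame with `id`, `residue`, `position`, plus the
#'   alignment `column` as an attribute
#' @export
map_ref_position <- function(aln, ref_id, ref_pos) {
  stopifnot(inherits(aln, "msa"))
  ri <- match(ref_id, aln$ids)
  if (is.na(ri)) stop("reference id '", ref_id, "' not in alignment")
  refch <- strsplit(aln$aligned[ri], "", fixed = TRUE)[[1L]]
  ungapped <- cumsum(refch != "-")
  if (ref_pos < 1L || ref_pos > max(ungapped))
    stop("ref_pos outside ungapped reference length")
  col <- which(ungapped == ref_pos & refch != "-")[1L]
  rows <- strsplit(aln$aligned, "", fixed = TRUE)
  residue <- vapply(rows, `[`, character(1), col)
  position <- vapply(rows, function(ch) {
    if (ch[col] == "-") return(NA_integer_)
    sum(ch[seq_len(col)] != "-")
  }, integer(1))
  out <- data.frame(id = aln$ids, residue = residue, position = position,
                    stringsAsFactors = FALSE)
  attr(out, "column") <- col
  out
}
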