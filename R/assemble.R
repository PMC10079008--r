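## Greedy overlap-layout-consensus assembly of recruited reads.

# internal contig state: layout rows (id, offset 0-based, strand, oriented
# seq, oriented qualities), current consensus, sort key (smallest read id)
new_state <- function(id, seq, qual) {
  list(layout = data.frame(id = id, offset = 0L, strand = "+", seq = seq,
                           qual = qual, stringsAsFactors = FALSE),
       consensus = seq, key = id)
}

flip_state <- function(st) {
  len <- nchar(st$consensus)
  st$layout$offset <- len - (st$layout$offset + nchar(st$layout$seq))
  st$layout$strand <- ifelse(st$layout$strand == "+", "-", "+")
  st$layout$seq <- revcomp(st$layout$seq)
  st$layout$qual <- vapply(st$layout$qual, function(q)
    if (is.na(q)) q else paste(rev(strsplit(q, "")[[1L]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
  st$consensus <- revcomp(st$consensus)
  st
}

# weighted-majority consensus: weights are base qualities when present,
# else 1; ties resolved in the fixed base order A < C < G < T
consensus_from_layout <- function(layout) {
  lens <- nchar(layout$seq)
  total <- max(layout$offset + lens)
  w <- matrix(0, nrow = 4L, ncol = total)
  depth <- integer(total)
  for (r in seq_len(nrow(layout))) {
    idx <- layout$offset[r] + seq_len(lens[r])
    ch <- strsplit(layout$seq[r], "", fixed = TRUE)[[1L]]
    code <- match(ch, DNA_BASES)
    q <- if (is.na(layout$qual[r])) rep(1, lens[r]) else
      pmax(utf8ToInt(layout$qual[r]) - 33L, 1L)
    ok <- !is.na(code)
    cb <- cbind(code[ok], idx[ok])
    w[cb] <- w[cb] + q[ok]
    depth[idx] <- depth[idx] + 1L
  }
  base_idx <- max.col(t(w), ties.method = "first")
  cons <- DNA_BASES[base_idx]
  cons[colSums(w) == 0] <- "N"
  list(consensus = paste(cons, collapse = ""), depth = depth)
}

state_to_contig <- function(st) {
  cc <- consensus_from_layout(st$layout)
  out <- list(consensus = cc$consensus, depth = cc$depth,
              n_reads = nrow(st$layout),
              layout = st$layout[, c("id", "offset", "strand")])
  class(out) <- "contig"
  out
}

#' @export
print.contig <- function(x, ...) {
  cat(sprintf("<contig> %d nt from %d reads, mean depth %.1f\n",
              nchar(x$consensus), x$n_reads, mean(x$depth)))
  invisible(x)
}

# merge two states given the overlap config from many_overlaps_cpp:
# 1: x then y(+); 2: x then revcomp(y); 3: y(+) then x; 4: revcomp(y) then x
merge_states <- function(x, y, L, config) {
  if (config %in% c(2L, 4L)) {
    y <- flip_state(y)
    config <- config - 1L
  }
  if (config == 1L) {
    off <- nchar(x$consensus) - L
    y$layout$offset <- y$layout$offset + off
    layout <- rbind(x$layout, y$layout)
  } else {
    off <- nchar(y$consensus) - L
    x$layout$offset <- x$layout$offset + off
    layout <- rbind(y$layout, x$layout)
  }
  st <- list(layout = layout,
             consensus = consensus_from_layout(layout)$consensus,
             key = min(x$key, y$key))
  st
}

#' Greedy overlap-layout-consensus assembly
#'
#' Repeatedly merges the pair of reads/contigs with the longest
#' suffix-prefix overlap of at least `min_overlap` bases whose mismatch
#' rate is at most `max_mismatch_rate`, considering both orientations.
#' Ties prefer the longer resulting contig, then lexicographically smaller
#' read ids. The per-column consensus is a weighted majority (weights =
#' base qualities when present, else 1) with ties resolved in the fixed
#' base order A < C < G < T. Stops when no merge qualifies.
#'
#' @param reads a [read_set()] (or data frame with `id`, `residues` and
#'   optionally `qualities`)
#' @param min_overlap minimum overlap length (default 30)
#' @param max_mismatch_rate maximum overlap mismatch rate (default 0.02)
#' @return list of `contig` objects sorted by consensus length descending
#' @export
greedy_assemble <- function(reads, min_overlap = 30L,
                            max_mismatch_rate = 0.02) {
  stopifnot(nrow(reads) >= 1L)
  qual <- if ("qualities" %in% names(reads)) reads$qualities else
    rep(NA_character_, nrow(reads))
  n0 <- nrow(reads)
  cap <- 2L * n0
  states <- vector("list", cap)
  alive <- logical(cap)
  for (i in seq_len(n0)) {
    states[[i]] <- new_state(reads$id[i], reads$residues[i], qual[i])
    alive[i] <- TRUE
  }
  L <- matrix(0L, cap, cap)
  CFG <- matrix(0L, cap, cap)
  XID <- matrix(0L, cap, cap)
  fill_row <- function(a, others) {
    if (!length(others)) return()
    ov <- many_overlaps_cpp(states[[a]]$consensus,
                            vapply(others, function(j)
                              states[[j]]$consensus, character(1)),
                            min_overlap, max_mismatch_rate)
    L[a, others] <<- ov$overlap
    L[others, a] <<- ov$overlap
    CFG[a, others] <<- ov$config
    CFG[others, a] <<- ov$config
    XID[a, others] <<- a
    XID[others, a] <<- a
  }
  for (i in seq_len(n0 - 1L)) fill_row(i, (i + 1L):n0)
  nxt <- n0 + 1L
  repeat {
    act <- which(alive)
    if (length(act) < 2L) break
    sub <- L[act, act, drop = FALSE]
    best <- max(sub)
    if (best < min_overlap) break
    cand <- which(sub == best, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    a <- act[cand[, 1L]]
    b <- act[cand[, 2L]]
    res_len <- nchar(vapply(states[a], `[[`, character(1), "consensus")) +
      nchar(vapply(states[b], `[[`, character(1), "consensus")) - best
    k1 <- pmin(vapply(states[a], `[[`, character(1), "key"),
               vapply(states[b], `[[`, character(1), "key"))
    k2 <- pmax(vapply(states[a], `[[`, character(1), "key"),
               vapply(states[b], `[[`, character(1), "key"))
    pick <- order(-res_len, k1, k2)[1L]
    i <- a[pick]; j <- b[pick]
    x <- if (XID[i, j] == i) i else j
    y <- if (x == i) j else i
    merged <- merge_states(states[[x]], states[[y]], L[i, j], CFG[i, j])
    if (nxt > cap) stop("assembly state overflow")  # cannot happen
    states[[nxt]] <- merged
    alive[c(i, j)] <- FALSE
    alive[nxt] <- TRUE
    L[c(i, j), ] <- 0L
    L[, c(i, j)] <- 0L
    fill_row(nxt, setdiff(which(alive), nxt))
    nxt <- nxt + 1L
  }
  contigs <- lapply(which(alive), function(i) state_to_contig(states[[i]]))
  len <- vapply(contigs, function(cg) nchar(cg$consensus), numeric(1))
  key <- vapply(which(alive), function(i) states[[i]]$key, character(1))
  contigs <- contigs[order(-len, key)]
  pipeline_log("assemble", "%d reads -> %d contigs (longest %d nt)",
               n0, length(contigs), max(len))
  contigs
}

#' Iterative homology rescue of a gene from raw reads
#'
#' One round = recruit reads against the current bait, assemble the
#' recruited set, and promote the longest contig (oriented to the strand
#' that aligns best to the current bait) to be the next bait. Rounds stop
#' when the recruited read set no longer changes or `max_rounds` is
#' reached. This is how a short or diverged bait is extended to a
#' full-length coding sequence.
#'
#' @param reads a [read_set()]
#' @param initial_bait DNA string or one-record DNA [seq_set()]
#' @param scheme a [scoring_scheme()]
#' @param max_rounds maximum recruit/assemble rounds (default 5)
#' @param min_overlap,max_mismatch_rate assembly thresholds
#' @return list with `contig` (final longest contig), `rounds`
#'   (data frame of per-round recruitment counts) and `final_bait`
#' @export
iterative_rescue <- function(reads, initial_bait, scheme = scoring_scheme(),
                             max_rounds = 5L, min_overlap = 30L,
                             max_mismatch_rate = 0.02) {
  bait <- if (inherits(initial_bait, "seq_set") ||
              is.data.frame(initial_bait)) initial_bait$residues[1L]
          else initial_bait
  prev_ids <- NULL
  contig <- NULL
  counts <- integer(0)
  for (round in seq_len(max_rounds)) {
    hits <- recruit(reads, bait, scheme)
    if (round == 1L && nrow(hits) == 0L)
      stop("no reads recruited: bait too diverged or threshold too strict")
    counts[round] <- nrow(hits)
    pipeline_log("rescue", "round %d: %d reads recruited", round,
                 nrow(hits))
    ids <- sort(hits$read_id)
    if (!is.null(prev_ids) && identical(ids, prev_ids)) break
    prev_ids <- ids
    sub <- reads[match(hits$read_id, reads$id), , drop = FALSE]
    contigs <- greedy_assemble(sub, min_overlap, max_mismatch_rate)
    cg <- contigs[[1L]]
    # canonical orientation: the strand aligning best to the current bait
    h <- score_read(cg$consensus, bait, scheme)
    if (!is.null(h) && h$strand == "-") {
      st <- list(layout = data.frame(id = cg$layout$id,
                                     offset = cg$layout$offset,
                                     strand = cg$layout$strand,
                                     seq = NA, qual = NA),
                 consensus = cg$consensus, key = "")
      cg$consensus <- revcomp(cg$consensus)
      cg$depth <- rev(cg$depth)
      len <- nchar(cg$consensus)
      cg$layout$offset <- len - (cg$layout$offset +
        vapply(cg$layout$id, function(i)
          nchar(reads$residues[match(i, reads$id)]), numeric(1)))
      cg$layout$strand <- ifelse(cg$layout$strand == "+", "-", "+")
    }
    contig <- cg
    bait <- cg$consensus
  }
  list(contig = contig,
       rounds = data.frame(round = seq_along(counts),
                           n_recruited = counts),
       final_bait = bait)
}

#' Find open reading frames in a contig
#'
#' ORFs are ATG...stop in all six frames with at least `min_aa` codons
#' (excluding the stop). Each ORF is reported with its frame (0-2),
#' strand, 0-based half-open nucleotide interval on the forward input
#' sequence (stop codon included) and translation under the standard
#' genetic code. The longest ORF is flagged as the candidate CDS.
#'
#' @param contig DNA string, `contig` object or one-record DNA [seq_set()]
#' @param min_aa minimum ORF length in codons (default 50)
#' @return data frame sorted by ORF length descending: `strand`, `frame`,
#'   `start`, `end`, `aa_length`, `translation`, `is_candidate`
#' @export
find_orfs <- function(contig, min_aa = 50L) {
  dna <- if (inherits(contig, "contig")) contig$consensus
         else if (is.data.frame(contig)) contig$residues[1L]
         else contig
  dna <- toupper(dna)
  stopifnot(nchar(dna) >= 3L)
  Lnt <- nchar(dna)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else revcomp(dna)
    for (f in 0:2) {
      sub <- substr(s, f + 1L, Lnt)
      if (nchar(sub) < 3L) next
      prot <- translate_dna(sub)
      stops <- c(gregexpr("\\*", prot)[[1L]])
      stops <- stops[stops > 0L]
      seg_start <- 1L
      for (t in stops) {
        seg <- substr(prot, seg_start, t - 1L)
        m <- regexpr("M", seg, fixed = TRUE)
        if (m > 0L) {
          m_abs <- seg_start + m - 1L
          aa_len <- t - m_abs
          if (aa_len >= min_aa) {
            nt_s <- f + 3L * (m_abs - 1L)          # 0-based, this strand
            nt_e <- f + 3L * t                     # includes stop codon
            if (strand == "-") {
              tmp <- nt_s
              nt_s <- Lnt - nt_e
              nt_e <- Lnt - tmp
            }
            rows[[length(rows) + 1L]] <- data.frame(
              strand = strand, frame = f, start = nt_s, end = nt_e,
              aa_length = aa_len,
              translation = substr(prot, m_abs, t - 1L),
              stringsAsFactors = FALSE)
          }
        }
        seg_start <- t + 1L
      }
    }
  }
  if (!length(rows))
    return(data.frame(strand = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      aa_length = integer(0), translation = character(0),
                      is_candidate = logical(0)))
  out <- do.call(rbind, rows)
  out <- out[order(-out$aa_length, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$is_candidate <- seq_len(nrow(out)) == 1L
  out
}
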