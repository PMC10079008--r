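options(gcrescue.verbose = FALSE)

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(1 - gc, gc, gc, 1 - gc) / 2), collapse = "")
}

random_protein <- function(n, alphabet = gcrescue:::AA_STANDARD) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# independent run-enumeration oracle for G/C stretches: regex matching
oracle_stretches <- function(seq, min_len) {
  m <- gregexpr(sprintf("[GC]{%d,}", min_len), seq)[[1L]]
  if (m[1L] < 0L) return(cbind(start = integer(0), end = integer(0)))
  cbind(start = as.integer(m) - 1L,
        end = as.integer(m) + attr(m, "match.length") - 1L)
}

# independent local-alignment oracle (Biostrings C implementation)
oracle_local_score <- function(read, bait, scheme = scoring_scheme()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scheme$match, mismatch = scheme$mismatch, baseOnly = TRUE)
  best <- -Inf
  for (s in c(read, as.character(revcomp(read)))) {
    a <- Biostrings::pairwiseAlignment(
      s, bait, type = "local", substitutionMatrix = mat,
      gapOpening = abs(scheme$gap_open), gapExtension = abs(scheme$gap_extend),
      scoreOnly = TRUE)
    best <- max(best, a)
  }
  best
}

# brute-force global affine alignment score by exhaustive path enumeration
# (gap of length L costs open + L * ext, matching the package convention)
oracle_global_score <- function(a, b, matrix, open = 10, ext = 1) {
  a <- strsplit(a, "", fixed = TRUE)[[1L]]
  b <- strsplit(b, "", fixed = TRUE)[[1L]]
  # state: 0 none/diag, 1 gap-in-b (consumed a), 2 gap-in-a
  rec <- function(i, j, state) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b))
      best <- max(best, matrix[a[i], b[j]] + rec(i + 1L, j + 1L, 0L))
    if (i <= length(a)) {
      cost <- if (state == 1L) ext else open + ext
      best <- max(best, -cost + rec(i + 1L, j, 1L))
    }
    if (j <= length(b)) {
      cost <- if (state == 2L) ext else open + ext
      best <- max(best, -cost + rec(i, j + 1L, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# additive distance matrix from a random tree (path lengths)
additive_matrix <- function(ntaxa, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(ntaxa, br = function(n) runif(n, 0.05, 1))
    tr <- ape::unroot(tr)
    list(tree = tr, D = ape::cophenetic.phylo(tr))
  })
}
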