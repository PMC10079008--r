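## Distance-based phylogeny: p/Poisson distances, Saitou-Nei neighbor
## joining, column-bootstrap supports, Robinson-Foulds topology distance.

#' Pairwise distances from a protein alignment
#'
#' For each pair of rows, only columns where neither row is gapped are
#' compared. `p` is the mismatch proportion over those columns;
#' `poisson` applies the multiple-hit correction `d = -ln(1 - p)` (an
#' error when `p = 1`).
#'
#' @param aln an [msa()]
#' @param model `"p"` or `"poisson"`
#' @return symmetric distance matrix with zero diagonal, labeled by row id
#' @export
pairwise_distances <- function(aln, model = c("poisson", "p")) {
  stopifnot(inherits(aln, "msa"), length(aln$ids) >= 2L)
  model <- match.arg(model)
  m <- as.matrix(aln)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok))
      stop("no comparable columns between '", aln$ids[i], "' and '",
           aln$ids[j], "'")
    p <- mean(m[i, ok] != m[j, ok])
    if (model == "poisson") {
      if (p >= 1) stop("p-distance of 1 between '", aln$ids[i], "' and '",
                       aln$ids[j], "': Poisson correction undefined")
      p <- -log(1 - p)
    }
    D[i, j] <- D[j, i] <- p
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining: iteratively joins the pair of clusters
#' minimizing the Q-criterion, with branch lengths from the standard NJ
#' formulas. Negative branch lengths are clamped to 0 (logged). Q-ties
#' are broken by lexicographic taxon-pair order (clusters are keyed by
#' their smallest member label), so the result is deterministic. The
#' returned tree is unrooted (trifurcating root node).
#'
#' @param dist symmetric distance matrix with labels (or a [stats::dist])
#' @return an [ape::phylo] tree; the agglomeration schedule is attached as
#'   attribute `join_order` (used as a guide order by [progressive_msa()])
#' @export
nj_tree <- function(dist) {
  D <- as.matrix(dist)
  labels <- rownames(D)
  if (is.null(labels)) stop("distance matrix must have labels")
  n <- nrow(D)
  stopifnot(n >= 3L, isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
  frag <- setNames(as.list(labels), labels)       # newick fragments
  members <- setNames(as.list(labels), labels)    # member ids per cluster
  active <- labels
  joins <- list()
  clamped <- 0L
  fmt <- function(x) sprintf("%.10g", x)
  while (length(active) > 3L) {
    nn <- length(active)
    d <- D[active, active]
    r <- rowSums(d)
    Q <- (nn - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    keyv <- vapply(active, function(x) min(members[[x]]), character(1))
    k1 <- pmin(keyv[cand[, 1L]], keyv[cand[, 2L]])
    k2 <- pmax(keyv[cand[, 1L]], keyv[cand[, 2L]])
    pick <- order(k1, k2)[1L]
    i <- active[cand[pick, 1L]]
    j <- active[cand[pick, 2L]]
    dij <- D[i, j]
    vi <- 0.5 * dij + (r[i] - r[j]) / (2 * (nn - 2))
    vj <- dij - vi
    if (vi < 0 || vj < 0) clamped <- clamped + 1L
    vi <- max(vi, 0); vj <- max(vj, 0)
    u <- paste0("join", length(joins) + 1L, "_")
    frag[[u]] <- paste0("(", frag[[i]], ":", fmt(vi), ",",
                        frag[[j]], ":", fmt(vj), ")")
    members[[u]] <- c(members[[i]], members[[j]])
    joins[[length(joins) + 1L]] <- list(left = members[[i]],
                                        right = members[[j]])
    others <- setdiff(active, c(i, j))
    newd <- 0.5 * (D[i, others] + D[j, others] - dij)
    D <- rbind(cbind(D, 0), 0)
    rownames(D)[nrow(D)] <- colnames(D)[ncol(D)] <- u
    D[u, others] <- newd
    D[others, u] <- newd
    active <- c(others, u)
  }
  a <- active[1L]; b <- active[2L]; c3 <- active[3L]
  va <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  vb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  vc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  if (min(va, vb, vc) < 0) clamped <- clamped + 1L
  va <- max(va, 0); vb <- max(vb, 0); vc <- max(vc, 0)
  if (clamped > 0L)
    pipeline_log("nj_tree", "%d negative branch length(s) clamped to 0",
                 clamped)
  nwk <- paste0("(", frag[[a]], ":", fmt(va), ",", frag[[b]], ":", fmt(vb),
                ",", frag[[c3]], ":", fmt(vc), ");")
  # final-three agglomeration order for guide use: closest pair first
  keys <- vapply(list(members[[a]], members[[b]], members[[c3]]),
                 function(m) min(unlist(m)), character(1))
  dd <- c(ab = D[a, b], ac = D[a, c3], bc = D[b, c3])
  prs <- list(ab = c(1L, 2L), ac = c(1L, 3L), bc = c(2L, 3L))
  pk <- vapply(prs, function(p) paste(sort(keys[p]), collapse = "\r"),
               character(1))
  first <- names(dd)[order(dd, pk)][1L]
  p <- prs[[first]]
  mem <- list(members[[a]], members[[b]], members[[c3]])
  joins[[length(joins) + 1L]] <- list(left = mem[[p[1L]]],
                                      right = mem[[p[2L]]])
  joins[[length(joins) + 1L]] <- list(
    left = c(mem[[p[1L]]], mem[[p[2L]]]),
    right = mem[[setdiff(1:3, p)]])
  tr <- ape::read.tree(text = nwk)
  attr(tr, "join_order") <- joins
  tr
}

# tip labels of the clade below each node (index = ape node number)
clade_tips <- function(phy) {
  ntip <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  tips <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) tips[[i]] <- phy$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    tips[[p]] <- c(tips[[p]], tips[[ch]])
  }
  tips
}

# canonical keys for the nontrivial bipartitions of an unrooted tree
tree_bipartitions <- function(phy) {
  ntip <- length(phy$tip.label)
  all_tips <- sort(phy$tip.label)
  anchor <- all_tips[1L]
  tips <- clade_tips(phy)
  root <- ntip + 1L
  internal <- setdiff(unique(phy$edge[, 2L]), seq_len(ntip))
  keys <- vapply(internal, function(node) {
    side <- tips[[node]]
    if (length(side) < 2L || length(side) > ntip - 2L) return(NA_character_)
    if (anchor %in% side) side <- setdiff(all_tips, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  stats::setNames(keys[!is.na(keys)], NULL)
}

#' Robinson-Foulds distance between two trees
#'
#' The number of nontrivial bipartitions present in exactly one of the
#' two unrooted trees; 0 means identical topologies.
#'
#' @param t1,t2 [ape::phylo] trees over the same leaf set
#' @return integer RF distance
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Columns of the alignment are resampled with replacement
#' `n_replicates` times; each replicate is run through
#' [pairwise_distances()] and [nj_tree()]. The support of each internal
#' edge of the tree built from the original alignment is the percent of
#' replicates containing the same bipartition. Supports are attached as
#' internal-node labels (root label empty).
#'
#' @param aln an [msa()] with at least 4 rows (3-taxon trees have no
#'   internal edge)
#' @param n_replicates bootstrap replicates (default 500)
#' @param seed RNG seed
#' @param model distance model passed to [pairwise_distances()]
#' @return the [ape::phylo] tree from the full alignment with `node.label`
#'   giving percent support for each internal edge
#' @export
bootstrap_supports <- function(aln, n_replicates = 500L, seed = 42L,
                               model = "poisson") {
  stopifnot(inherits(aln, "msa"), n_replicates >= 1L)
  tree <- nj_tree(pairwise_distances(aln, model))
  ntip <- length(tree$tip.label)
  keys <- tree_bipartitions(tree)
  counts <- setNames(numeric(length(keys)), keys)
  cols <- as.matrix(aln)
  with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      idx <- sample.int(ncol(cols), replace = TRUE)
      rep_aln <- msa(aln$ids, apply(cols[, idx, drop = FALSE], 1L, paste,
                                    collapse = ""))
      rep_tree <- nj_tree(pairwise_distances(rep_aln, model))
      hit <- intersect(tree_bipartitions(rep_tree), keys)
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- 100 * counts / n_replicates
  # map supports onto internal nodes via their bipartition keys
  tips <- clade_tips(tree)
  all_tips <- sort(tree$tip.label)
  anchor <- all_tips[1L]
  labs <- character(tree$Nnode)
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    side <- tips[[node]]
    if (length(side) < 2L || length(side) > ntip - 2L ||
        node == ntip + 1L) {
      labs[node - ntip] <- ""
      next
    }
    if (anchor %in% side) side <- setdiff(all_tips, side)
    key <- paste(sort(side), collapse = "|")
    labs[node - ntip] <- if (key %in% names(support))
      sprintf("%g", support[[key]]) else ""
  }
  tree$node.label <- labs
  attr(tree, "support") <- support
  tree
}
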