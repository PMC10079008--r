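#' Parameters for a LAT-like protein scaffold
#'
#' Describes the planted features of a synthetic transmembrane-adaptor
#' protein modeled on LAT: a juxtamembrane palmitoylation cysteine pair
#' (C-x-x-C), four phosphorylatable docking tyrosines (reference numbering
#' 132/171/191/226), the residue immediately before the first (PLC-gamma
#' binding) tyrosine — glycine in tetrapods, aspartate/glutamate in some
#' fish — a proline-enriched region, and optionally the exact LCK-binding
#' hexapeptide `PIPRSP` (absent from the avian-like scaffold by default).
#' The first docking tyrosine carries the context `Y-L-V-V`; the scaffold
#' starts with an initiator methionine so its reverse-translation is an
#' ATG-initiated open reading frame.
#'
#' @param protein_length residues (default 230)
#' @param dicysteine_position 1-based index of the first Cys of the
#'   C-x-x-C pair (default 26; the partner Cys sits at +3)
#' @param docking_tyrosine_positions four 1-based indices
#'   (default `c(132, 171, 191, 226)`)
#' @param plc_context_residue residue placed immediately before the first
#'   docking tyrosine, one of G, D, E (default `"G"`)
#' @param proline_region 1-based inclusive interval enriched for proline
#'   (default `c(30, 100)`)
#' @param proline_prob proline probability inside the region (default 0.4)
#' @param include_pip_motif plant the exact hexapeptide `PIPRSP`?
#' @param pip_position 1-based start of the planted `PIPRSP` (default 104)
#' @param background_bias `"uniform"` (default): residues outside planted
#'   sites drawn uniformly from the non-C, non-Y amino acids;
#'   `"gc_rich"`: G/A/P/R (each offering a fully-GC codon) are drawn with
#'   4-fold weight, emulating the amino-acid composition of GC-extreme
#'   genes and guaranteeing that ~72% GC is reachable by synonymous codon
#'   choice alone for every seed
#' @return a validated `lat_scaffold_params` list
#' @export
lat_scaffold_params <- function(protein_length = 230L,
                                dicysteine_position = 26L,
                                docking_tyrosine_positions = c(132L, 171L,
                                                               191L, 226L),
                                plc_context_residue = "G",
                                proline_region = c(30L, 100L),
                                proline_prob = 0.4,
                                include_pip_motif = FALSE,
                                pip_position = 104L,
                                background_bias = c("uniform", "gc_rich")) {
  stopifnot(length(docking_tyrosine_positions) == 4L,
            plc_context_residue %in% c("G", "D", "E"),
            length(proline_region) == 2L,
            proline_region[1L] <= proline_region[2L])
  p <- list(protein_length = as.integer(protein_length),
            dicysteine_position = as.integer(dicysteine_position),
            docking_tyrosine_positions =
              as.integer(docking_tyrosine_positions),
            plc_context_residue = plc_context_residue,
            proline_region = as.integer(proline_region),
            proline_prob = proline_prob,
            include_pip_motif = isTRUE(include_pip_motif),
            pip_position = as.integer(pip_position),
            background_bias = match.arg(background_bias))
  sites <- scaffold_planted_sites(p)
  if (any(sites$pos > p$protein_length) || any(sites$pos < 1L))
    stop("planted position outside protein length")
  if (any(duplicated(sites$pos)))
    stop("planted positions overlap")
  class(p) <- "lat_scaffold_params"
  p
}

# positions (1-based) and fixed residues planted by the scaffold
scaffold_planted_sites <- function(params) {
  pos <- 1L
  res <- "M"
  d <- params$dicysteine_position
  pos <- c(pos, d, d + 3L)
  res <- c(res, "C", "C")
  y <- params$docking_tyrosine_positions
  # first docking tyrosine: context residue, then Y-L-V-V
  pos <- c(pos, y[1L] - 1L, y[1L], y[1L] + 1L, y[1L] + 2L, y[1L] + 3L)
  res <- c(res, params$plc_context_residue, "Y", "L", "V", "V")
  # tyrosines 2-4 in a Y-x-N context (x filled randomly later)
  for (k in 2:4) {
    pos <- c(pos, y[k], y[k] + 2L)
    res <- c(res, "Y", "N")
  }
  if (params$include_pip_motif) {
    pos <- c(pos, params$pip_position + 0:5)
    res <- c(res, strsplit("PIPRSP", "")[[1L]])
  }
  data.frame(pos = pos, res = res, stringsAsFactors = FALSE)
}

#' Planted (invariant) sites of a scaffold
#'
#' The 1-based positions fixed by [make_lat_like_protein()]; useful as the
#' `invariant_sites` argument of [evolve_orthologs()] so the motif panel
#' survives divergence.
#'
#' @param params a [lat_scaffold_params()]
#' @return sorted integer vector of 1-based positions
#' @export
scaffold_invariant_sites <- function(params = lat_scaffold_params()) {
  sort(scaffold_planted_sites(params)$pos)
}

#' Generate a LAT-like protein scaffold
#'
#' A random protein with the motif panel of [lat_scaffold_params()]
#' planted at the stated positions. Residues outside planted sites are
#' drawn uniformly from the non-cysteine, non-tyrosine amino acids (so
#' planted motifs are unique with high probability); inside the proline
#' region, proline is drawn with probability `proline_prob`.
#'
#' @param params a [lat_scaffold_params()]
#' @param seed RNG seed
#' @return a protein [seq_set()] with one record
#' @export
make_lat_like_protein <- function(params = lat_scaffold_params(),
                                  seed = 42L) {
  stopifnot(inherits(params, "lat_scaffold_params"))
  with_seed(seed, {
    L <- params$protein_length
    bg <- setdiff(AA_STANDARD, c("C", "Y"))
    w <- rep(1, length(bg))
    if (params$background_bias == "gc_rich")
      w[bg %in% c("G", "A", "P", "R")] <- 4
    aa <- sample(bg, L, replace = TRUE, prob = w)
    reg <- params$proline_region
    idx <- reg[1L]:reg[2L]
    put_p <- runif(length(idx)) < params$proline_prob
    aa[idx[put_p]] <- "P"
    sites <- scaffold_planted_sites(params)
    aa[sites$pos] <- sites$res
    seq_set("scaffold", paste(aa, collapse = ""),
            "synthetic LAT-like protein scaffold", alphabet = "PROTEIN")
  })
}

# synonymous codon tables from the standard genetic code
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Reverse-translate a protein with a GC-content bias
#'
#' Codon choice per site samples among synonymous codons with weights
#' `exp(beta * gc_count(codon))`; `beta` is tuned by bisection so that the
#' expected GC of the coding sequence matches `target_gc`, and a final
#' deterministic adjustment pass swaps synonymous codons until the
#' realized GC is within 0.02 of the target (or of the closest achievable
#' bound for extreme targets). The CDS has length `3 * nchar(protein) + 3`
#' (a stop codon is appended) and translates exactly back to the input.
#'
#' @param protein a protein string or one-record protein [seq_set()]
#' @param target_gc target GC fraction in `[0.25, 0.95]`
#' @param seed RNG seed
#' @return a DNA [seq_set()] with one record
#' @export
reverse_translate_gc_biased <- function(protein, target_gc, seed = 42L) {
  if (inherits(protein, "seq_set") || is.data.frame(protein)) {
    id <- protein$id[1L]
    protein <- protein$residues[1L]
  } else id <- "cds"
  stopifnot(target_gc >= 0.25, target_gc <= 0.95)
  aa <- c(strsplit(protein, "", fixed = TRUE)[[1L]], "*")
  tab <- codon_table()
  if (!all(aa %in% names(tab))) stop("untranslatable residue in protein")
  gc_of <- function(codons) nchar(gsub("[^GC]", "", codons))
  cods <- tab[aa]
  gcs <- lapply(cods, gc_of)
  total_nt <- 3L * length(aa)

  exp_gc <- function(beta) {
    e <- vapply(gcs, function(g) {
      w <- exp(beta * g)
      sum(w * g) / sum(w)
    }, numeric(1))
    sum(e) / total_nt
  }
  lo <- exp_gc(-40); hi <- exp_gc(40)
  clamped <- min(max(target_gc, lo), hi)
  if (abs(clamped - target_gc) > 0.05)
    stop(sprintf(
      "target GC %.3f unreachable; achievable range [%.3f, %.3f]",
      target_gc, lo, hi))
  b_lo <- -40; b_hi <- 40
  for (i in 1:60) {
    mid <- (b_lo + b_hi) / 2
    if (exp_gc(mid) < clamped) b_lo <- mid else b_hi <- mid
  }
  beta <- (b_lo + b_hi) / 2

  with_seed(seed, {
    chosen <- vapply(seq_along(cods), function(i) {
      w <- exp(beta * gcs[[i]])
      cods[[i]][sample.int(length(cods[[i]]), 1L, prob = w)]
    }, character(1))
    # deterministic correction toward the (possibly clamped) target
    realized <- sum(vapply(chosen, function(c) gc_of(c), numeric(1)))
    want <- clamped * total_nt
    order_sites <- sample.int(length(chosen))  # seeded, fixed visit order
    for (i in order_sites) {
      if (abs(realized - want) <= 0.02 * total_nt) break
      g_now <- gc_of(chosen[i])
      alt <- cods[[i]]
      g_alt <- gcs[[i]]
      delta <- want - realized
      j <- if (delta > 0) which.max(g_alt) else which.min(g_alt)
      if ((delta > 0 && g_alt[j] > g_now) ||
          (delta < 0 && g_alt[j] < g_now)) {
        realized <- realized - g_now + g_alt[j]
        chosen[i] <- alt[j]
      }
    }
    seq_set(id, paste(chosen, collapse = ""),
            sprintf("GC-biased reverse translation (target %.2f)", target_gc),
            alphabet = "DNA")
  })
}

#' Evolve a protein along a tree
#'
#' Along each branch of length `b` (expected substitutions per site), each
#' non-invariant site substitutes with probability `1 - exp(-b)`; the
#' replacement is drawn uniformly from the 19 other residues. Sites listed
#' in `invariant_sites` (for example planted motifs) are never touched.
#'
#' @param root_protein protein string or one-record protein [seq_set()]
#' @param tree an [ape::phylo] tree or Newick string with branch lengths
#' @param invariant_sites 1-based positions held fixed
#' @param seed RNG seed
#' @return a protein [seq_set()] with one record per leaf, named by leaf
#'   label, in tip-label order
#' @export
evolve_orthologs <- function(root_protein, tree, invariant_sites = integer(0),
                             seed = 42L) {
  if (inherits(root_protein, "seq_set") || is.data.frame(root_protein))
    root_protein <- root_protein$residues[1L]
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  L <- nchar(root_protein)
  invariant_sites <- as.integer(invariant_sites)
  if (length(invariant_sites) && (min(invariant_sites) < 1L ||
                                  max(invariant_sites) > L))
    stop("invariant site outside protein length")
  mutable <- setdiff(seq_len(L), invariant_sites)

  with_seed(seed, {
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    seqs <- vector("list", nnode)
    root <- ntip + 1L
    seqs[[root]] <- strsplit(root_protein, "", fixed = TRUE)[[1L]]
    ord <- reorder(tree, "cladewise")  # parent before child
    for (e in seq_len(nrow(ord$edge))) {
      par <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
      b <- ord$edge.length[e]
      s <- seqs[[par]]
      if (b > 0 && length(mutable)) {
        hit <- mutable[runif(length(mutable)) < (1 - exp(-b))]
        for (i in hit) s[i] <- sample(setdiff(AA_STANDARD, s[i]), 1L)
      }
      seqs[[child]] <- s
    }
    res <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                  character(1))
    seq_set(tree$tip.label, res, "evolved ortholog", alphabet = "PROTEIN")
  })
}

#' Simulate single-end sequencing reads
#'
#' Each read picks a template with probability proportional to
#' `weight * template_length`, a uniform start position and a uniform
#' strand (reverse-complemented on minus). Each base flips to a uniformly
#' chosen different base with probability `error_rate`; an optional indel
#' mode (off by default) additionally deletes or inserts bases at
#' `indel_rate` per position, for stress-testing the assembler. The true
#' origin (`template|start|strand`) is recorded in the read id and
#' qualities are constant Q30.
#'
#' @param templates DNA [seq_set()] (or data frame with `id`, `residues`)
#' @param weights abundance weights, one per template (default equal)
#' @param n_reads number of reads
#' @param read_length read length; must not exceed the shortest template
#' @param error_rate per-base substitution probability
#' @param indel_rate per-base indel probability (default 0)
#' @param seed RNG seed
#' @param source source label stored with each read
#' @return a [read_set()]
#' @export
simulate_reads <- function(templates, n_reads, read_length = 100L,
                           error_rate = 0, weights = NULL, indel_rate = 0,
                           seed = 42L, source = "") {
  tlen <- nchar(templates$residues)
  if (is.null(weights)) weights <- rep(1, nrow(templates))
  stopifnot(length(weights) == nrow(templates), all(weights >= 0),
            any(weights > 0), read_length <= min(tlen), n_reads >= 0)
  if (n_reads == 0L)
    return(read_set(character(0), character(0), character(0), source))
  with_seed(seed, {
    p <- weights * tlen
    ti <- sample.int(nrow(templates), n_reads, replace = TRUE, prob = p)
    start <- floor(runif(n_reads) * (tlen[ti] - read_length + 1))
    minus <- runif(n_reads) < 0.5
    reads <- substring(templates$residues[ti], start + 1L,
                       start + read_length)
    if (any(minus)) reads[minus] <- revcomp(reads[minus])
    if (error_rate > 0) {
      nerr <- rbinom(n_reads, read_length, error_rate)
      which_err <- which(nerr > 0L)
      if (length(which_err)) {
        mat <- matrix(unlist(strsplit(reads[which_err], "", fixed = TRUE)),
                      nrow = length(which_err), byrow = TRUE)
        ridx <- rep(seq_along(which_err), nerr[which_err])
        pos <- unlist(lapply(nerr[which_err], sample.int,
                             n = read_length))
        cur <- mat[cbind(ridx, pos)]
        shift <- sample.int(3L, length(cur), replace = TRUE)
        code <- match(cur, DNA_BASES)
        mat[cbind(ridx, pos)] <- DNA_BASES[(code - 1L + shift) %% 4L + 1L]
        reads[which_err] <- do.call(paste0, as.data.frame(mat))
      }
    }
    if (indel_rate > 0) {
      for (i in seq_len(n_reads)) {
        ch <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
        keep <- runif(length(ch)) >= indel_rate / 2
        ch <- ch[keep]
        ins <- which(runif(length(ch)) < indel_rate / 2)
        for (k in rev(ins))
          ch <- append(ch, sample(DNA_BASES, 1L), after = k)
        reads[i] <- paste(ch, collapse = "")
      }
    }
    ids <- sprintf("r%07d|%s|%d|%s", seq_len(n_reads), templates$id[ti],
                   start, ifelse(minus, "-", "+"))
    qual <- strrep("?", nchar(reads))  # '?' = Phred 30
    read_set(ids, reads, qual, source)
  })
}

#' Embed a CDS in a synthetic transcript
#'
#' Adds random UTR flanks around a coding sequence. The last three bases
#' of the 5' UTR are forced to a stop codon in frame with the CDS, so the
#' planted ATG...stop open reading frame is exactly the recoverable unit
#' (as for an annotated ORF with an upstream in-frame stop); without this
#' a chance upstream in-frame ATG could extend the ORF beyond the planted
#' protein.
#'
#' @param cds one-record DNA [seq_set()] or DNA string
#' @param utr5,utr3 flank lengths (default 100; `utr5` >= 3)
#' @param gc flank GC fraction (default 0.5)
#' @param seed RNG seed
#' @return one-record DNA [seq_set()]; the CDS interval (0-based
#'   half-open) is attached as attribute `cds_interval`
#' @export
make_transcript <- function(cds, utr5 = 100L, utr3 = 100L, gc = 0.5,
                            seed = 42L) {
  if (inherits(cds, "seq_set") || is.data.frame(cds)) {
    id <- cds$id[1L]
    cds <- cds$residues[1L]
  } else id <- "cds"
  stopifnot(utr5 >= 3L, utr3 >= 0L, gc >= 0, gc <= 1)
  with_seed(seed, {
    prob <- c(1 - gc, gc, gc, 1 - gc) / 2  # A C G T
    rnd <- function(n) if (n == 0L) "" else
      paste(sample(DNA_BASES, n, replace = TRUE, prob = prob),
            collapse = "")
    tx <- paste0(rnd(utr5 - 3L), "TAA", cds, rnd(utr3))
    out <- seq_set(paste0(id, "_tx"), tx, "synthetic transcript",
                   alphabet = "DNA")
    attr(out, "cds_interval") <- c(utr5, utr5 + nchar(cds))
    out
  })
}

#' True origin of simulated reads
#'
#' Parses the `template|start|strand` truth fields that
#' [simulate_reads()] embeds in read ids.
#'
#' @param ids read id vector
#' @return data frame with `template`, `start`, `strand`
#' @export
read_truth <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  data.frame(template = vapply(parts, `[`, character(1), 2L),
             start = as.integer(vapply(parts, `[`, character(1), 3L)),
             strand = vapply(parts, `[`, character(1), 4L),
             stringsAsFactors = FALSE)
}

#' Default tissue panel truth table
#'
#' Six chicken-like tissues: three immune (spleen, thymus, bursa) with
#' high target-gene abundance and three non-immune (liver, brain, muscle)
#' with low-to-zero abundance, each with a 1e5-read library. Values are
#' chosen so the target gene is clearly enriched in immune organs while
#' per-tissue counts stay in the tens, as for a moderately expressed
#' adaptor gene at desk-scale library sizes.
#'
#' @return data frame with `tissue`, `library_size`, `true_rpkm`,
#'   `immune_flag`
#' @export
default_tissue_truth <- function() {
  data.frame(
    tissue = c("spleen", "thymus", "bursa", "liver", "brain", "muscle"),
    library_size = rep(100000L, 6L),
    true_rpkm = c(400, 300, 250, 40, 15, 0),
    immune_flag = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Expected recruited-read count under the RPKM identity
#'
#' `count = rpkm * (gene_length / 1000) * (library_size / 1e6)`.
#'
#' @param true_rpkm true RPKM
#' @param gene_length_nt gene length in nucleotides
#' @param library_size total reads in the library
#' @return expected read count
#' @export
expected_read_count <- function(true_rpkm, gene_length_nt, library_size) {
  true_rpkm * (gene_length_nt / 1000) * (library_size / 1e6)
}

#' Generate a tissue-stratified read panel with known truth
#'
#' For each tissue, the target gene contributes a Poisson-distributed
#' number of reads with mean given by [expected_read_count()]; the
#' remaining reads are drawn from the background genes with equal weights.
#' Reads carry their true origin in the id.
#'
#' @param genes DNA [seq_set()] containing the target and background genes
#' @param target_id id of the target gene within `genes`
#' @param truth truth table as in [default_tissue_truth()]
#' @param read_length read length
#' @param error_rate per-base substitution error rate
#' @param seed RNG seed
#' @return list with `tissues` (named list of [read_set()]) and `truth`
#'   (the input table plus the realized target read count per tissue)
#' @export
make_tissue_panel <- function(genes, target_id, truth = default_tissue_truth(),
                              read_length = 100L, error_rate = 0.01,
                              seed = 42L) {
  stopifnot(target_id %in% genes$id,
            all(c("tissue", "library_size", "true_rpkm", "immune_flag") %in%
                  names(truth)),
            all(truth$library_size >= 10000L), all(truth$true_rpkm >= 0),
            any(truth$immune_flag), any(!truth$immune_flag))
  target <- genes[genes$id == target_id, , drop = FALSE]
  background <- genes[genes$id != target_id, , drop = FALSE]
  if (nrow(background) == 0L) stop("no background genes")
  glen <- nchar(target$residues)
  with_seed(seed, {
    sub_seeds <- sample.int(2^30, 2L * nrow(truth))
    tissues <- vector("list", nrow(truth))
    names(tissues) <- truth$tissue
    realized <- integer(nrow(truth))
    for (i in seq_len(nrow(truth))) {
      lambda <- expected_read_count(truth$true_rpkm[i], glen,
                                    truth$library_size[i])
      n_target <- rpois(1L, lambda)
      n_target <- min(n_target, truth$library_size[i])
      realized[i] <- n_target
      tr <- simulate_reads(target, n_target, read_length, error_rate,
                           seed = sub_seeds[2L * i - 1L],
                           source = truth$tissue[i])
      br <- simulate_reads(background, truth$library_size[i] - n_target,
                           read_length, error_rate,
                           seed = sub_seeds[2L * i],
                           source = truth$tissue[i])
      all <- rbind(tr, br)
      # re-number ids so they stay unique within the tissue
      all$id <- sprintf("%s_%07d|%s", truth$tissue[i], seq_len(nrow(all)),
                        sub("^[^|]*\\|", "", all$id))
      class(all) <- c("read_set", "data.frame")
      tissues[[i]] <- all
      pipeline_log("make_tissue_panel",
                   "%s: %d reads (%d target-origin, lambda %.1f)",
                   truth$tissue[i], nrow(all), n_target, lambda)
    }
    truth$realized_target_reads <- realized
    list(tissues = tissues, truth = truth)
  })
}

#' Write a tissue panel to disk
#'
#' One FASTQ per tissue plus a truth TSV
#' (`tissue`, `library_size`, `true_rpkm`, `immune_flag`).
#'
#' @param panel result of [make_tissue_panel()]
#' @param dir output directory (created if missing)
#' @return named vector of FASTQ paths, invisibly
#' @export
write_tissue_panel <- function(panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(panel$tissues), function(t) {
    p <- file.path(dir, paste0(t, ".fastq"))
    write_fastq(panel$tissues[[t]], p)
    p
  }, character(1))
  write.table(panel$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
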