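test_that("two overlapping reads merge into one contig of the right length", {
  withr::with_seed(41, tmpl <- random_dna(150))
  r1 <- substr(tmpl, 1, 100)
  r2 <- substr(tmpl, 51, 150)   # 50 nt exact overlap
  contigs <- greedy_assemble(read_set(c("a", "b"), c(r1, r2)))
  expect_length(contigs, 1L)
  expect_equal(nchar(contigs[[1L]]$consensus), 100L + 100L - 50L)
  expect_identical(contigs[[1L]]$consensus, tmpl)
  expect_equal(contigs[[1L]]$n_reads, 2L)
  expect_equal(length(contigs[[1L]]$depth), 150L)
  expect_true(all(contigs[[1L]]$depth >= 1L))
  expect_equal(sum(contigs[[1L]]$depth == 2L), 50L)
})

test_that("reads below the overlap threshold stay separate", {
  withr::with_seed(42, tmpl <- random_dna(220))
  r1 <- substr(tmpl, 1, 100)
  r2 <- substr(tmpl, 81, 180)  # 20 nt overlap < 30
  contigs <- greedy_assemble(read_set(c("a", "b"), c(r1, r2)))
  expect_length(contigs, 2L)
})

test_that("merging works across orientations", {
  withr::with_seed(43, tmpl <- random_dna(160))
  r1 <- substr(tmpl, 1, 100)
  r2 <- as.character(revcomp(substr(tmpl, 61, 160)))
  contigs <- greedy_assemble(read_set(c("a", "b"), c(r1, r2)))
  expect_length(contigs, 1L)
  cons <- contigs[[1L]]$consensus
  expect_true(cons == tmpl || cons == as.character(revcomp(tmpl)))
})

test_that("error-free tiling coverage reconstructs the template exactly", {
  withr::with_seed(44, tmpl <- seq_set("t", random_dna(400, gc = 0.6)))
  reads <- simulate_reads(tmpl, 160, 80, error_rate = 0, seed = 45)  # 32x
  contigs <- greedy_assemble(reads)
  cons <- contigs[[1L]]$consensus
  target <- tmpl$residues
  # coverage gaps at the extreme template ends are possible; the contig
  # must be an exact substring of the template
  expect_gte(nchar(cons), 390L)
  expect_true(grepl(cons, target, fixed = TRUE) ||
                grepl(as.character(revcomp(cons)), target, fixed = TRUE))
})

test_that("quality-weighted consensus fixes read errors at depth", {
  withr::with_seed(46, tmpl <- seq_set("t", random_dna(400, gc = 0.6)))
  reads <- simulate_reads(tmpl, 200, 80, error_rate = 0.01, seed = 47)
  contigs <- greedy_assemble(reads)
  cons <- contigs[[1L]]$consensus
  al <- Biostrings::pairwiseAlignment(cons, tmpl$residues, type = "local")
  ident <- Biostrings::nmatch(al) / nchar(cons)
  expect_gte(ident, 0.999)
})

test_that("assembly is deterministic", {
  withr::with_seed(48, tmpl <- seq_set("t", random_dna(300)))
  reads <- simulate_reads(tmpl, 90, 70, error_rate = 0.01, seed = 49)
  c1 <- greedy_assemble(reads)
  c2 <- greedy_assemble(reads)
  expect_identical(lapply(c1, `[[`, "consensus"),
                   lapply(c2, `[[`, "consensus"))
})

test_that("iterative rescue reaches a fixed point with a full-length bait", {
  withr::with_seed(51, gene <- seq_set("g", random_dna(600, gc = 0.7)))
  reads <- simulate_reads(gene, 240, 100, error_rate = 0, seed = 52)
  res <- iterative_rescue(reads, gene$residues, max_rounds = 5)
  # full bait recruits everything in round 1; round 2 confirms the fixed point
  expect_equal(res$rounds$n_recruited[1L], res$rounds$n_recruited[2L])
  expect_lte(nrow(res$rounds), 2L)
})

test_that("recruited-read counts never decrease across rescue rounds", {
  for (s in 1:5) {
    withr::with_seed(60 + s, {
      gene <- seq_set("g", random_dna(600, gc = 0.7))
    })
    reads <- simulate_reads(gene, 240, 100, error_rate = 0, seed = 70 + s)
    bait <- substr(gene$residues, 201, 400)
    res <- iterative_rescue(reads, bait, max_rounds = 8)
    expect_true(all(diff(res$rounds$n_recruited) >= 0L))
  }
})

test_that("rescue errors when nothing is recruited in round one", {
  withr::with_seed(53, {
    gene <- seq_set("g", random_dna(500))
    unrelated <- seq_set("u", random_dna(500))
  })
  reads <- simulate_reads(gene, 50, 80, seed = 54)
  expect_error(iterative_rescue(reads, unrelated$residues),
               "bait too diverged or threshold too strict")
})

test_that("find_orfs translates minimal and strand-flipped ORFs", {
  orfs <- find_orfs("ATGAAATAA", min_aa = 2L)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$translation, "MK")
  expect_equal(orfs$strand, "+")
  expect_equal(c(orfs$start, orfs$end), c(0L, 9L))

  rc <- find_orfs(as.character(revcomp("ATGAAATAA")), min_aa = 2L)
  expect_equal(rc$translation, "MK")
  expect_equal(rc$strand, "-")
  expect_equal(c(rc$start, rc$end), c(0L, 9L))
})

test_that("the planted CDS is recovered as the candidate ORF", {
  params <- lat_scaffold_params(protein_length = 120L,
                                docking_tyrosine_positions = c(80L, 95L,
                                                               105L, 115L),
                                proline_region = c(30L, 70L),
                                pip_position = 72L)
  prot <- make_lat_like_protein(params, seed = 55)
  cds <- reverse_translate_gc_biased(prot, 0.7, seed = 56)
  tx <- make_transcript(cds, utr5 = 60, utr3 = 60, seed = 57)
  orfs <- find_orfs(tx$residues)
  expect_identical(orfs$translation[orfs$is_candidate], prot$residues)
  iv <- attr(tx, "cds_interval")
  expect_equal(c(orfs$start[1L], orfs$end[1L]), iv)
})
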