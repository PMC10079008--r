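test_that("LAT-like scaffold plants every motif at its stated position", {
  prot <- make_lat_like_protein(seed = 1)$residues
  expect_equal(nchar(prot), 230L)
  expect_equal(substr(prot, 1, 1), "M")
  expect_equal(substr(prot, 26, 26), "C")
  expect_equal(substr(prot, 29, 29), "C")
  expect_equal(substr(prot, 131, 131), "G")
  expect_equal(substr(prot, 132, 135), "YLVV")
  for (y in c(171L, 191L, 226L)) {
    expect_equal(substr(prot, y, y), "Y")
    expect_equal(substr(prot, y + 2L, y + 2L), "N")
  }
  expect_false(grepl("PIPRSP", prot, fixed = TRUE))

  d <- make_lat_like_protein(lat_scaffold_params(plc_context_residue = "D"),
                             seed = 1)$residues
  expect_equal(substr(d, 131, 131), "D")

  pip <- make_lat_like_protein(lat_scaffold_params(include_pip_motif = TRUE),
                               seed = 1)$residues
  expect_equal(substr(pip, 104, 109), "PIPRSP")
})

test_that("scaffolds from different seeds agree exactly at planted sites", {
  params <- lat_scaffold_params()
  a <- strsplit(make_lat_like_protein(params, seed = 1)$residues, "")[[1L]]
  b <- strsplit(make_lat_like_protein(params, seed = 2)$residues, "")[[1L]]
  planted <- scaffold_invariant_sites(params)
  expect_identical(a[planted], b[planted])
  expect_true(any(a[-planted] != b[-planted]))
  # determinism
  expect_identical(a, strsplit(make_lat_like_protein(params,
                                                     seed = 1)$residues,
                               "")[[1L]])
})

test_that("infeasible scaffold placements error", {
  expect_error(lat_scaffold_params(protein_length = 199L),
               "outside protein length")
  expect_error(lat_scaffold_params(dicysteine_position = 131L), "overlap")
})

test_that("GC-biased reverse translation is an exact inverse and monotone", {
  withr::with_seed(11, {
    for (i in 1:25) {
      p <- random_protein(sample(30:80, 1L))
      cds <- reverse_translate_gc_biased(p, runif(1, 0.35, 0.6), seed = i)
      expect_identical(translate_dna(cds$residues), paste0(p, "*"))
    }
  })
  # a composition spanning per-codon GC 0-3 (K/L low, G/A/P/R high)
  # makes both 0.50 and 0.75 reachable
  withr::with_seed(12, p <- random_protein(150, alphabet = c("G", "A", "P",
                                                             "R", "L", "K")))
  lo <- reverse_translate_gc_biased(p, 0.50, seed = 3)$residues
  hi <- reverse_translate_gc_biased(p, 0.75, seed = 3)$residues
  expect_gt(gc_fraction(hi), gc_fraction(lo))
  expect_lt(abs(gc_fraction(lo) - 0.50), 0.02)
  expect_lt(abs(gc_fraction(hi) - 0.75), 0.02)
})

test_that("unreachable GC targets report the achievable range", {
  # lysine codons are AAA/AAG: at most 1 GC of 3 per codon, so the
  # achievable maximum is exactly 1/3
  polyk <- strrep("K", 100L)
  expect_error(reverse_translate_gc_biased(polyk, 0.75, seed = 1),
               "achievable range \\[0\\.000, 0\\.333\\]")
})

test_that("ortholog evolution follows its closed-form change probability", {
  root <- random_protein(2000)
  # zero branch lengths: all leaves identical to root
  same <- evolve_orthologs(root, "(A:0,B:0);", seed = 1)
  expect_identical(same$residues, c(root, root))

  # single branch b = 0.2: change fraction ~ 1 - exp(-0.2) within 3 SE
  ev <- evolve_orthologs(root, "(A:0.2,B:0);", seed = 2)
  a <- strsplit(ev$residues[ev$id == "A"], "")[[1L]]
  r <- strsplit(root, "")[[1L]]
  p_hat <- mean(a != r)
  p_true <- 1 - exp(-0.2)
  se <- sqrt(p_true * (1 - p_true) / 2000)
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("invariant sites never change in any leaf", {
  params <- lat_scaffold_params()
  root <- make_lat_like_protein(params, seed = 3)
  inv <- scaffold_invariant_sites(params)
  ev <- evolve_orthologs(root, "((A:0.5,B:0.4):0.2,(C:0.6,D:0.3):0.1);",
                         invariant_sites = inv, seed = 4)
  rootch <- strsplit(root$residues, "")[[1L]]
  for (i in seq_len(nrow(ev)))
    expect_identical(strsplit(ev$residues[i], "")[[1L]][inv], rootch[inv])
})

test_that("simulated error-free reads are exact template substrings", {
  tmpl <- seq_set("g1", random_dna(500))
  reads <- simulate_reads(tmpl, 200, read_length = 80, error_rate = 0,
                          seed = 5)
  tr <- read_truth(reads$id)
  for (i in seq_len(50)) {
    frag <- substr(tmpl$residues, tr$start[i] + 1L, tr$start[i] + 80L)
    if (tr$strand[i] == "-") frag <- revcomp(frag)
    expect_identical(reads$residues[i], frag)
  }
})

test_that("read origins follow the weighted sampling model", {
  withr::with_seed(6, {
    t2 <- seq_set(c("big", "small"), c(random_dna(400), random_dna(400)))
  })
  reads <- simulate_reads(t2, 10000, read_length = 60, weights = c(9, 1),
                          seed = 7)
  n_big <- sum(read_truth(reads$id)$template == "big")
  sd3 <- 3 * sqrt(10000 * 0.9 * 0.1)
  expect_lt(abs(n_big - 9000), sd3)
})

test_that("read simulation is byte-identical under a fixed seed", {
  tmpl <- seq_set("g1", random_dna(300))
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(tmpl, 100, 50, error_rate = 0.02, seed = 8), f1)
  write_fastq(simulate_reads(tmpl, 100, 50, error_rate = 0.02, seed = 8), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the indel stress mode perturbs read lengths, off by default", {
  tmpl <- seq_set("g1", random_dna(400))
  plain <- simulate_reads(tmpl, 50, 80, seed = 17)
  expect_true(all(nchar(plain$residues) == 80L))
  bumpy <- simulate_reads(tmpl, 50, 80, indel_rate = 0.05, seed = 17)
  expect_true(any(nchar(bumpy$residues) != 80L))
  expect_identical(bumpy$residues,
                   simulate_reads(tmpl, 50, 80, indel_rate = 0.05,
                                  seed = 17)$residues)
  expect_identical(nchar(bumpy$qualities), nchar(bumpy$residues))
})

test_that("transcripts embed the CDS behind an in-frame stop", {
  cds <- reverse_translate_gc_biased(random_protein(60), 0.6, seed = 9)
  tx <- make_transcript(cds, utr5 = 50, utr3 = 30, seed = 10)
  iv <- attr(tx, "cds_interval")
  expect_equal(iv, c(50L, 50L + nchar(cds$residues)))
  expect_identical(substr(tx$residues, iv[1L] + 1L, iv[2L]), cds$residues)
  expect_identical(substr(tx$residues, 48, 50), "TAA")
})

test_that("tissue panels realize the RPKM identity", {
  # expected count arithmetic: rpkm 100, 500 nt gene, 1e6 reads -> 50
  expect_equal(expected_read_count(100, 500, 1e6), 50)
  expect_equal(expected_read_count(100, 500, 2e6), 100)  # linear in depth

  genes <- seq_set(c("target", "bg1", "bg2"),
                   c(random_dna(600, gc = 0.7), random_dna(700),
                     random_dna(800)))
  truth <- data.frame(tissue = c("spleen", "liver"),
                      library_size = c(20000L, 20000L),
                      true_rpkm = c(500, 0),
                      immune_flag = c(TRUE, FALSE))
  panel <- make_tissue_panel(genes, "target", truth, read_length = 80,
                             error_rate = 0, seed = 11)
  expect_named(panel$tissues, c("spleen", "liver"))
  expect_equal(nrow(panel$tissues$spleen), 20000L)
  origins <- read_truth(panel$tissues$liver$id)
  expect_equal(sum(origins$template == "target"), 0L)  # true RPKM 0
  lam <- expected_read_count(500, 600, 20000)
  expect_lt(abs(panel$truth$realized_target_reads[1L] - lam),
            4 * sqrt(lam))
})
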