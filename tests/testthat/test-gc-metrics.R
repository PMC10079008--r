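test_that("gc_fraction counts G+C over A/C/G/T only", {
  expect_equal(gc_fraction("AAAA"), 0)
  expect_equal(gc_fraction("GGCC"), 1)
  expect_equal(gc_fraction("GGGATCCCC"), 7 / 9)
  expect_equal(gc_fraction("GGNNAA"), 2 / 4)  # N excluded from both sides
  expect_error(gc_fraction("NNNN"), "undefined")
})

test_that("gc_stretches returns maximal qualifying runs", {
  # "CCCCGC" is one undisrupted run of 6: maximality merges adjacent G/C
  expect_equal(gc_stretches("GGGATCCCCGC"),
               cbind(start = c(0L, 5L), end = c(3L, 11L)))
  # a separated terminal run shorter than 3 is excluded
  expect_equal(gc_stretches("GGGATCCCCAGC"),
               cbind(start = c(0L, 5L), end = c(3L, 9L)))
  expect_equal(nrow(gc_stretches("ATATAT")), 0L)
  expect_equal(gc_stretches("GCGCGC", 3L), cbind(start = 0L, end = 6L))
  # N breaks a run
  expect_equal(gc_stretches("GGGNGGG"),
               cbind(start = c(0L, 4L), end = c(3L, 7L)))
  # min_len 1 reports every run
  expect_equal(nrow(gc_stretches("GAGAGA", 1L)), 3L)
})

test_that("stretch_summary aggregates count and mean correctly", {
  s <- stretch_summary("GGGATCCCCGC")
  expect_equal(s$stretch_count, 2L)
  expect_equal(s$mean_stretch_length, (3 + 6) / 2)
  expect_equal(s$gc_fraction, 9 / 11)

  s2 <- stretch_summary("GGGATCCCCAGC")
  expect_equal(s2$stretch_count, 2L)
  expect_equal(s2$mean_stretch_length, (3 + 4) / 2)

  empty <- stretch_summary("ATATAT")
  expect_equal(empty$stretch_count, 0L)
  expect_equal(empty$mean_stretch_length, 0)
})

test_that("higher GC targets yield longer G/C stretches on the same protein", {
  # per-codon GC spans 0-3 for this composition: 0.50 and 0.75 reachable
  withr::with_seed(21, p <- random_protein(150, alphabet = c("G", "A", "P",
                                                             "R", "L", "K")))
  lo <- reverse_translate_gc_biased(p, 0.50, seed = 1)$residues
  hi <- reverse_translate_gc_biased(p, 0.75, seed = 1)$residues
  expect_gt(stretch_summary(hi)$mean_stretch_length,
            stretch_summary(lo)$mean_stretch_length)
})

test_that("gc_stretches matches the run-enumeration oracle", {
  withr::with_seed(22, {
    for (i in 1:200) {
      s <- random_dna(sample(10:120, 1L), gc = runif(1, 0.2, 0.8))
      for (ml in c(1L, 3L, 5L)) {
        got <- gc_stretches(s, ml)
        want <- oracle_stretches(s, ml)
        expect_equal(unname(got), unname(want))
      }
    }
  })
})

test_that("stretch structure behaves under concatenation", {
  withr::with_seed(23, {
    for (i in 1:50) {
      a <- random_dna(40); b <- random_dna(40)
      # a non-G/C separator never merges stretches: the joined set is the
      # union of the two sides' stretches, with b's shifted by |a| + 1
      joined <- gc_stretches(paste0(a, "T", b))
      sa <- gc_stretches(a)
      sb <- gc_stretches(b)
      want <- rbind(sa, sb + nchar(a) + 1L)
      expect_equal(unname(joined), unname(want))
      # inserting "G" between G/C-ending and G/C-starting parts can only
      # merge the two adjacent runs, never any others
      g_joined <- gc_stretches(paste0(a, "G", b))
      expect_gte(nrow(g_joined), nrow(sa) + nrow(sb) - 1L)
      # total stretch length never exceeds the G+C count
      expect_lte(sum(joined[, 2L] - joined[, 1L]),
                 nchar(gsub("[^GC]", "", paste0(a, "T", b))))
    }
  })
})

test_that("gene_set_profile filters, bins and ranks", {
  withr::with_seed(24, {
    cds <- seq_set(paste0("g", 1:6),
                   c(random_dna(400), random_dna(350), random_dna(200),
                     random_dna(500, gc = 0.8), random_dna(320),
                     random_dna(299)))
  })
  prof <- gene_set_profile(cds)
  expect_equal(nrow(prof$table), 4L)   # 200 nt and 299 nt filtered
  expect_equal(prof$n_filtered, 2L)
  expect_equal(sum(prof$histogram$count), nrow(prof$table))

  # the GC-rich gene outranks every background gene
  prof2 <- gene_set_profile(cds, query = "g4")
  expect_equal(prof2$query_percentile, 100)

  short <- seq_set("s", random_dna(100))
  expect_error(gene_set_profile(short), "no CDS left")
})

test_that("histogram counts are conserved on larger random sets", {
  withr::with_seed(25, {
    cds <- seq_set(paste0("g", 1:300),
                   replicate(300, random_dna(sample(300:900, 1L),
                                             gc = runif(1, 0.3, 0.8))))
  })
  prof <- gene_set_profile(cds)
  expect_equal(sum(prof$histogram$count), nrow(prof$table))
  expect_true(all(prof$table$length_nt >= 300L))
})
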