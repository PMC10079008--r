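test_that("rpkm follows its defining identity", {
  expect_equal(rpkm(50, 500, 1e6), 100)
  expect_equal(rpkm(0, 500, 1e6), 0)
  # scale invariance: count and library multiplied by 10
  expect_equal(rpkm(500, 500, 1e7), rpkm(50, 500, 1e6))
  expect_error(rpkm(1, 0, 1e6))
})

test_that("per-tissue counting is independent, linear and zero-safe", {
  withr::with_seed(91, {
    gene <- seq_set("g", random_dna(600, gc = 0.7))
    bg <- seq_set("b", random_dna(600, gc = 0.5))
  })
  t1 <- simulate_reads(gene, 60, 100, error_rate = 0.01, seed = 92,
                       source = "spleen")
  t2 <- simulate_reads(bg, 200, 100, error_rate = 0.01, seed = 93,
                       source = "liver")
  counts <- count_recruited(list(spleen = t1, liver = t2), gene)
  expect_equal(counts$count[counts$tissue == "liver"], 0L)
  expect_equal(counts$library_size, c(60L, 200L))

  # duplicating every read doubles both count and library size
  dup <- t1
  dup$id <- paste0(dup$id, "_dup")
  both <- rbind(t1, dup)
  class(both) <- class(t1)
  c2 <- count_recruited(list(spleen = both), gene)
  expect_equal(c2$count, 2L * counts$count[counts$tissue == "spleen"])
  expect_equal(c2$library_size, 120L)

  # processing order does not matter
  rev_counts <- count_recruited(list(liver = t2, spleen = t1), gene)
  expect_equal(rev_counts[order(rev_counts$tissue), -1L],
               counts[order(counts$tissue), -1L],
               ignore_attr = TRUE)

  empty <- read_set(character(0), character(0))
  expect_warning(c0 <- count_recruited(list(none = empty), gene),
                 "empty read set")
  expect_equal(c0$count, 0L)
})

test_that("enrichment report implements the median-ratio rule", {
  rec <- data.frame(tissue = c("spleen", "thymus", "liver", "brain",
                               "muscle"),
                    rpkm = c(100, 80, 5, 3, 1))
  flags <- c(spleen = TRUE, thymus = TRUE, liver = FALSE, brain = FALSE,
             muscle = FALSE)
  er <- enrichment_report(rec, flags)
  expect_equal(er$immune_median, 90)
  expect_equal(er$non_immune_median, 3)
  expect_equal(er$ratio, 30)
  expect_true(er$enriched)
  expect_equal(er$records$tissue[1L], "spleen")  # sorted by rpkm

  # all-equal profile is not enriched (no value exceeds the median)
  eq <- data.frame(tissue = rec$tissue, rpkm = rep(7, 5))
  expect_false(enrichment_report(eq, flags)$enriched)

  # zero non-immune median: ratio undefined but flag still computable
  z <- data.frame(tissue = rec$tissue, rpkm = c(10, 8, 0, 0, 0))
  erz <- enrichment_report(z, flags)
  expect_false(erz$ratio_defined)
  expect_true(is.na(erz$ratio))
  expect_true(erz$enriched)

  expect_error(enrichment_report(rec, flags[-1L]), "missing for tissue")
  expect_error(enrichment_report(rec[1:2, ], flags),
               "at least one immune and one non-immune")
})

test_that("estimated RPKM is unbiased over repeated panels", {
  # scaled-down from the full panel (library 2e4, 10 panels) to keep the
  # suite fast; the acceptance suite runs the full 6-tissue 1e5 panel
  withr::with_seed(94, {
    genes <- seq_set(c("target", "bg1", "bg2"),
                     c(random_dna(600, gc = 0.72), random_dna(650),
                       random_dna(700)))
  })
  truth <- data.frame(tissue = c("spleen", "liver"),
                      library_size = c(20000L, 20000L),
                      true_rpkm = c(2000, 250),
                      immune_flag = c(TRUE, FALSE))
  ests <- matrix(NA_real_, nrow = 10L, ncol = 2L)
  for (s in 1:10) {
    panel <- make_tissue_panel(genes, "target", truth, read_length = 100,
                               error_rate = 0.01, seed = 200 + s)
    q <- quantify_expression(panel$tissues,
                             genes[genes$id == "target", ],
                             setNames(truth$immune_flag, truth$tissue))
    ests[s, ] <- q$table$rpkm[match(truth$tissue, q$table$tissue)]
  }
  denom <- (600 / 1000) * (20000 / 1e6)
  for (k in 1:2) {
    lam <- truth$true_rpkm[k] * denom
    se_mean <- sqrt(lam) / denom / sqrt(10)
    expect_lt(abs(mean(ests[, k]) - truth$true_rpkm[k]), 3 * se_mean)
  }
})

test_that("estimated rank order matches truth at 2-fold spacing", {
  withr::with_seed(95, {
    genes <- seq_set(c("target", "bg1"),
                     c(random_dna(693, gc = 0.7), random_dna(700)))
  })
  truth <- data.frame(
    tissue = c("t1", "t2", "t3", "t4", "t5", "t6"),
    library_size = rep(20000L, 6L),
    true_rpkm = c(51200, 25600, 12800, 6400, 3200, 1600),
    immune_flag = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  panel <- make_tissue_panel(genes, "target", truth, read_length = 100,
                             error_rate = 0.01, seed = 96)
  q <- quantify_expression(panel$tissues, genes[genes$id == "target", ],
                           setNames(truth$immune_flag, truth$tissue))
  est <- q$table$rpkm[match(truth$tissue, q$table$tissue)]
  expect_equal(order(-est), order(-truth$true_rpkm))
})
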