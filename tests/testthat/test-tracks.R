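# Signal binning, LAD/inter-LAD assignment rules, sum normalisation with
# pseudocount, and fold-change summaries.

test_that("bin_signal distributes weight by overlap and conserves totals", {
  # one read fully inside one bin
  t1 <- bin_signal(tibble::tibble(start = 1500, end = 1800, weight = 2),
                   bin_size = 1000, n_bins = 4)
  expect_equal(t1$value, c(0, 2, 0, 0))

  # read spanning two bins 60/40
  t2 <- bin_signal(tibble::tibble(start = 400, end = 1400, weight = 1),
                   bin_size = 1000, n_bins = 2)
  expect_equal(t2$value, c(0.6, 0.4))

  # empty input -> all-zero track
  t3 <- bin_signal(tibble::tibble(start = numeric(0), end = numeric(0)),
                   bin_size = 1000, n_bins = 3)
  expect_equal(t3$value, c(0, 0, 0))

  # totals conserved after clipping
  set.seed(40)
  iv <- tibble::tibble(start = sample(0:9000, 20),
                       end = pmin(10000, sample(0:9000, 20) + 500),
                       weight = runif(20))
  iv <- dplyr::filter(iv, end > start)
  tt <- suppressWarnings(bin_signal(iv, 1000, 10))
  expect_equal(sum(tt$value), sum(iv$weight), tolerance = 1e-9)
})

test_that("gene TSS assignment follows the in-LAD / 1-kb-distant rules", {
  lads <- tibble::tibble(start = 10000, end = 20000)
  genes <- tibble::tibble(
    start = c(14000, 20500, 30000, 9990),
    end = c(16000, 21500, 32000, 9999),
    strand = c("+", "+", "+", "+"))
  out <- assign_lad_class(genes, lads, kind = "gene")
  expect_equal(out$lad_class,
               c("LAD",          # TSS at LAD midpoint
                 "unassigned",   # 500 bp outside
                 "interLAD",     # 10 kb away
                 "unassigned"))  # 10 bp outside
  # strand-aware 5' end: minus-strand gene, TSS = end - 1, 800 bp past
  # the LAD edge -> inside neither class
  g2 <- tibble::tibble(start = 15000, end = 20800, strand = "-")
  expect_equal(assign_lad_class(g2, lads, "gene")$lad_class, "unassigned")
  g3 <- tibble::tibble(start = 5000, end = 15000, strand = "-")
  expect_equal(assign_lad_class(g3, lads, "gene")$lad_class, "LAD")
  # missing strand is rejected
  expect_error(assign_lad_class(tibble::tibble(start = 1, end = 2), lads,
                                "gene"), "strand")
})

test_that("region assignment uses any-overlap and the same distance rule", {
  lads <- tibble::tibble(start = 10000, end = 20000)
  regs <- tibble::tibble(start = c(19990, 20100, 25000),
                         end = c(20500, 20600, 26000))
  out <- assign_lad_class(regs, lads, kind = "region")
  expect_equal(out$lad_class, c("LAD", "unassigned", "interLAD"))
})

test_that("normalisation, zero-row filter and pseudocount behave as stated", {
  v <- tibble::tibble(feature_id = c("a", "b", "c", "z"),
                      k1 = c(10, 100, 20, 0), k2 = c(12, 110, 18, 0),
                      c1 = c(11, 95, 21, 0), c2 = c(9, 105, 19, 0))
  out <- normalize_and_log2fc(v, c("k1", "k2"), c("c1", "c2"))
  expect_false("z" %in% out$feature_id)     # all-zero feature dropped
  expect_gt(attr(out, "pseudocount"), 0)
  expect_true(all(is.finite(out$log2fc)))

  # identical tables give exactly zero
  v2 <- tibble::tibble(feature_id = c("a", "b"), k1 = c(5, 50), k2 = c(6, 60),
                       c1 = c(5, 50), c2 = c(6, 60))
  expect_equal(normalize_and_log2fc(v2, c("k1", "k2"), c("c1", "c2"))$log2fc,
               c(0, 0))

  # a feature doubled in both KD replicates, against a large stable
  # background: log2FC approaches 1. A tiny feature pins the pseudocount
  # (the minimal positive normalised value) far below the signal range.
  n <- 50
  base <- tibble::tibble(
    feature_id = c("hit", "tiny", sprintf("bg%02d", 1:n)),
    k1 = c(2000, 1, rep(1000, n)), k2 = c(2000, 1, rep(1000, n)),
    c1 = c(1000, 1, rep(1000, n)), c2 = c(1000, 1, rep(1000, n)))
  out3 <- normalize_and_log2fc(base, c("k1", "k2"), c("c1", "c2"))
  # normalisation by totals shifts everything by the same constant;
  # difference to background log2FC isolates the doubling
  hit <- out3$log2fc[out3$feature_id == "hit"]
  bg <- median(out3$log2fc[grepl("^bg", out3$feature_id)])
  expect_equal(hit - bg, 1, tolerance = 0.01)

  expect_error(normalize_and_log2fc(
    tibble::tibble(feature_id = "a", k1 = 0, k2 = 1, c1 = 1, c2 = 1),
    c("k1", "k2"), c("c1", "c2")), "zero total")
})

test_that("LAD vs inter-LAD summaries recover a planted shift", {
  set.seed(41)
  d <- tibble::tibble(
    lad_class = rep(c("LAD", "interLAD"), each = 200),
    log2fc = c(rnorm(200, 0.5, 0.2), rnorm(200, 0, 0.2)))
  res <- lad_vs_interlad_change(d)
  expect_equal(res$by_class$median[res$by_class$lad_class == "LAD"], 0.5,
               tolerance = 0.05)
  expect_equal(res$by_class$median[res$by_class$lad_class == "interLAD"], 0,
               tolerance = 0.05)
  expect_lt(res$p_between, 1e-6)

  # all features in LADs: inter-LAD class empty, flagged
  d2 <- tibble::tibble(lad_class = rep("LAD", 10), log2fc = rnorm(10))
  res2 <- lad_vs_interlad_change(d2)
  expect_equal(res2$by_class$n[res2$by_class$lad_class == "interLAD"], 0)
  expect_true(is.na(res2$p_between))
})
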