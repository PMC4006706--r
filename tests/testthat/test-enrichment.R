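test_that("TSS classes partition distance and match a linear-scan oracle", {
  g <- genome("chr1", 10e6)
  tss <- data.frame(chrom = "chr1", pos = c(1e6, 4e6, 9e6))
  # midpoint exactly at a TSS
  at <- data.frame(chrom = "chr1", start = 1e6 - 500, end = 1e6 + 500)
  expect_equal(assign_tss_class(at, tss), "[0,1kb)")
  # 500 kb from the nearest TSS
  far <- data.frame(chrom = "chr1", start = 4.5e6 - 100, end = 4.5e6 + 100)
  expect_equal(assign_tss_class(far, tss), "[100kb,1Mb)")
  # no TSS on the chromosome: farthest class
  g2 <- genome(c("chr1", "chr2"), c(10e6, 10e6))
  none <- data.frame(chrom = "chr2", start = 0, end = 200)
  expect_equal(assign_tss_class(none, tss), ">=1Mb")
  # random features vs brute-force nearest-TSS scan
  set.seed(80)
  f <- random_intervals(200, 10e6, max_len = 10e3)
  mine <- assign_tss_class(f, tss)
  labs <- c("[0,1kb)", "[1kb,10kb)", "[10kb,100kb)", "[100kb,1Mb)", ">=1Mb")
  oracle <- vapply(seq_len(200), function(i) {
    d <- min(abs((f$start[i] + f$end[i]) / 2 - tss$pos))
    labs[findInterval(d, c(0, 1e3, 1e4, 1e5, 1e6))]
  }, "")
  expect_equal(mine, oracle)
})

test_that("shuffling conserves per-stratum counts and lengths exactly", {
  set.seed(81)
  g <- genome(c("chr1", "chr2"), c(20e6, 20e6))
  tss <- data.frame(chrom = rep(c("chr1", "chr2"), each = 15),
                    pos = c(sort(runif(15, 0, 20e6)),
                            sort(runif(15, 0, 20e6))))
  f <- rbind(random_intervals(60, 20e6, "chr1", max_len = 20e3),
             random_intervals(60, 20e6, "chr2", max_len = 20e3))
  cls0 <- assign_tss_class(f, tss)
  sh <- shuffle_features(f, g, tss, n_shuffles = 25, seed = 123)
  for (s in sh) {
    expect_equal(s$end - s$start, f$end - f$start)
    expect_equal(s$chrom, f$chrom)
    cls1 <- assign_tss_class(s, tss)
    expect_equal(table(paste(s$chrom, cls1)),
                 table(paste(f$chrom, cls0)))
  }
  # byte-identical stream under the same seed
  sh2 <- shuffle_features(f, g, tss, n_shuffles = 25, seed = 123)
  expect_identical(sh, sh2)
  expect_error(shuffle_features(f, g, tss, 5), "seed")
})

test_that("single-class placement is uniform over the chromosome", {
  g <- genome("chr1", 10e6)
  tss <- data.frame(chrom = character(), pos = numeric())
  f <- data.frame(chrom = "chr1", start = 0, end = 2000)
  sh <- shuffle_features(f, g, tss, n_shuffles = 10000, seed = 9)
  mids <- vapply(sh, function(s) (s$start + s$end) / 2, 0)
  expect_lt(abs(mean(mids) - 5e6) / 10e6, 0.01)
})

test_that("published overlap tallies reproduce the printed enrichment ratios", {
  marks <- histone_mark_overlaps()
  expect_equal(nrow(marks), 10)
  expect_equal(round_percent(100 * marks$observed / marks$expected) / 100,
               marks$enrichment)
  genes <- feature_overlap_summary()
  grow <- genes[genes$feature == "genes", ]
  expect_equal(round_percent(100 * grow$observed / grow$expected) / 100,
               0.63)
  expect_equal(grow$observed, 386)
  expect_equal(grow$expected, 617)
})

test_that("enrichment test is calibrated on a constructed neutral case", {
  g <- genome("chr1", 30e6)
  tss <- data.frame(chrom = character(), pos = numeric())
  set.seed(82)
  st <- seq(2e6, 26e6, by = 3e6)
  doms <- data.frame(chrom = "chr1", start = st, end = st + 1e6)
  f <- random_intervals(400, 30e6, max_len = 2000)
  res <- enrichment_test(f, doms, g, tss, n_shuffles = 200, seed = 83)
  # features were placed uniformly, the null is uniform: enrichment ~ 1
  expect_lt(abs(res$enrichment - 1), 0.15)
  expect_gt(res$p_value, 0.01)
  expect_true(res$direction %in% c("enriched", "depleted"))
})

test_that("the analytic expected-overlap formula matches simulation", {
  g <- genome("chr1", 30e6)
  tss <- data.frame(chrom = character(), pos = numeric())
  st <- seq(2e6, 26e6, by = 3e6)
  doms <- data.frame(chrom = "chr1", start = st, end = st + 1e6)
  m <- nrow(doms)
  f_frac <- sum(doms$end - doms$start) / 30e6
  len <- 20e3
  n <- 500
  f <- data.frame(chrom = "chr1", start = rep(0, n), end = rep(len, n))
  sh <- shuffle_features(f, g, tss, n_shuffles = 120, seed = 84)
  counts <- vapply(sh, function(s) {
    sum(overlaps_any(s, doms))
  }, 0)
  expected_analytic <- n * min(1, f_frac + len * m / 30e6)
  mc_se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected_analytic), 3 * mc_se + 1e-9)
})

test_that("gene deserts are exactly the zero-annotation tiles", {
  g <- genome("chr1", 40e6)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric())
  expect_equal(nrow(find_gene_deserts(empty, g)), 40)
  # one gene per tile: no deserts
  dense <- data.frame(chrom = "chr1", start = (0:39) * 1e6 + 5e5,
                      end = (0:39) * 1e6 + 5.1e5)
  expect_equal(nrow(find_gene_deserts(dense, g)), 0)
  # 30 constructed desert tiles recovered exactly
  set.seed(85)
  desert_idx <- sort(sample(0:39, 30))
  gene_tiles <- setdiff(0:39, desert_idx)
  genes <- data.frame(chrom = "chr1", start = gene_tiles * 1e6 + 2e5,
                      end = gene_tiles * 1e6 + 2.6e5)
  des <- find_gene_deserts(genes, g)
  expect_equal(nrow(des), 30)
  expect_equal(des$start, desert_idx * 1e6)
})

test_that("constructed mark densities are recovered as enrichment ratios", {
  # generator placing peaks at a 1.45x in:out density ratio yields ~1.45x
  cfg <- sim_config(host_gene_mult = 1, n_desert_tiles = 0,
                    n_domains = 5, size_meanlog = log(6e5),
                    marks = list(rep_mark = list(class = "repressive",
                                                 ratio = 1.45,
                                                 n_peaks = 4000,
                                                 peak_len = 1000)))
  truth <- simulate_reference(cfg, seed = 86)
  me <- simulate_marks_and_expression(truth, seed = 87)
  g <- truth$genome
  res <- enrichment_test(as.data.frame(me$marks$rep_mark),
                         truth$ur_domains, g, truth$tss,
                         n_shuffles = 150, seed = 88,
                         feature_name = "rep_mark")
  expect_lt(abs(res$enrichment - 1.45), 0.1)
  expect_equal(res$direction, "enriched")
  expect_lt(res$p_value, 0.001)
})
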