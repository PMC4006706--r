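test_that("window means match a brute-force oracle and drop sparse windows", {
  v <- rep(2.5, 400)
  tr <- toy_track(v, kind = "fold-enrichment")
  w <- window_signal(tr, 1e6)  # 200 bins per window
  expect_equal(nrow(w), 2)
  expect_true(all(w$mean == 2.5))
  # arithmetic mean of an arbitrary window
  set.seed(90)
  v2 <- rnorm(400)
  tr2 <- toy_track(v2, kind = "fold-enrichment")
  w2 <- window_signal(tr2, 1e6)
  expect_equal(w2$mean, c(mean(v2[1:200]), mean(v2[201:400])),
               tolerance = 1e-12)
  # a window with < 50% usable bins is dropped
  m <- rep(TRUE, 400); m[1:150] <- FALSE
  tr3 <- toy_track(v2, kind = "fold-enrichment", mask = m)
  w3 <- window_signal(tr3, 1e6)
  expect_equal(nrow(w3), 1)
  expect_equal(w3$start, 1e6)
  expect_error(window_signal(tr2, 1234), "multiple")
})

test_that("windowed correlations hit the exact extremes", {
  set.seed(91)
  v <- rnorm(4000)
  a <- toy_track(v, kind = "normalized-log2-ratio")
  b <- toy_track(v, kind = "fold-enrichment")
  nb <- toy_track(-v, kind = "fold-enrichment")
  expect_equal(correlation_profile(a, b)$r, 1)
  expect_equal(correlation_profile(a, nb)$r, -1)
  short <- toy_track(rnorm(400), kind = "fold-enrichment")
  expect_error(correlation_profile(toy_track(rnorm(400)), short, 1e6),
               "windows")
})

test_that("representation anticorrelates with a domain-elevated repressive signal", {
  truth <- simulate_reference(sim_config(), seed = 92)
  d <- simulate_depth(truth, seed = 93)
  rep_tr <- log2_ratio_track(d$test, d$control)
  # repressive-signal track: elevated fold enrichment inside truth domains
  g <- truth$genome
  set.seed(94)
  vals <- lapply(g$chrom$chrom, function(ch) {
    n <- length(rep_tr$values[[ch]])
    v <- rnorm(n, 1, 0.3)
    dd <- truth$ur_domains[truth$ur_domains$chrom == ch, ]
    for (i in seq_len(nrow(dd))) {
      from <- floor(dd$start[i] / 5000) + 1; to <- ceiling(dd$end[i] / 5000)
      v[from:to] <- v[from:to] + 2
    }
    v
  })
  names(vals) <- g$chrom$chrom
  sig <- binned_track(g, 5000, values = vals, kind = "fold-enrichment")
  cp <- correlation_profile(rep_tr, sig, window = 1e6)
  expect_lt(cp$r, -0.3)
  expect_lt(cp$p_value, 1e-3)
})

test_that("segmentation is exact on steps and idempotent on its reconstruction", {
  # exact step: one breakpoint at bin 200
  v <- c(rep(1, 200), rep(-1, 200))
  seg <- segment_timing(toy_track(v, kind = "timing"))
  expect_equal(nrow(seg), 2)
  expect_equal(seg$end[1], 200 * 5000)
  expect_equal(seg$state, c("early", "late"))
  # constant track: single segment
  seg1 <- segment_timing(toy_track(rep(0.7, 300), kind = "timing"))
  expect_equal(nrow(seg1), 1)
  # idempotence: segmenting the piecewise-constant reconstruction
  recon <- rep(seg$mean_timing, times = seg$n_bins)
  seg2 <- segment_timing(toy_track(recon, kind = "timing"))
  expect_equal(seg2$end, seg$end)
  expect_equal(seg2$state, seg$state)
})

test_that("noisy two-state breakpoints land within three bins over 20 trials", {
  for (s in 1:20) {
    set.seed(900 + s)
    br <- sample(100:300, 1)
    v <- c(rnorm(br, 1, 0.3), rnorm(400 - br, -1, 0.3))
    seg <- segment_timing(toy_track(v, kind = "timing"))
    late_starts <- seg$start[seg$state == "late"] / 5000
    expect_equal(nrow(seg), 2)
    expect_lte(abs(late_starts[1] - br), 3)
  }
})

test_that("segments tile each chromosome without overlap", {
  truth <- simulate_reference(sim_config(), seed = 95)
  tt <- simulate_timing_track(truth, seed = 96)
  seg <- segment_timing(tt)
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    expect_equal(s$start[1], 0)
    expect_equal(s$end[nrow(s)], 60e6)
    if (nrow(s) > 1) expect_equal(s$start[-1], s$end[-nrow(s)])
    # alternating states after same-state merging
    if (nrow(s) > 1) expect_true(all(s$state[-1] != s$state[-nrow(s)]))
  }
})

test_that("late-region containment separates hosting from non-hosting blocks", {
  # strict containment and boundary-crossing domains
  seg <- data.frame(chrom = "chr1", start = c(0, 2e6, 5e6),
                    end = c(2e6, 5e6, 8e6),
                    n_bins = c(400, 600, 600),
                    state = c("early", "late", "early"),
                    mean_timing = c(1, -1, 1))
  class(seg) <- c("timing_segments", "data.frame")
  inside <- data.frame(chrom = "chr1", start = 3e6, end = 4e6)
  crossing <- data.frame(chrom = "chr1", start = 4.5e6, end = 5.5e6)
  genes <- data.frame(chrom = "chr1", start = c(1e6, 6e6),
                      end = c(1.1e6, 6.1e6))
  rep1 <- late_region_analysis(inside, seg, genes)
  expect_equal(rep1$containment_fraction, 1)
  expect_true(rep1$domains$strict)
  rep2 <- late_region_analysis(crossing, seg, genes, tolerance_bp = 5000)
  expect_equal(rep2$containment_fraction, 0)
  # synthetic truth: all domains inside large gene-poor late blocks
  truth <- simulate_reference(sim_config(n_nonhost_late = 30), seed = 97)
  tt <- simulate_timing_track(truth, seed = 98)
  segs <- segment_timing(tt)
  rep3 <- late_region_analysis(truth$ur_domains, segs,
                               as.data.frame(truth$genes),
                               tolerance_bp = 5000)
  expect_equal(rep3$containment_fraction, 1)
  expect_lt(rep3$comparisons$size$p_value, 0.01)
  expect_lt(rep3$comparisons$n_genes$p_value, 0.01)
  expect_lt(rep3$comparisons$size$median_b,
            rep3$comparisons$size$median_a)
  expect_lt(rep3$comparisons$n_genes$median_a,
            rep3$comparisons$n_genes$median_b)
})

test_that("expression joins genes to representation and domain membership", {
  v <- rep(0, 400); v[101:200] <- -1
  tr <- toy_track(v - median(v))
  doms <- data.frame(chrom = "chr1", start = 100 * 5000, end = 200 * 5000)
  genes <- data.frame(chrom = "chr1",
                      start = c(50, 120, 300) * 5000,
                      end = c(51, 121, 301) * 5000,
                      gene_id = c("g1", "g2", "g3"))
  # gene tiling exactly one bin reports that bin's value
  expr_eq <- data.frame(gene_id = c("g1", "g2", "g3"),
                        expression = c(5, 5, 5))
  je <- expression_by_domain(expr_eq, genes, tr, doms)
  expect_equal(je$table$nlog2[je$table$gene_id == "g2"],
               tr$values$chr1[121])
  expect_equal(je$table$in_domain, c(FALSE, TRUE, FALSE))
  # all-equal expression: medians equal
  expect_equal(je$median_in, je$median_out)
  # unjoined genes are excluded with a message
  expr_missing <- expr_eq[1:2, ]
  expect_message(jm <- expression_by_domain(expr_missing, genes, tr, doms),
                 "1 genes")
  expect_equal(nrow(jm$table), 2)
})

test_that("silenced in-domain expression is detected as a rank shift", {
  truth <- simulate_reference(sim_config(host_gene_mult = 0.3), seed = 99)
  me <- simulate_marks_and_expression(truth, seed = 100)
  d <- simulate_depth(truth, seed = 101)
  tr <- log2_ratio_track(d$test, d$control)
  genes <- as.data.frame(truth$genes)
  res <- expression_by_domain(me$expression[c("gene_id", "expression")],
                              genes, tr, truth$ur_domains)
  expect_lt(res$median_in, res$median_out)
  expect_lt(res$p_value, 0.01)
})
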