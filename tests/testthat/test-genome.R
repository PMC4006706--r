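test_that("genome construction enforces its invariants", {
  g <- genome(c("chr1", "chr2"), c(1e6, 2e6), name = "toy")
  expect_equal(unname(chrom_lengths(g)), c(1e6, 2e6))
  expect_equal(genome_size(g), 3e6)
  expect_error(genome(c("chr1", "chr1"), c(1, 2)), "unique")
  expect_error(genome("chr1", 0), "positive")
})

test_that("sort_and_merge handles empty, abutting and gapped inputs", {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric())
  expect_equal(nrow(sort_and_merge(empty)), 0)
  ab <- data.frame(chrom = "chr1", start = c(0, 10), end = c(10, 20))
  m <- sort_and_merge(ab, gap = 0)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 20))
  # a 5 bp gap bridged only when gap >= 5
  gp <- data.frame(chrom = "chr1", start = c(0, 15), end = c(10, 20))
  expect_equal(nrow(sort_and_merge(gp, gap = 4)), 2)
  expect_equal(nrow(sort_and_merge(gp, gap = 5)), 1)
  expect_error(
    sort_and_merge(data.frame(chrom = "chrX", start = 0, end = 10),
                   genome = genome("chr1", 100)), "unknown chromosome")
})

test_that("interval arithmetic agrees with a per-base mask oracle", {
  set.seed(42)
  L <- 10e3
  for (rep in 1:20) {
    x <- random_intervals(50, L)
    y <- random_intervals(50, L)
    mx <- base_mask(x, L); my <- base_mask(y, L)
    # union via merge
    m <- sort_and_merge(x)
    expect_equal(sum(m$end - m$start), sum(mx))
    # intersection
    it <- intersect_intervals(x, y)
    expect_equal(sum(it$end - it$start), sum(mx & my))
    # subtraction
    sb <- subtract_intervals(x, y)
    expect_equal(sum(sb$end - sb$start), sum(mx & !my))
    # per-query overlap totals
    q <- random_intervals(10, L)
    ov <- interval_overlap_bp(q, y)
    ov_oracle <- vapply(seq_len(10), function(i)
      sum(base_mask(q[i, ], L) & my), 0)
    expect_equal(ov, ov_oracle)
  }
})

test_that("merged intervals match the GenomicRanges reduction", {
  skip_if_not_installed("GenomicRanges")
  set.seed(7)
  x <- random_intervals(100, 50e3)
  for (gap in c(0, 25)) {
    mine <- sort_and_merge(x, gap = gap)
    gr <- GenomicRanges::reduce(
      GenomicRanges::GRanges(x$chrom,
                             IRanges::IRanges(x$start + 1, x$end)),
      min.gapwidth = gap + 1)
    expect_equal(mine$start, GenomicRanges::start(gr) - 1)
    expect_equal(mine$end, GenomicRanges::end(gr))
  }
})

test_that("overlap_length is symmetric and chromosome-aware", {
  a <- data.frame(chrom = "chr1", start = 0, end = 100)
  b <- data.frame(chrom = "chr1", start = 50, end = 150)
  expect_equal(overlap_length(a, b), 50)
  expect_equal(overlap_length(b, a), 50)
  expect_equal(overlap_length(a, data.frame(chrom = "chr2", start = 0,
                                            end = 100)), 0)
  expect_equal(overlap_length(a, data.frame(chrom = "chr1", start = 100,
                                            end = 200)), 0)
})

test_that("interval files round-trip and malformed input is caught", {
  g <- genome(c("chr1", "chr2"), c(1e6, 1e6))
  x <- feature_set(data.frame(chrom = c("chr1", "chr2", "chr1"),
                              start = c(100, 0, 5000),
                              end = c(200, 400, 6000)), genome = g)
  path <- tempfile(fileext = ".bed")
  write_intervals(x, path)
  y <- read_intervals(path, genome = g)
  expect_equal(as.data.frame(y)[c("chrom", "start", "end")],
               as.data.frame(x)[c("chrom", "start", "end")])
  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t30\t25"), bad)
  expect_error(read_intervals(bad), "line 2")
  # 1-based inclusive dialect shifts starts by one
  writeLines("chr1\t101\t200", bad)
  z <- read_intervals(bad, one_based = TRUE)
  expect_equal(z$start, 100)
  expect_equal(z$end - z$start, 100)
})

test_that("the published domain catalog is coherent on re-read", {
  cat47 <- ur_domain_catalog()
  expect_equal(nrow(cat47), 47)
  expect_equal(sum(cat47$size), 138485000)
  expect_true(all(cat47$end - cat47$start == cat47$size))
  # round-trips through BED
  path <- tempfile(fileext = ".bed")
  write_intervals(cat47, path)
  back <- read_intervals(path)
  expect_equal(nrow(back), 47)
  expect_equal(sum(back$end - back$start), 138485000)
})

test_that("chromosome naming is normalized across conventions", {
  g <- genome(c("chr1", "chr2"), c(1e6, 1e6))
  expect_equal(normalize_chrom(c("1", "chr2", "7"), g),
               c("chr1", "chr2", "7"))
  g2 <- genome(c("1", "2"), c(1e6, 1e6))
  expect_equal(normalize_chrom("chr1", g2), "1")
})
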