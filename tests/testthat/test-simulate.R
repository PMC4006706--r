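test_that("the generator is deterministic and honors its config", {
  cfg <- sim_config()
  t1 <- simulate_reference(cfg, seed = 1)
  t2 <- simulate_reference(cfg, seed = 1)
  expect_identical(t1$ur_domains, t2$ur_domains)
  expect_identical(as.data.frame(t1$genes), as.data.frame(t2$genes))
  t3 <- simulate_reference(cfg, seed = 2)
  expect_false(identical(t1$ur_domains, t3$ur_domains))
  # zero domains still produce genes and timing structure
  t0 <- simulate_reference(sim_config(n_domains = 0), seed = 3)
  expect_equal(nrow(t0$ur_domains), 0)
  expect_gt(nrow(t0$genes), 0)
  expect_gt(nrow(t0$late_blocks), 0)
  expect_error(simulate_reference(cfg), "seed")
  expect_error(sim_config(d_range = c(0, 0.5)), "d_range")
})

test_that("implanted domains sit inside gene-poor late blocks", {
  truth <- simulate_reference(sim_config(), seed = 4)
  doms <- truth$ur_domains
  late <- truth$late_blocks
  host <- late[late$hosts_domain, ]
  for (i in seq_len(nrow(doms))) {
    inside <- any(host$chrom == doms$chrom[i] &
                    host$start <= doms$start[i] &
                    host$end >= doms$end[i])
    expect_true(inside)
  }
  # sizes and depths within the configured ranges, snapped to the grid
  expect_true(all(doms$end - doms$start >= 75e3))
  expect_true(all(doms$end - doms$start <= 9e6))
  expect_true(all(doms$d >= 0.27 & doms$d <= 0.54))
  expect_true(all(doms$start %% 5000 == 0 & doms$end %% 5000 == 0))
  # hosting blocks are poorer in genes than other late blocks, per Mb
  genes <- as.data.frame(truth$genes)
  dens <- function(blocks) {
    n <- vapply(seq_len(nrow(blocks)), function(i)
      sum(genes$chrom == blocks$chrom[i] & genes$start < blocks$end[i] &
            genes$end > blocks$start[i]), 0L)
    sum(n) / sum(blocks$end - blocks$start) * 1e6
  }
  expect_lt(dens(host), dens(late[!late$hosts_domain, ]))
})

test_that("simulated depth has the promised signal structure", {
  truth0 <- simulate_reference(sim_config(n_domains = 0), seed = 5)
  d0 <- simulate_depth(truth0, seed = 6)
  r0 <- log2_ratio_track(d0$test, d0$control)
  expect_lt(abs(mean(track_values(r0))), 0.01)
  # a d = 0.5 domain lands at log2 ~ -1
  truth5 <- simulate_reference(sim_config(d_range = c(0.5, 0.5)), seed = 7)
  d5 <- simulate_depth(truth5, seed = 8)
  r5 <- log2_ratio_track(d5$test, d5$control)
  s <- summarize_domains(d5$truth_domains, r5)
  expect_true(all(abs(s$mean_log2 - (-1)) < 0.05))
  # library-scale nuisance cancels after normalization (same Poisson draws
  # differ, so compare the domain means rather than bin identity)
  d5b <- simulate_depth(truth5, seed = 8, s = 2)
  r5b <- log2_ratio_track(d5b$test, d5b$control)
  sb <- summarize_domains(d5$truth_domains, r5b)
  expect_true(all(abs(sb$mean_log2 - (-1)) < 0.05))
})

test_that("stage adjustment shrinks domains around their centers", {
  truth <- simulate_reference(sim_config(), seed = 9)
  e95 <- stage_truth_domains(truth, "e9.5")
  e80 <- stage_truth_domains(truth, "e8.0")
  expect_equal(e95$d, truth$ur_domains$d)
  m0 <- match(e80$domain_idx, truth$ur_domains$domain_idx)
  expect_equal(e80$d, truth$ur_domains$d[m0] * 0.8)
  m95 <- match(e80$domain_idx, e95$domain_idx)
  expect_true(all(e80$start >= e95$start[m95]))
  expect_true(all(e80$end <= e95$end[m95]))
  size_ratio <- (e80$end - e80$start) / (e95$end - e95$start)[m95]
  expect_true(all(abs(size_ratio - 0.6) < 0.15))
  expect_error(stage_truth_domains(truth, "e7.0"), "unknown stage")
})

test_that("marks and expression carry the configured contrasts", {
  truth <- simulate_reference(sim_config(), seed = 10)
  me <- simulate_marks_and_expression(truth, seed = 11)
  expect_setequal(names(me$marks),
                  c("H3K9me3", "H3K27me3", "H3K4me3", "H3K27ac"))
  doms <- truth$ur_domains
  f <- sum(doms$end - doms$start) / genome_size(truth$genome)
  in_frac <- vapply(me$marks, function(pk)
    mean(overlaps_any(as.data.frame(pk), doms)), 0)
  # repressive marks over-represented in domains, active under-represented
  expect_gt(in_frac[["H3K9me3"]], f)
  expect_lt(in_frac[["H3K4me3"]], f)
  # in-domain genes are silenced relative to the rest
  expr <- me$expression
  expect_lt(median(expr$expression[expr$in_domain]),
            median(expr$expression[!expr$in_domain]))
  # neutral density ratio gives ~1.0 enrichment
  cfg1 <- sim_config(host_gene_mult = 1, n_desert_tiles = 0,
                     marks = list(neutral = list(class = "repressive",
                                                 ratio = 1, n_peaks = 2000,
                                                 peak_len = 1000)))
  tr1 <- simulate_reference(cfg1, seed = 12)
  me1 <- simulate_marks_and_expression(tr1, seed = 13)
  res <- enrichment_test(as.data.frame(me1$marks$neutral), tr1$ur_domains,
                         tr1$genome, tr1$tss, n_shuffles = 150, seed = 14)
  expect_lt(abs(res$enrichment - 1), 0.1)
})

test_that("a synthetic data set round-trips through its own file formats", {
  truth <- simulate_reference(sim_config(n_domains = 4,
                                         gene_density = 5), seed = 15)
  dir <- file.path(tempdir(), "synthds")
  write_synthetic_dataset(truth, dir, seed = 16)
  g <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  expect_equal(chrom_lengths(g), chrom_lengths(truth$genome))
  td <- read_intervals(file.path(dir, "truth_domains.bed"), genome = g)
  expect_equal(nrow(td), nrow(truth$ur_domains))
  test_tr <- read_bedgraph(file.path(dir, "test_counts.bedgraph"), g, 5000)
  ctrl_tr <- read_bedgraph(file.path(dir, "control_counts.bedgraph"), g,
                           5000)
  r <- log2_ratio_track(test_tr, ctrl_tr)
  calls <- call_ur_domains(r)
  expect_gte(nrow(calls), 3)
  unlink(dir, recursive = TRUE)
})
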