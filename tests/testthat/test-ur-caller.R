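test_that("caller configuration rejects invalid parameters", {
  expect_error(ur_caller_config(log2_threshold = 0.3), "negative")
  expect_error(ur_caller_config(p_value_max = 1.5), "0, 1")
  expect_error(ur_caller_config(min_bins = 0), "min_bins")
})

test_that("candidate runs require a centered track and find exact runs", {
  expect_error(candidate_runs(toy_track(rep(0.5, 100))), "median-centered")
  # all-zero track: no runs
  expect_equal(nrow(candidate_runs(toy_track(rep(0, 100)))), 0)
  # 20 bins at -0.7 flanked by zeros -> one run of exactly 100 kb
  v <- rep(0, 100); v[21:40] <- -0.7
  r <- candidate_runs(toy_track(v))
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(20 * 5000, 40 * 5000))
  expect_equal(r$mean_log2, -0.7)
  # a bin exactly at the threshold is included (<=)
  v2 <- rep(0, 100); v2[21:40] <- -0.3
  expect_equal(nrow(candidate_runs(toy_track(v2))), 1)
})

test_that("runs bridge short interior gaps when the mean stays below threshold", {
  v <- rep(0, 200); v[11:30] <- -0.6; v[31] <- -0.1; v[32:51] <- -0.6
  r <- candidate_runs(toy_track(v))
  expect_equal(nrow(r), 1)
  expect_equal(r$n_bins, 41)
  expect_equal(r$mean_log2, (40 * -0.6 - 0.1) / 41)
  expect_lt(r$mean_log2, -0.3)
  # a 3-bin gap exceeds merge_gap_bins = 2: two separate runs
  v2 <- rep(0, 200); v2[11:30] <- -0.6; v2[34:53] <- -0.6
  expect_equal(nrow(candidate_runs(toy_track(v2))), 2)
  # runs shorter than min_bins are discarded
  v3 <- rep(0, 200); v3[11:20] <- -0.8
  expect_equal(nrow(candidate_runs(toy_track(v3))), 0)
  expect_equal(nrow(candidate_runs(toy_track(v3),
                                   ur_caller_config(min_bins = 10))), 1)
})

test_that("significance is the normal tail of the run mean", {
  # run mean 0 -> p = 0.5 under the symmetric null
  expect_equal(score_significance(data.frame(n_bins = 10, mean_log2 = 0),
                                  sd_genome = 0.2)$p_value, 0.5)
  p15 <- score_significance(data.frame(n_bins = 15, mean_log2 = -0.3),
                            sd_genome = 0.2)$p_value
  expect_equal(p15, pnorm(-0.3 * sqrt(15) / 0.2))
  expect_lt(p15, 0.01)
  expect_equal(round(p15 / 1e-9, 1), 3.1)
  # a single bin at -0.3 against sd 0.3 is not significant at 0.01
  p1 <- score_significance(data.frame(n_bins = 1, mean_log2 = -0.3),
                           sd_genome = 0.3)$p_value
  expect_equal(round(p1, 3), 0.159)
  expect_gt(p1, 0.01)
  expect_error(score_significance(data.frame(n_bins = 1, mean_log2 = -1),
                                  sd_genome = 0), "degenerate")
})

test_that("a flat track yields no calls and shallow depletion is not called", {
  set.seed(10)
  g <- genome("chr1", 10e6)
  flat <- rnorm(2000, 0, 0.1)
  flat <- flat - median(flat)
  tr <- binned_track(g, 5000, values = list(chr1 = flat),
                     kind = "normalized-log2-ratio")
  expect_equal(nrow(call_ur_domains(tr)), 0)
  # d = 0.15 sits at log2 ~ -0.234, above the -0.3 threshold by construction
  lam <- 500
  dep <- rep(0, 2000); dep[501:700] <- 0.15
  r <- log2_ratio_track(
    binned_track(g, 5000, values = list(chr1 = rpois(2000, lam * (1 - dep)))),
    binned_track(g, 5000, values = list(chr1 = rpois(2000, lam))))
  expect_equal(nrow(call_ur_domains(r)), 0)
})

test_that("implanted domains are recovered with tight boundaries", {
  # 10 domains, d 0.3-0.5, 100 kb - 2 Mb, at the default coverage:
  # boundaries land within two bins of truth
  cfg <- sim_config(d_range = c(0.3, 0.5), size_range = c(100e3, 2e6),
                    size_meanlog = log(5e5), size_sdlog = 0.6)
  truth <- simulate_reference(cfg, seed = 71)
  d <- simulate_depth(truth, seed = 72)
  tr <- log2_ratio_track(d$test, d$control)
  calls <- call_ur_domains(tr)
  td <- d$truth_domains
  hit <- 0
  for (i in seq_len(nrow(td))) {
    match <- calls[calls$chrom == td$chrom[i] &
                     calls$end > td$start[i] & calls$start < td$end[i], ]
    if (nrow(match) == 1 &&
        abs(match$start - td$start[i]) <= 2 * 5000 &&
        abs(match$end - td$end[i]) <= 2 * 5000) hit <- hit + 1
  }
  expect_gte(hit, 9)
  # at a quarter of that coverage (lambda = 100) edge bins are noisy enough
  # that a thresholded-run caller trims or splits boundaries, but the
  # domains themselves are still recovered
  cfg100 <- sim_config(lambda = 100, d_range = c(0.3, 0.5),
                       size_range = c(100e3, 2e6), size_meanlog = log(5e5),
                       size_sdlog = 0.6)
  truth100 <- simulate_reference(cfg100, seed = 71)
  d100 <- simulate_depth(truth100, seed = 72)
  calls100 <- call_ur_domains(log2_ratio_track(d100$test, d100$control))
  td100 <- d100$truth_domains
  jac <- vapply(seq_len(nrow(td100)), function(i)
    best_jaccard(td100[i, ], as.data.frame(calls100)), 0)
  expect_gte(sum(jac >= 0.7), 9)
})

test_that("calls are disjoint, satisfy their own filters, and are deterministic", {
  set.seed(20)
  truth <- simulate_reference(sim_config(), seed = 21)
  d <- simulate_depth(truth, seed = 22)
  tr <- log2_ratio_track(d$test, d$control)
  cfg <- ur_caller_config()
  calls <- call_ur_domains(tr, cfg)
  expect_gt(nrow(calls), 0)
  expect_true(all(calls$mean_log2 <= cfg$log2_threshold))
  expect_true(all(calls$p_value <= cfg$p_value_max))
  # non-overlapping within chromosome
  cc <- sort_intervals(as.data.frame(calls))
  if (nrow(cc) > 1) {
    same <- cc$chrom[-1] == cc$chrom[-nrow(cc)]
    expect_true(all(cc$start[-1][same] >= cc$end[-nrow(cc)][same]))
  }
  expect_identical(as.data.frame(call_ur_domains(tr, cfg)),
                   as.data.frame(calls))
})

test_that("relaxing the threshold never removes a called base", {
  for (s in 1:3) {
    truth <- simulate_reference(sim_config(), seed = 30 + s)
    d <- simulate_depth(truth, seed = 40 + s)
    tr <- log2_ratio_track(d$test, d$control)
    tight <- call_ur_domains(tr, ur_caller_config(log2_threshold = -0.3))
    loose <- call_ur_domains(tr, ur_caller_config(log2_threshold = -0.2))
    if (nrow(tight)) {
      cov <- interval_overlap_bp(as.data.frame(tight),
                                 as.data.frame(loose))
      expect_equal(cov, tight$size)
    }
  }
})
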