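# Shared helpers: brute-force oracles and small generators used across tests.

# per-base boolean mask of an interval set on a toy chromosome of length L
base_mask <- function(iv, L) {
  m <- logical(L)
  for (i in seq_len(nrow(iv))) {
    if (iv$end[i] > iv$start[i])
      m[(iv$start[i] + 1):iv$end[i]] <- TRUE
  }
  m
}

random_intervals <- function(n, L, chrom = "chr1", max_len = 500) {
  start <- sample.int(L - max_len, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

# best per-truth-domain Jaccard against a set of calls
best_jaccard <- function(truth_row, calls) {
  best <- 0
  for (j in seq_len(nrow(calls))) {
    if (calls$chrom[j] != truth_row$chrom) next
    o <- max(0, min(calls$end[j], truth_row$end) -
               max(calls$start[j], truth_row$start))
    u <- (truth_row$end - truth_row$start) +
      (calls$end[j] - calls$start[j]) - o
    best <- max(best, o / u)
  }
  best
}

# constant-value normalized track on one toy chromosome
toy_track <- function(v, bin_size = 5000, kind = "normalized-log2-ratio",
                      mask = NULL) {
  g <- genome("chr1", length(v) * bin_size)
  binned_track(g, bin_size, values = list(chr1 = v),
               mask = if (is.null(mask)) NULL else list(chr1 = mask),
               kind = kind)
}
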