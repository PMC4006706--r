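#' Configuration for the UR-domain caller
#'
#' The caller finds maximal runs of neighboring bins whose normalized log2
#' ratio is at or below `log2_threshold` (-0.3 by default, i.e. at least
#' ~19% depletion), allows short interior interruptions, scores each run
#' against a genome-wide null, and keeps runs significant at `p_value_max`.
#'
#' @param log2_threshold Per-bin log2-ratio threshold (< 0; bins exactly at
#'   the threshold are included).
#' @param p_value_max Maximum one-sided p-value for an accepted call
#'   (default 0.01).
#' @param min_bins Minimum run length in bins (default 15; 75 kb on the 5 kb
#'   grid, the smallest reported domain size).
#' @param merge_gap_bins Maximum number of consecutive interior bins above
#'   threshold (or masked) a run may bridge, and the maximum gap in bins at
#'   which accepted calls are merged (default 2, i.e. 10 kb at 5 kb bins).
#' @return A list of class `ur_caller_config`.
#' @export
ur_caller_config <- function(log2_threshold = -0.3, p_value_max = 0.01,
                             min_bins = 15, merge_gap_bins = 2) {
  if (log2_threshold >= 0) stop("log2_threshold must be negative")
  if (p_value_max <= 0 || p_value_max >= 1)
    stop("p_value_max must be in (0, 1)")
  if (min_bins < 1) stop("min_bins must be >= 1")
  if (merge_gap_bins < 0) stop("merge_gap_bins must be >= 0")
  structure(list(log2_threshold = log2_threshold, p_value_max = p_value_max,
                 min_bins = as.integer(min_bins),
                 merge_gap_bins = as.integer(merge_gap_bins)),
            class = "ur_caller_config")
}

check_normalized <- function(track, tol = 1e-6) {
  if (track$kind != "normalized-log2-ratio")
    stop("track must be of kind 'normalized-log2-ratio'")
  med <- stats::median(track_values(track))
  if (!is.finite(med) || abs(med) > tol)
    stop(sprintf("track is not median-centered (median = %.3g)", med))
  invisible(TRUE)
}

#' Genome-wide robust bin standard deviation
#'
#' 1.4826 x the median absolute deviation of the unmasked bin values: the
#' scale of the null (neutral-representation) fluctuations, robust to the
#' minority of depleted bins. On a degenerate track whose majority of bins
#' are exactly equal (noise-free constructed inputs) the MAD collapses to
#' zero; the classical SD is used as the scale there.
#'
#' @param track A normalized log2-ratio [binned_track()].
#' @export
robust_track_sd <- function(track) {
  v <- track_values(track)
  s <- stats::mad(v, center = 0)
  if (!is.finite(s) || s == 0) s <- stats::sd(v)
  s
}

run_mean_stats <- function(track, chrom, from, to) {
  v <- track$values[[chrom]][from:to]
  m <- track$mask[[chrom]][from:to]
  v <- v[m & !is.na(v)]
  list(n = length(v), mean = mean(v), median = stats::median(v))
}

#' Candidate below-threshold runs on a normalized track
#'
#' Finds, per chromosome, maximal runs of unmasked bins at or below the
#' threshold. Runs separated by at most `merge_gap_bins` consecutive
#' interior bins (above threshold or masked) are fused, greedily left to
#' right, provided the fused run's mean over unmasked bins stays at or below
#' the threshold. Runs shorter than `min_bins` are discarded. Runs never
#' cross chromosomes or masked gaps longer than `merge_gap_bins`.
#'
#' @param track A normalized log2-ratio [binned_track()] (median-centered;
#'   enforced).
#' @param cfg A [ur_caller_config()].
#' @return data.frame of unscored candidate runs: `chrom`, `start`, `end`,
#'   `first_bin`, `last_bin`, `n_bins`, `mean_log2`, `median_log2`.
#' @export
candidate_runs <- function(track, cfg = ur_caller_config()) {
  check_normalized(track)
  thr <- cfg$log2_threshold
  res <- list()
  for (ch in track$genome$chrom$chrom) {
    v <- track$values[[ch]]
    m <- track$mask[[ch]]
    below <- !is.na(v) & m & v <= thr
    if (!any(below)) next
    idx <- which(below)
    # seed runs: maximal stretches of consecutive below-threshold bins
    brk <- c(0L, which(diff(idx) > 1L), length(idx))
    seg <- data.frame(
      from = idx[brk[-length(brk)] + 1L],
      to = idx[brk[-1L]]
    )
    # greedy left-to-right fusion across short interior gaps
    i <- 1L
    while (i < nrow(seg)) {
      gap <- seg$from[i + 1L] - seg$to[i] - 1L
      if (gap <= cfg$merge_gap_bins) {
        st <- run_mean_stats(track, ch, seg$from[i], seg$to[i + 1L])
        if (st$n > 0 && st$mean <= thr) {
          seg$to[i] <- seg$to[i + 1L]
          seg <- seg[-(i + 1L), , drop = FALSE]
          next
        }
      }
      i <- i + 1L
    }
    seg <- seg[seg$to - seg$from + 1L >= cfg$min_bins, , drop = FALSE]
    if (!nrow(seg)) next
    for (j in seq_len(nrow(seg))) {
      st <- run_mean_stats(track, ch, seg$from[j], seg$to[j])
      iv <- bins_to_interval(ch, seg$from[j], seg$to[j], track$bin_size,
                             track$genome)
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch, start = iv$start, end = iv$end,
        first_bin = seg$from[j], last_bin = seg$to[j],
        n_bins = st$n, mean_log2 = st$mean, median_log2 = st$median,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), first_bin = integer(),
                      last_bin = integer(), n_bins = integer(),
                      mean_log2 = numeric(), median_log2 = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Score a run's significance against the genome-wide null
#'
#' Under a normal null with mean 0 and per-bin scale `sd_genome` (the
#' genome-wide robust bin SD), the mean of n independent bins has SD
#' `sd_genome / sqrt(n)`; the one-sided p-value for a run of `n` unmasked
#' bins with observed mean `m` is `pnorm(m * sqrt(n) / sd_genome)`.
#' Deterministic.
#'
#' @param runs data.frame from [candidate_runs()] (columns `n_bins`,
#'   `mean_log2`).
#' @param track The track the runs came from, used for `sd_genome` unless
#'   given.
#' @param sd_genome Optional pre-computed robust bin SD.
#' @return `runs` with a `p_value` column appended.
#' @examples
#' score_significance(data.frame(n_bins = 15, mean_log2 = -0.3),
#'                    sd_genome = 0.2)$p_value  # ~3.1e-9
#' @export
score_significance <- function(runs, track = NULL, sd_genome = NULL) {
  if (is.null(sd_genome)) {
    if (is.null(track)) stop("need either a track or sd_genome")
    sd_genome <- robust_track_sd(track)
  }
  if (!is.finite(sd_genome) || sd_genome <= 0)
    stop("degenerate track: genome-wide bin SD is zero")
  if (any(runs$n_bins < 1)) stop("runs must have >= 1 unmasked bin")
  z <- runs$mean_log2 * sqrt(runs$n_bins) / sd_genome
  runs$p_value <- stats::pnorm(z)
  runs
}

#' Call UR domains on a normalized log2-ratio track
#'
#' The full caller: candidate runs ([candidate_runs()]) are scored
#' ([score_significance()]), filtered at `p <= p_value_max`, accepted calls
#' separated by at most `merge_gap_bins` bins are merged, and summaries are
#' recomputed on the merged intervals. Output calls are sorted and
#' non-overlapping, each with `mean_log2 <= log2_threshold` and
#' `p_value <= p_value_max`. Identical track and configuration always give
#' the identical call list.
#'
#' @inheritParams candidate_runs
#' @param sample_id Label attached to every call.
#' @return An object of class `ur_calls`: a data.frame with columns `chrom`,
#'   `start`, `end`, `size`, `n_bins`, `mean_log2`, `median_log2`,
#'   `pct_depl_mean`, `pct_depl_median`, `p_value`, `sample_id`, carrying
#'   the configuration, the genome and the genome-wide robust SD as
#'   attributes.
#' @examples
#' g <- genome("chr1", 1e6)
#' v <- rep(0, 200); v[51:90] <- -0.7
#' tr <- binned_track(g, 5000, values = list(chr1 = v),
#'                    kind = "normalized-log2-ratio")
#' call_ur_domains(tr)
#' @export
call_ur_domains <- function(track, cfg = ur_caller_config(),
                            sample_id = "sample") {
  check_normalized(track)
  sd_genome <- robust_track_sd(track)
  runs <- candidate_runs(track, cfg)
  if (nrow(runs)) {
    runs <- score_significance(runs, sd_genome = sd_genome)
    runs <- runs[runs$p_value <= cfg$p_value_max, , drop = FALSE]
  }
  # merge accepted calls separated by <= merge_gap_bins bins, per chromosome
  merged <- list()
  if (nrow(runs)) {
    runs <- runs[order(match(runs$chrom, track$genome$chrom$chrom),
                       runs$first_bin), , drop = FALSE]
    i <- 1L
    while (i <= nrow(runs)) {
      ch <- runs$chrom[i]
      from <- runs$first_bin[i]; to <- runs$last_bin[i]
      j <- i + 1L
      while (j <= nrow(runs) && runs$chrom[j] == ch &&
             runs$first_bin[j] - to - 1L <= cfg$merge_gap_bins) {
        to <- runs$last_bin[j]
        j <- j + 1L
      }
      merged[[length(merged) + 1L]] <- list(chrom = ch, from = from, to = to)
      i <- j
    }
  }
  rows <- lapply(merged, function(mr) {
    st <- run_mean_stats(track, mr$chrom, mr$from, mr$to)
    iv <- bins_to_interval(mr$chrom, mr$from, mr$to, track$bin_size,
                           track$genome)
    data.frame(chrom = mr$chrom, start = iv$start, end = iv$end,
               size = iv$end - iv$start, n_bins = st$n,
               mean_log2 = st$mean, median_log2 = st$median,
               pct_depl_mean = percent_depletion(st$mean),
               pct_depl_median = percent_depletion(st$median),
               p_value = stats::pnorm(st$mean * sqrt(st$n) / sd_genome),
               sample_id = sample_id, stringsAsFactors = FALSE)
  })
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               size = numeric(), n_bins = integer(), mean_log2 = numeric(),
               median_log2 = numeric(), pct_depl_mean = numeric(),
               pct_depl_median = numeric(), p_value = numeric(),
               sample_id = character(), stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  structure(calls,
            class = c("ur_calls", "data.frame"),
            config = cfg, genome = track$genome,
            bin_size = track$bin_size, sd_genome = sd_genome,
            sample_id = sample_id)
}

#' @export
print.ur_calls <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("UR domain calls for '%s': %d domains (threshold %.2f, p <= %g)\n",
              attr(x, "sample_id"), nrow(x), cfg$log2_threshold,
              cfg$p_value_max))
  if (nrow(x)) {
    cat(sprintf("  total %.2f Mb; size %.0f kb - %.0f kb; mean depletion %.0f%% - %.0f%%\n",
                sum(x$size) / 1e6, min(x$size) / 1e3, max(x$size) / 1e3,
                min(x$pct_depl_mean), max(x$pct_depl_mean)))
    print.data.frame(utils::head(as.data.frame(x), 10), digits = 3)
    if (nrow(x) > 10) cat(sprintf("  ... and %d more\n", nrow(x) - 10))
  }
  invisible(x)
}

#' @export
summary.ur_calls <- function(object, ...) {
  out <- list(
    sample_id = attr(object, "sample_id"),
    n_domains = nrow(object),
    total_bp = sum(object$size),
    genome_fraction = sum(object$size) / genome_size(attr(object, "genome")),
    size_range = if (nrow(object)) range(object$size) else c(NA, NA),
    pct_depl_mean_range = if (nrow(object)) range(object$pct_depl_mean)
      else c(NA, NA),
    pct_depl_median_max = if (nrow(object)) max(object$pct_depl_median)
      else NA,
    sd_genome = attr(object, "sd_genome"))
  class(out) <- "summary.ur_calls"
  out
}

#' @export
print.summary.ur_calls <- function(x, ...) {
  cat(sprintf("UR domains for '%s'\n", x$sample_id))
  cat(sprintf("  domains:        %d\n", x$n_domains))
  cat(sprintf("  total:          %.2f Mb (%.1f%% of genome)\n",
              x$total_bp / 1e6, 100 * x$genome_fraction))
  if (x$n_domains) {
    cat(sprintf("  sizes:          %.0f kb - %.0f kb\n",
                x$size_range[1] / 1e3, x$size_range[2] / 1e3))
    cat(sprintf("  mean depletion: %.0f%% - %.0f%% (max median %.0f%%)\n",
                x$pct_depl_mean_range[1], x$pct_depl_mean_range[2],
                x$pct_depl_median_max))
  }
  cat(sprintf("  null bin SD:    %.4f\n", x$sd_genome))
  invisible(x)
}

#' Plot a chromosome's track with its UR calls
#'
#' Base-graphics view of the normalized log2-ratio along one chromosome with
#' the calls shaded and the calling threshold drawn.
#'
#' @param x An `ur_calls` object.
#' @param track The track the calls were made on.
#' @param chrom Chromosome to plot (default: first with a call, else first).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ur_calls <- function(x, track, chrom = NULL, ...) {
  if (is.null(chrom))
    chrom <- if (nrow(x)) x$chrom[1] else track$genome$chrom$chrom[1]
  v <- track$values[[chrom]]
  pos <- (seq_along(v) - 0.5) * track$bin_size / 1e6
  graphics::plot(pos, v, type = "p", pch = 16, cex = 0.3,
                 col = "grey40", xlab = sprintf("%s position (Mb)", chrom),
                 ylab = "normalized log2 ratio", ...)
  cc <- x[x$chrom == chrom, , drop = FALSE]
  if (nrow(cc))
    graphics::rect(cc$start / 1e6, graphics::par("usr")[3], cc$end / 1e6,
                   graphics::par("usr")[4],
                   col = grDevices::adjustcolor("indianred", 0.25),
                   border = NA)
  graphics::abline(h = attr(x, "config")$log2_threshold, lty = 2,
                   col = "steelblue")
  invisible(x)
}

#' Write calls as a BED file and a full TSV report
#'
#' @param x An `ur_calls` object.
#' @param bed,tsv Output paths (either may be `NULL` to skip).
#' @export
write_ur_calls <- function(x, bed = NULL, tsv = NULL) {
  if (!is.null(bed)) write_intervals(as.data.frame(x), bed,
                                     extra_cols = "sample_id")
  if (!is.null(tsv))
    utils::write.table(as.data.frame(x), tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(x)
}
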