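#' Percent depletion implied by a log2 ratio
#'
#' A normalized log2 coverage ratio L corresponds to a representation of
#' `2^L` of the expected copies, i.e. a depletion of `100 * (1 - 2^L)`
#' percent. L = 0 gives 0%; L = -1 gives 50% (half representation).
#' Monotone decreasing in L; [depletion_log2()] is its exact inverse.
#'
#' @param L Log2 ratio(s).
#' @return Percent depletion, unrounded (use [round_percent()] at report
#'   time).
#' @examples
#' percent_depletion(-0.71)  # 38.86, printed as 39%
#' @export
percent_depletion <- function(L) 100 * (1 - 2^L)

#' Log2 ratio implied by a percent depletion (inverse of percent_depletion)
#' @param pct Percent depletion.
#' @export
depletion_log2 <- function(pct) log2(1 - pct / 100)

#' Round a percentage for reporting (half away from zero)
#'
#' Integer-percent report rounding: `39.5 -> 40`, `-39.5 -> -40` (base
#' `round()` would round half to even).
#'
#' @param pct Numeric vector.
#' @export
round_percent <- function(pct) sign(pct) * floor(abs(pct) + 0.5)

#' Depletion summary of one domain on a track
#'
#' Mean and median normalized log2 over the unmasked bins overlapping the
#' domain, their percent depletions, and the chromosome-median-adjusted
#' percent depletion (the domain's median log2 minus the chromosome-wide
#' median log2, converted to percent) — a chromosome-normalized variant of
#' the per-domain statistic.
#'
#' @param domain Single-row interval data.frame (`chrom`, `start`, `end`).
#' @param track A normalized log2-ratio [binned_track()].
#' @return One-row data.frame with `chrom`, `start`, `end`, `size`,
#'   `n_bins`, `mean_log2`, `median_log2`, `pct_depl_mean`,
#'   `pct_depl_median`, `pct_depl_chrom_median`.
#' @export
summarize_domain <- function(domain, track) {
  ch <- domain$chrom[1]
  if (!ch %in% names(track$values))
    stop(sprintf("domain chromosome '%s' not on the track's genome", ch))
  rng <- interval_to_bins(domain, track$bin_size, track$genome)
  v <- track$values[[ch]][rng["from"]:rng["to"]]
  m <- track$mask[[ch]][rng["from"]:rng["to"]]
  v <- v[m & !is.na(v)]
  if (!length(v))
    stop("domain overlaps no unmasked bins")
  chrom_med <- stats::median(
    track$values[[ch]][track$mask[[ch]]], na.rm = TRUE)
  med <- stats::median(v)
  data.frame(chrom = ch, start = domain$start[1], end = domain$end[1],
             size = domain$end[1] - domain$start[1], n_bins = length(v),
             mean_log2 = mean(v), median_log2 = med,
             pct_depl_mean = percent_depletion(mean(v)),
             pct_depl_median = percent_depletion(med),
             pct_depl_chrom_median = percent_depletion(med - chrom_med),
             stringsAsFactors = FALSE)
}

#' Depletion summaries for a set of domains
#'
#' @param domains Interval data.frame (e.g. an `ur_calls` object).
#' @inheritParams summarize_domain
#' @return data.frame with one [summarize_domain()] row per domain.
#' @export
summarize_domains <- function(domains, track) {
  rows <- lapply(seq_len(nrow(domains)), function(i)
    summarize_domain(domains[i, , drop = FALSE], track))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Size-depletion relationship across domains
#'
#' Pearson correlation (with two-sided p) between domain size and percent
#' depletion. In the published data the larger the domain the greater its
#' underrepresentation.
#'
#' @param summaries data.frame with columns `size` and the chosen depletion
#'   column, e.g. from [summarize_domains()].
#' @param depletion Column to correlate against size (default
#'   `"pct_depl_chrom_median"`, falling back to `"pct_depl_median"` when
#'   absent).
#' @return List with `r`, `p_value`, `slope` (percent points per Mb), `n`.
#' @export
size_depletion_correlation <- function(summaries,
                                       depletion = "pct_depl_chrom_median") {
  if (!depletion %in% names(summaries)) depletion <- "pct_depl_median"
  if (nrow(summaries) < 3)
    stop("need at least 3 domains for a size-depletion correlation")
  s <- summaries$size
  d <- summaries[[depletion]]
  ct <- stats::cor.test(s, d, method = "pearson")
  fit <- stats::lm(d ~ I(s / 1e6))
  list(r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2]), n = nrow(summaries))
}

#' Report table for a call set, in the published catalog's shape
#'
#' One row per domain: coordinates, size, mean/median log2, integer percent
#' depletions (rounded half away from zero), p-value and sample id.
#'
#' @param calls An `ur_calls` object or interval data.frame.
#' @param track Optional track to (re)compute summaries from; if `NULL` the
#'   columns already present on `calls` are used.
#' @return data.frame ready for `write.table`.
#' @export
domain_report <- function(calls, track = NULL) {
  x <- if (!is.null(track)) summarize_domains(calls, track)
       else as.data.frame(calls)
  data.frame(chrom = x$chrom, start = x$start, end = x$end,
             size = x$end - x$start, n_bins = x$n_bins,
             mean_log2 = round(x$mean_log2, 2),
             median_log2 = round(x$median_log2, 2),
             pct_depl_mean = round_percent(x$pct_depl_mean),
             pct_depl_median = round_percent(x$pct_depl_median),
             p_value = if ("p_value" %in% names(x)) signif(x$p_value, 3)
               else NA,
             sample_id = if ("sample_id" %in% names(x)) x$sample_id else NA,
             stringsAsFactors = FALSE)
}
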