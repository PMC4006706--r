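#' Paired-end insert-size model
#'
#' Describes a sequencing library's insert geometry: two `read_length` bp
#' mates flanking an unsequenced middle, with outer-mate-to-outer-mate span
#' (the insert) distributed around `mean_insert`. A mapped pair is
#' "discordant" when its apparent reference span exceeds
#' `mean_insert + discordance_k * sd_insert` — evidence that sequence
#' between the mates is missing from the sequenced genome.
#'
#' @param mean_insert Mean insert (outer span) in bp (default 500).
#' @param sd_insert Insert SD in bp (default 50).
#' @param read_length Mate length in bp (default 101).
#' @param discordance_k Number of SDs above the mean defining discordance
#'   (default 4).
#' @return List of class `insert_model` with the fields above plus
#'   `discordance_threshold`.
#' @export
insert_model <- function(mean_insert = 500, sd_insert = 50,
                         read_length = 101, discordance_k = 4) {
  if (mean_insert <= 2 * read_length)
    stop("mean_insert must exceed twice the read length")
  if (sd_insert <= 0 || discordance_k <= 0)
    stop("sd_insert and discordance_k must be positive")
  structure(list(mean_insert = mean_insert, sd_insert = sd_insert,
                 read_length = read_length, discordance_k = discordance_k,
                 discordance_threshold = mean_insert +
                   discordance_k * sd_insert),
            class = "insert_model")
}

#' Count discordant pairs spanning a region
#'
#' Counts pairs whose mates flank the region (left mate ends at or before
#' the region start, right mate begins at or after the region end) and
#' whose apparent span exceeds the discordance threshold. Pairs mapping
#' fully inside the region do not count: they exist only on chromosome
#' copies that retain the region.
#'
#' @param pairs data.frame with columns `chrom`, `left_start` (0-based
#'   start of the left mate) and `span` (outer-mate-to-outer-mate apparent
#'   reference span, bp).
#' @param region Single-row interval data.frame.
#' @param model An [insert_model()].
#' @return Integer count.
#' @examples
#' m <- insert_model()
#' p <- data.frame(chrom = "chr1", left_start = 4800, span = 10000)
#' count_discordant_spanning(p, data.frame(chrom = "chr1", start = 5000,
#'                                         end = 14500), m)  # 1
#' @export
count_discordant_spanning <- function(pairs, region, model) {
  if (!nrow(pairs)) return(0L)
  sel <- pairs$chrom == region$chrom[1]
  if (!any(sel)) return(0L)
  p <- pairs[sel, , drop = FALSE]
  left_end <- p$left_start + model$read_length
  right_begin <- p$left_start + p$span - model$read_length
  sum(left_end <= region$start[1] &
        right_begin >= region$end[1] &
        p$span > model$discordance_threshold)
}

#' Classify a region as deleted or underreplication-consistent
#'
#' Under a true deletion carried by `deleted_fraction` of the genome
#' copies, pairs whose unsequenced middle crosses the deletion junction map
#' back with the deletion's length added to their span and flank the
#' region. Their expected number is
#' `coverage / (2 * read_length) * max(0, mean_insert - 2 * read_length) *
#' deleted_fraction` (pair rate per bp times the junction-crossing window).
#' The verdict is `deletion` when the observed discordant count reaches
#' `max(2, 10%)` of that expectation. The per-sample probability of
#' missing a true deletion is the Poisson tail below the verdict
#' threshold; across independent samples the joint non-detection
#' probability is that tail to the n-th power (see
#' [multi_sample_nondetection()]).
#'
#' @param discordant Observed discordant flanking-pair count.
#' @param coverage_depth Fold sequencing coverage (> 0).
#' @param region Single-row interval data.frame (used for reporting).
#' @param model An [insert_model()].
#' @param deleted_fraction Fraction of copies assumed to carry the deletion
#'   under the alternative (default 0.5, the depth-implied scenario).
#' @return List of class `deletion_verdict`: `verdict` (`"deletion"`,
#'   `"underreplication-consistent"` or `"withheld"`), `observed`,
#'   `expected_if_deleted`, `threshold`, `p_no_deletion_missed` (per-sample
#'   probability that a true deletion would have produced fewer discordant
#'   pairs than the threshold).
#' @export
classify_region <- function(discordant, coverage_depth, region, model,
                            deleted_fraction = 0.5) {
  if (coverage_depth <= 0) stop("coverage_depth must be positive")
  window <- max(0, model$mean_insert - 2 * model$read_length)
  expected <- coverage_depth / (2 * model$read_length) * window *
    deleted_fraction
  if (expected <= 0) {
    return(structure(list(verdict = "withheld", observed = discordant,
                          expected_if_deleted = expected, threshold = NA,
                          p_no_deletion_missed = NA_real_,
                          region = region), class = "deletion_verdict"))
  }
  threshold <- max(2, 0.1 * expected)
  verdict <- if (discordant >= threshold) "deletion"
             else "underreplication-consistent"
  # probability a true deletion would yield a sub-threshold count
  q <- stats::ppois(ceiling(threshold) - 1, expected)
  structure(list(verdict = verdict, observed = discordant,
                 expected_if_deleted = expected, threshold = threshold,
                 p_no_deletion_missed = q, region = region),
            class = "deletion_verdict")
}

#' @export
print.deletion_verdict <- function(x, ...) {
  cat(sprintf("verdict: %s (observed %d discordant pairs, %.1f expected under deletion)\n",
              x$verdict, x$observed, x$expected_if_deleted))
  if (is.finite(x$p_no_deletion_missed))
    cat(sprintf("  per-sample probability of missing a true deletion: %.3g\n",
                x$p_no_deletion_missed))
  invisible(x)
}

#' Joint probability that a deletion escapes detection in every sample
#'
#' With per-sample detection probability `p_detect`, the probability that a
#' genuine deletion is detected in none of `n_samples` independent samples
#' is `(1 - p_detect)^n_samples`. With `p_detect = 0.835` and six samples
#' this is about 2e-5.
#'
#' @param p_detect Per-sample detection probability in (0, 1].
#' @param n_samples Number of independent samples.
#' @export
multi_sample_nondetection <- function(p_detect, n_samples) {
  if (any(p_detect <= 0) || any(p_detect > 1))
    stop("p_detect must be in (0, 1]")
  (1 - p_detect)^n_samples
}
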