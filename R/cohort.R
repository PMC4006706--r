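#' Bundle one sample's domain calls with its identity and stage
#'
#' @param calls Interval data.frame of the sample's calls (sorted,
#'   non-overlapping; enforced by merging).
#' @param sample_id Sample label.
#' @param stage Developmental stage label (e.g. `"e8.0"`, `"e9.5"`,
#'   `"day7"`).
#' @return List of class `sample_call_set`.
#' @export
sample_call_set <- function(calls, sample_id, stage = NA_character_) {
  calls <- as.data.frame(calls)
  validate_intervals(calls)
  calls <- sort_intervals(calls)
  if (nrow(calls) > 1) {
    ovl <- any(calls$chrom[-1] == calls$chrom[-nrow(calls)] &
                 calls$start[-1] < calls$end[-nrow(calls)])
    if (ovl) stop("calls within one sample must be non-overlapping")
  }
  rownames(calls) <- NULL
  structure(list(sample_id = sample_id, stage = stage, calls = calls),
            class = "sample_call_set")
}

#' @export
print.sample_call_set <- function(x, ...) {
  cat(sprintf("<sample_call_set '%s' (stage %s): %d domains>\n",
              x$sample_id, x$stage, nrow(x$calls)))
  invisible(x)
}

match_pair <- function(a, b, rule) {
  # does interval a (row) overlap interval b (row) under the match rule?
  ov <- max(0, min(a$end, b$end) - max(a$start, b$start))
  if (ov <= 0 || a$chrom != b$chrom) return(FALSE)
  if (rule == "any-overlap") return(TRUE)
  ov >= 0.5 * (a$end - a$start) && ov >= 0.5 * (b$end - b$start)
}

#' Consensus domains across samples
#'
#' Groups domains from multiple samples by overlap (connected components
#' under the match rule) and reports, per group, the number of distinct
#' supporting samples and the consensus interval. The consensus interval is
#' the intersection of each supporting sample's merged member span
#' (conservative, the defensible shared core); `consensus = "union"` gives
#' the union instead.
#'
#' @param sets List of [sample_call_set()]s (>= 2) on one genome.
#' @param min_support Keep only groups supported by at least this many
#'   samples (default 1: keep all).
#' @param match_rule `"any-overlap"` (>= 1 bp, default) or `"reciprocal-50"`
#'   (each member covers >= 50% of the other).
#' @param consensus `"intersection"` (default) or `"union"`.
#' @return data.frame with `chrom`, `start`, `end`, `support`,
#'   `samples` (comma-joined ids); groups whose intersection is empty under
#'   `consensus = "intersection"` get the minimal covering core of the
#'   members instead and are flagged in `intersection_empty`.
#' @export
consensus_domains <- function(sets, min_support = 1,
                              match_rule = c("any-overlap", "reciprocal-50"),
                              consensus = c("intersection", "union")) {
  match_rule <- match.arg(match_rule)
  consensus <- match.arg(consensus)
  if (length(sets) < 2) stop("need at least 2 sample call sets")
  all_rows <- do.call(rbind, lapply(sets, function(s) {
    if (!nrow(s$calls)) return(NULL)
    data.frame(chrom = s$calls$chrom, start = s$calls$start,
               end = s$calls$end, sample_id = s$sample_id,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all_rows) || !nrow(all_rows))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), support = integer(),
                      samples = character(),
                      intersection_empty = logical()))
  all_rows <- sort_intervals(all_rows)
  rownames(all_rows) <- NULL
  n <- nrow(all_rows)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (all_rows$chrom[j] != all_rows$chrom[i]) break
      if (all_rows$start[j] >= all_rows$end[i]) break
      if (match_pair(all_rows[i, ], all_rows[j, ], match_rule)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  groups <- split(seq_len(n), roots)
  rows <- lapply(groups, function(ix) {
    g <- all_rows[ix, , drop = FALSE]
    ids <- unique(g$sample_id)
    per_sample <- lapply(ids, function(id) {
      gg <- g[g$sample_id == id, , drop = FALSE]
      c(min(gg$start), max(gg$end))
    })
    lo <- vapply(per_sample, `[`, 0, 1)
    hi <- vapply(per_sample, `[`, 0, 2)
    if (consensus == "union") {
      s <- min(lo); e <- max(hi); empty <- FALSE
    } else {
      s <- max(lo); e <- min(hi)
      empty <- e <= s
      if (empty) { s <- min(lo); e <- max(hi) }
    }
    data.frame(chrom = g$chrom[1], start = s, end = e,
               support = length(ids),
               samples = paste(sort(ids), collapse = ","),
               intersection_empty = empty, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- sort_intervals(out)
  rownames(out) <- NULL
  out
}

#' Pairwise nestedness of sample call sets
#'
#' For each ordered pair (query, reference): the fraction of the query
#' sample's domains that overlap the union of the reference sample's
#' domains. A sample fully nested in another has fraction 1; fractions are
#' in [0, 1] and `fraction(X in X) = 1`. Samples without calls get `NA`.
#'
#' @param sets List of [sample_call_set()]s (>= 2).
#' @return List with `fractions` (matrix, rows = query, cols = reference)
#'   and `n_calls` (per-sample call counts).
#' @export
nestedness <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 sample call sets")
  ids <- vapply(sets, function(s) s$sample_id, "")
  k <- length(sets)
  fr <- matrix(NA_real_, k, k, dimnames = list(query = ids, reference = ids))
  for (i in seq_len(k)) {
    qi <- sets[[i]]$calls
    if (!nrow(qi)) next
    for (j in seq_len(k)) {
      rj <- sets[[j]]$calls
      fr[i, j] <- if (nrow(rj)) mean(overlaps_any(qi, rj)) else 0
    }
  }
  list(fractions = fr,
       n_calls = stats::setNames(vapply(sets, function(s) nrow(s$calls), 0L),
                                 ids))
}

#' Distribution-free comparison of two groups of domain statistics
#'
#' Two-sided Wilcoxon rank-sum comparison of, e.g., domain sizes or percent
#' depletions between two stages or samples; significance is declared at
#' `p < alpha` (0.01 by default, matching the box-plot comparisons of the
#' published analysis). Fully tied degenerate inputs give p = 1.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param alpha Significance level (default 0.01).
#' @return List with `statistic` (W), `p_value`, `significant`,
#'   `median_a`, `median_b`.
#' @export
compare_groups <- function(a, b, alpha = 0.01) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (length(unique(c(a, b))) == 1L) {
    return(list(statistic = NA_real_, p_value = 1, significant = FALSE,
                median_a = stats::median(a), median_b = stats::median(b)))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       significant = wt$p.value < alpha,
       median_a = stats::median(a), median_b = stats::median(b))
}
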