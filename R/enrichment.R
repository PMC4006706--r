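#' TSS-distance class boundaries
#'
#' Features are stratified by the distance from their midpoint to the
#' nearest transcriptional start site into the classes
#' `[0,1kb) [1kb,10kb) [10kb,100kb) [100kb,1Mb) >=1Mb`, which partition
#' `[0, Inf)`. Randomization preserves these classes so that the null keeps
#' each feature's relationship to genes.
#'
#' @return Numeric vector of finite class boundaries (bp).
#' @export
tss_class_boundaries <- function() c(1e3, 1e4, 1e5, 1e6)

tss_class_labels <- function(boundaries = tss_class_boundaries()) {
  fmt <- function(x) ifelse(x >= 1e6, paste0(x / 1e6, "Mb"),
                            ifelse(x >= 1e3, paste0(x / 1e3, "kb"),
                                   as.character(x)))
  lo <- c(0, boundaries[-length(boundaries)])
  c(paste0("[", fmt(lo), ",", fmt(boundaries), ")"),
    paste0(">=", fmt(boundaries[length(boundaries)])))
}

tss_by_chrom <- function(tss) {
  # accepts a data.frame (chrom, pos) or a named list of sorted positions
  if (is.data.frame(tss)) {
    split_pos <- split(tss$pos, tss$chrom)
  } else {
    split_pos <- tss
  }
  lapply(split_pos, function(p) sort(as.numeric(p)))
}

nearest_tss_distance <- function(chrom, mid, tss_list) {
  out <- rep(Inf, length(mid))
  for (ch in unique(chrom)) {
    p <- tss_list[[ch]]
    if (is.null(p) || !length(p)) next
    sel <- which(chrom == ch)
    i <- findInterval(mid[sel], p)
    lo <- ifelse(i >= 1, mid[sel] - p[pmax(i, 1)], Inf)
    hi <- ifelse(i < length(p), p[pmin(i + 1, length(p))] - mid[sel], Inf)
    out[sel] <- pmin(abs(lo), abs(hi))
  }
  out
}

#' Assign features to TSS-distance classes
#'
#' Distance is the minimum absolute distance from the feature midpoint to
#' any TSS on its chromosome; chromosomes without any TSS fall in the
#' farthest class.
#'
#' @param features Interval data.frame.
#' @param tss data.frame with columns `chrom`, `pos`, or a named list of
#'   per-chromosome sorted TSS positions.
#' @param boundaries Class boundaries, see [tss_class_boundaries()].
#' @return Character vector of class labels, one per feature.
#' @export
assign_tss_class <- function(features, tss,
                             boundaries = tss_class_boundaries()) {
  labs <- tss_class_labels(boundaries)
  if (!nrow(features)) return(character())
  tl <- tss_by_chrom(tss)
  mid <- (features$start + features$end) / 2
  d <- nearest_tss_distance(features$chrom, mid, tl)
  labs[findInterval(d, c(0, boundaries))]
}

#' Per-(chromosome, class) midpoint territories
#'
#' The set of genomic positions whose nearest-TSS distance falls in each
#' TSS-distance class, per chromosome. Precompute once and pass to
#' [shuffle_features()] / [enrichment_test()] when running many tests on
#' one genome.
#'
#' @inheritParams assign_tss_class
#' @param genome A [genome()] object.
#' @return Nested list: per chromosome, a named list of interval
#'   data.frames, one per class label.
#' @export
class_territories <- function(genome, tss,
                              boundaries = tss_class_boundaries()) {
  labs <- tss_class_labels(boundaries)
  tl <- tss_by_chrom(tss)
  len <- chrom_lengths(genome)
  out <- list()
  for (ch in genome$chrom$chrom) {
    whole <- as_intervals(ch, 0, len[[ch]])
    p <- tl[[ch]]
    if (is.null(p) || !length(p)) {
      # no TSS: every position is in the farthest class
      out[[ch]] <- stats::setNames(c(rep(list(whole[0, ]),
                                         length(labs) - 1), list(whole)),
                                   labs)
      next
    }
    near <- function(b) {
      iv <- as_intervals(ch, pmax(0, p - b), pmin(len[[ch]], p + b))
      iv <- iv[iv$end > iv$start, , drop = FALSE]
      if (nrow(iv)) sort_and_merge(iv) else whole[0, ]
    }
    regions <- lapply(boundaries, near)
    terr <- vector("list", length(labs))
    prev <- whole[0, ]
    for (k in seq_along(boundaries)) {
      terr[[k]] <- if (nrow(prev)) subtract_intervals(regions[[k]], prev)
                   else regions[[k]]
      prev <- regions[[k]]
    }
    terr[[length(labs)]] <- subtract_intervals(whole, prev)
    out[[ch]] <- stats::setNames(terr, labs)
  }
  out
}

sample_from_territory <- function(terr, k) {
  # k uniform draws from a set of intervals (one chromosome)
  w <- terr$end - terr$start
  tot <- sum(w)
  if (tot <= 0 || !nrow(terr)) return(rep(NA_real_, k))
  u <- stats::runif(k) * tot
  cs <- cumsum(w)
  seg <- findInterval(u, c(0, cs[-length(cs)]), left.open = TRUE)
  seg <- pmax(seg, 1L)
  terr$start[seg] + (u - c(0, cs)[seg])
}

#' Shuffle a feature set preserving chromosome, length and TSS class
#'
#' Each shuffled replicate redraws every feature's midpoint uniformly from
#' the genomic territory of its (chromosome, TSS-distance-class) stratum,
#' keeping its chromosome, its length and its class exactly; feature count
#' is conserved and shuffled features may overlap one another. When a
#' feature is too long to fit around any point of its stratum's territory
#' it is placed at the nearest feasible position and tallied in the
#' `n_fallback` attribute. Reproducible under `seed`.
#'
#' @param features Interval data.frame.
#' @param genome A [genome()] object.
#' @param tss TSS positions, see [assign_tss_class()].
#' @param n_shuffles Number of replicates.
#' @param seed Integer seed (mandatory: randomized placements must be
#'   reproducible).
#' @param territories Optional precomputed [class_territories()] result.
#' @return List of `n_shuffles` data.frames (`chrom`, `start`, `end`,
#'   `tss_class`), with attribute `n_fallback`.
#' @export
shuffle_features <- function(features, genome, tss, n_shuffles, seed,
                             territories = NULL) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(seed)
  if (is.null(territories))
    territories <- class_territories(genome, tss)
  cls <- assign_tss_class(features, tss)
  len <- chrom_lengths(genome)
  n <- nrow(features)
  flen <- features$end - features$start
  strata <- split(seq_len(n), paste(features$chrom, cls, sep = "\r"))
  n_fallback <- 0L
  out <- vector("list", n_shuffles)
  for (s in seq_len(n_shuffles)) {
    start <- numeric(n)
    for (key in names(strata)) {
      ix <- strata[[key]]
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      ch <- parts[1]
      terr <- territories[[ch]][[parts[2]]]
      mid <- sample_from_territory(terr, length(ix))
      half <- flen[ix] / 2
      # integer starts keep end - start exactly equal to the feature length
      st <- floor(mid - half)
      # keep the feature on the chromosome without changing its length
      lo_bad <- !is.na(st) & st < 0
      hi_bad <- !is.na(st) & (st + flen[ix]) > len[[ch]]
      if (any(is.na(st))) {
        st[is.na(st)] <- pmax(0, (len[[ch]] - flen[ix])[is.na(st)] / 2)
        n_fallback <- n_fallback + sum(is.na(mid))
      }
      if (any(lo_bad)) { st[lo_bad] <- 0; n_fallback <- n_fallback + sum(lo_bad) }
      if (any(hi_bad)) {
        st[hi_bad] <- len[[ch]] - flen[ix][hi_bad]
        n_fallback <- n_fallback + sum(hi_bad)
      }
      start[ix] <- st
    }
    df <- data.frame(chrom = features$chrom, start = start,
                     end = start + flen, tss_class = cls,
                     stringsAsFactors = FALSE)
    out[[s]] <- df
  }
  attr(out, "n_fallback") <- n_fallback
  out
}

count_overlapping_features <- function(features, dom_by_chrom) {
  total <- 0L
  for (ch in names(dom_by_chrom)) {
    d <- dom_by_chrom[[ch]]
    sel <- features$chrom == ch
    if (!any(sel) || !nrow(d)) next
    s <- features$start[sel]; e <- features$end[sel]
    # first merged domain whose end exceeds the feature start; overlap iff
    # that domain starts before the feature end
    i <- findInterval(s, d$end) + 1L
    hit <- i <= nrow(d) & d$start[pmin(i, nrow(d))] < e
    total <- total + sum(hit)
  }
  total
}

#' Randomization enrichment test of a feature set within domains
#'
#' A feature counts as overlapping if it intersects any domain by at least
#' 1 bp. The expected count is the mean over TSS-class-preserving shuffles
#' ([shuffle_features()]); significance comes from a binomial test with
#' `n =` number of features and success probability `expected / n`,
#' one-sided in the direction of the observed deviation and doubled for the
#' two-sided report (capped at 1). The mid-p tail (half weight on the
#' observed count) is used so that null p-values are uniform rather than
#' conservative.
#'
#' @param features Interval data.frame (the feature set under test).
#' @param domains Interval data.frame (held fixed).
#' @param genome A [genome()] object.
#' @param tss TSS positions, see [assign_tss_class()].
#' @param n_shuffles Number of randomizations (>= 100; default 1000).
#' @param seed Integer seed.
#' @param feature_name Label for the report.
#' @param territories Optional precomputed [class_territories()].
#' @return One-row data.frame of class `enrichment_result`: `feature_name`,
#'   `n_features`, `observed`, `expected`, `enrichment`, `p_value`,
#'   `direction`, `n_shuffles`, `seed`, `smoothed`.
#' @export
enrichment_test <- function(features, domains, genome, tss,
                            n_shuffles = 1000, seed,
                            feature_name = "features",
                            territories = NULL) {
  if (n_shuffles < 100) stop("n_shuffles must be >= 100")
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  n <- nrow(features)
  if (!n) stop("empty feature set")
  dom <- sort_and_merge(domains)
  dom_by_chrom <- split(dom, dom$chrom)
  observed <- count_overlapping_features(features, dom_by_chrom)
  if (is.null(territories))
    territories <- class_territories(genome, tss)
  shuffles <- shuffle_features(features, genome, tss, n_shuffles, seed,
                               territories = territories)
  counts <- vapply(shuffles, count_overlapping_features, 0L,
                   dom_by_chrom = dom_by_chrom)
  expected <- mean(counts)
  smoothed <- FALSE
  if (expected == 0 && observed > 0) {
    expected_p <- (sum(counts) + 1) / (n_shuffles * n)
    smoothed <- TRUE
  } else {
    expected_p <- min(max(expected / n, .Machine$double.eps), 1)
  }
  # mid-p one-sided tail (half weight on the observed count), doubled for
  # the two-sided report: plain discrete tails are conservative enough to
  # break null calibration
  if (observed >= expected) {
    p_one <- stats::pbinom(observed, n, expected_p, lower.tail = FALSE) +
      0.5 * stats::dbinom(observed, n, expected_p)
    direction <- "enriched"
  } else {
    p_one <- stats::pbinom(observed - 1, n, expected_p) +
      0.5 * stats::dbinom(observed, n, expected_p)
    direction <- "depleted"
  }
  out <- data.frame(feature_name = feature_name, n_features = n,
                    observed = observed, expected = expected,
                    enrichment = if (expected > 0) observed / expected
                      else NA_real_,
                    p_value = min(1, 2 * p_one), direction = direction,
                    n_shuffles = n_shuffles, seed = seed,
                    smoothed = smoothed, stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%s: %d observed vs %.1f expected (%.2fx, %s, p = %.3g)\n",
                x$feature_name[i], x$observed[i], x$expected[i],
                x$enrichment[i], x$direction[i], x$p_value[i]))
  }
  invisible(x)
}

#' Find gene deserts: fixed windows without any annotation
#'
#' Tiles each chromosome with non-overlapping windows (1 Mb by default,
#' complete windows only) and returns those overlapped by no feature. A
#' sliding variant (`step < window`) is available; the returned tiles are
#' then merged.
#'
#' @param genes Interval data.frame of annotations.
#' @param genome A [genome()] object.
#' @param window Window size in bp (default 1 Mb).
#' @param step Step between window starts (default `window`:
#'   non-overlapping tiling).
#' @return A [feature_set()] of desert windows.
#' @export
find_gene_deserts <- function(genes, genome, window = 1e6, step = window) {
  if (window <= 0 || step <= 0) stop("window and step must be positive")
  len <- chrom_lengths(genome)
  gmerged <- if (nrow(genes)) sort_and_merge(genes) else genes
  gl <- if (nrow(genes)) split(gmerged, gmerged$chrom) else list()
  tiles <- list()
  for (ch in genome$chrom$chrom) {
    starts <- seq(0, len[[ch]] - window, by = step)
    if (!length(starts)) next
    tl <- as_intervals(ch, starts, starts + window)
    d <- gl[[ch]]
    if (!is.null(d) && nrow(d)) {
      i <- findInterval(tl$start, d$end) + 1L
      hit <- i <= nrow(d) & d$start[pmin(i, nrow(d))] < tl$end
      tl <- tl[!hit, , drop = FALSE]
    }
    if (nrow(tl)) tiles[[ch]] <- tl
  }
  res <- if (length(tiles)) do.call(rbind, tiles) else
    as_intervals(character(), numeric(), numeric())
  if (step < window && nrow(res)) res <- sort_and_merge(res)
  feature_set(res, name = sprintf("gene_deserts_%gkb", window / 1e3),
              genome = genome)
}
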