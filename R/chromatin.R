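#' Mean signal per fixed non-overlapping window
#'
#' Averages a binned track over consecutive non-overlapping windows
#' (complete windows only). Windows with fewer than `min_frac` of their bins
#' unmasked are dropped.
#'
#' @param track A [binned_track()].
#' @param window Window size in bp; must be a multiple of the bin size.
#' @param min_frac Minimum usable-bin fraction to keep a window
#'   (default 0.5).
#' @return data.frame with `chrom`, `start`, `end`, `mean`,
#'   `n_bins_used`.
#' @export
window_signal <- function(track, window = 1e6, min_frac = 0.5) {
  k <- window / track$bin_size
  if (k != round(k) || k < 1)
    stop("window must be a positive multiple of bin_size")
  k <- as.integer(k)
  len <- chrom_lengths(track$genome)
  rows <- list()
  for (ch in track$genome$chrom$chrom) {
    v <- track$values[[ch]]
    m <- track$mask[[ch]] & !is.na(v)
    nw <- floor(length(v) / k)
    # the trailing partial window (if any) is dropped
    if (nw < 1) next
    idx <- seq_len(nw * k)
    wi <- rep(seq_len(nw), each = k)
    used <- tapply(m[idx], wi, sum)
    sums <- tapply(ifelse(m[idx], v[idx], 0), wi, sum)
    keep <- used >= min_frac * k
    if (!any(keep)) next
    wstart <- (which(keep) - 1) * window
    rows[[ch]] <- data.frame(
      chrom = ch, start = wstart, end = wstart + window,
      mean = (sums / used)[keep], n_bins_used = as.integer(used[keep]),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               mean = numeric(), n_bins_used = integer())
  rownames(out) <- NULL
  out
}

#' Windowed correlation of representation against a signal track
#'
#' Pearson correlation (two-sided p) between per-window means of a
#' normalized log2-ratio representation track and any signal track
#' (histone-mark fold enrichment, replication timing, ...), over windows
#' usable on both sides. The paired window values are returned for
#' scatter/lowess plotting downstream.
#'
#' @param representation,signal [binned_track()]s on one genome.
#' @param window Window size in bp (default 1 Mb).
#' @param min_frac Passed to [window_signal()].
#' @return List with `r`, `p_value`, `n_windows`, and `windows` (data.frame
#'   `chrom`, `start`, `representation`, `signal`).
#' @export
correlation_profile <- function(representation, signal, window = 1e6,
                                min_frac = 0.5) {
  if (!identical(representation$genome$chrom, signal$genome$chrom))
    stop("tracks are on different genomes")
  a <- window_signal(representation, window, min_frac)
  b <- window_signal(signal, window, min_frac)
  key_a <- paste(a$chrom, a$start)
  key_b <- paste(b$chrom, b$start)
  common <- intersect(key_a, key_b)
  if (length(common) < 10)
    stop(sprintf("only %d usable windows; need >= 10", length(common)))
  ia <- match(common, key_a); ib <- match(common, key_b)
  pairs <- data.frame(chrom = a$chrom[ia], start = a$start[ia],
                      representation = a$mean[ia], signal = b$mean[ib],
                      stringsAsFactors = FALSE)
  ct <- stats::cor.test(pairs$representation, pairs$signal,
                        method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n_windows = nrow(pairs), windows = pairs)
}

## ---- two-state replication-timing segmentation ---------------------------

segment_one <- function(v, penalty) {
  # recursive binary segmentation on a numeric vector (NAs ignored in cost);
  # returns integer breakpoints (last bin of each segment except the final)
  n <- length(v)
  ok <- !is.na(v)
  sse <- function(from, to) {
    x <- v[from:to]; x <- x[!is.na(x)]
    if (length(x) < 2) return(0)
    sum((x - mean(x))^2)
  }
  best_split <- function(from, to) {
    x <- v[from:to]
    use <- !is.na(x)
    if (sum(use) < 4) return(NULL)
    x0 <- ifelse(use, x, 0)
    cs <- cumsum(x0); cs2 <- cumsum(x0^2); cn <- cumsum(use)
    tot_s <- cs[length(x)]; tot_s2 <- cs2[length(x)]; tot_n <- cn[length(x)]
    m <- length(x) - 1
    i <- seq_len(m)
    nl <- cn[i]; nr <- tot_n - nl
    valid <- nl >= 1 & nr >= 1
    sl <- cs[i]; sr <- tot_s - sl
    s2l <- cs2[i]; s2r <- tot_s2 - s2l
    cost <- (s2l - sl^2 / pmax(nl, 1)) + (s2r - sr^2 / pmax(nr, 1))
    cost[!valid] <- Inf
    j <- which.min(cost)
    list(at = from + j - 1L, cost = cost[j],
         cost0 = tot_s2 - tot_s^2 / tot_n)
  }
  breaks <- integer()
  recurse <- function(from, to) {
    sp <- best_split(from, to)
    if (is.null(sp)) return()
    if (sp$cost0 - sp$cost > penalty) {
      breaks <<- c(breaks, sp$at)
      recurse(from, sp$at)
      recurse(sp$at + 1L, to)
    }
  }
  if (any(ok)) recurse(1L, n)
  sort(breaks)
}

#' Segment a replication-timing track into early/late domains
#'
#' Recursive binary segmentation minimizing within-segment squared error: a
#' split is accepted when it reduces the squared error by more than a
#' BIC-like per-breakpoint penalty (default `2 * sigma^2 * log(n)` with
#' `sigma` the robust SD of successive bin differences divided by
#' `sqrt(2)`). Adjacent segments with the same state are merged, so segments
#' tile each analyzed chromosome, alternate in state, and the procedure is
#' idempotent on its own piecewise-constant reconstruction. Early means
#' positive timing values, late negative (`state = early` iff the segment's
#' mean timing > 0). Deterministic. All-masked chromosomes are skipped.
#'
#' @param timing A [binned_track()] of kind `timing` (early > 0, late < 0).
#' @param penalty Per-breakpoint penalty; `NULL` for the default.
#' @return data.frame of class `timing_segments`: `chrom`, `start`, `end`,
#'   `n_bins`, `state` (`"early"`/`"late"`), `mean_timing`.
#' @export
segment_timing <- function(timing, penalty = NULL) {
  rows <- list()
  for (ch in timing$genome$chrom$chrom) {
    v <- timing$values[[ch]]
    v[!timing$mask[[ch]]] <- NA
    if (all(is.na(v))) {
      message(sprintf("segment_timing: %s fully masked, skipped", ch))
      next
    }
    if (is.null(penalty)) {
      d <- diff(v[!is.na(v)])
      sig <- stats::mad(d) / sqrt(2)
      if (!is.finite(sig) || sig == 0) sig <- stats::sd(d) / sqrt(2)
      if (!is.finite(sig) || sig == 0) sig <- 1e-8
      pen <- 2 * sig^2 * log(sum(!is.na(v)))
    } else pen <- penalty
    breaks <- segment_one(v, pen)
    bounds <- c(0L, breaks, length(v))
    seg <- data.frame(from = bounds[-length(bounds)] + 1L,
                      to = bounds[-1])
    seg$mean <- vapply(seq_len(nrow(seg)), function(i)
      mean(v[seg$from[i]:seg$to[i]], na.rm = TRUE), 0)
    seg$state <- ifelse(seg$mean > 0, "early", "late")
    # merge adjacent same-state segments (maximal same-state segments)
    i <- 1L
    while (i < nrow(seg)) {
      if (identical(seg$state[i], seg$state[i + 1L])) {
        seg$to[i] <- seg$to[i + 1L]
        seg$mean[i] <- mean(v[seg$from[i]:seg$to[i]], na.rm = TRUE)
        seg <- seg[-(i + 1L), , drop = FALSE]
      } else i <- i + 1L
    }
    iv <- bins_to_interval(ch, seg$from, seg$to, timing$bin_size,
                           timing$genome)
    rows[[ch]] <- data.frame(chrom = ch, start = iv$start, end = iv$end,
                             n_bins = seg$to - seg$from + 1L,
                             state = seg$state, mean_timing = seg$mean,
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_bins = integer(), state = character(),
               mean_timing = numeric())
  rownames(out) <- NULL
  class(out) <- c("timing_segments", "data.frame")
  out
}

#' Containment of UR domains within late-replicating segments
#'
#' For each domain, the late segment that contains it (containment = the
#' domain lies inside the segment up to `tolerance_bp` at each side; the
#' strict zero-tolerance count is also reported). For each late segment:
#' size, whether it hosts a domain, gene count and mean timing; hosting and
#' non-hosting late segments are compared by two-sided rank-sum tests on
#' size, gene count and timing.
#'
#' @param domains Interval data.frame of UR domains.
#' @param segments A [segment_timing()] result.
#' @param genes Interval data.frame of gene annotations.
#' @param tolerance_bp Containment slack in bp per side (default one 5 kb
#'   bin).
#' @param alpha Significance level for the comparisons (default 0.01).
#' @return List of class `late_region_report`: `domains` (per-domain
#'   containment), `late_segments` (per-segment stats),
#'   `containment_fraction`, `strict_containment_fraction`, and
#'   `comparisons` (size/genes/timing rank-sum results).
#' @export
late_region_analysis <- function(domains, segments, genes,
                                 tolerance_bp = 5000, alpha = 0.01) {
  late <- segments[segments$state == "late", , drop = FALSE]
  dom <- as.data.frame(domains)
  contained <- logical(nrow(dom))
  strict <- logical(nrow(dom))
  host_idx <- rep(NA_integer_, nrow(dom))
  for (i in seq_len(nrow(dom))) {
    cand <- which(late$chrom == dom$chrom[i] &
                    late$start - tolerance_bp <= dom$start[i] &
                    late$end + tolerance_bp >= dom$end[i])
    if (!length(cand)) {
      if (!any(segments$chrom == dom$chrom[i]))
        warning(sprintf("domain %s:%g-%g on a chromosome without segments",
                        dom$chrom[i], dom$start[i], dom$end[i]))
      next
    }
    # prefer the segment with the largest overlap
    ov <- pmin(late$end[cand], dom$end[i]) - pmax(late$start[cand],
                                                  dom$start[i])
    host_idx[i] <- cand[which.max(ov)]
    contained[i] <- TRUE
    strict[i] <- late$start[host_idx[i]] <= dom$start[i] &&
      late$end[host_idx[i]] >= dom$end[i]
  }
  late$size <- late$end - late$start
  late$hosts_domain <- seq_len(nrow(late)) %in% host_idx[!is.na(host_idx)]
  late$n_genes <- if (nrow(genes)) vapply(seq_len(nrow(late)), function(i)
    sum(genes$chrom == late$chrom[i] & genes$start < late$end[i] &
          genes$end > late$start[i]), 0L) else rep(0L, nrow(late))
  cmp <- list()
  if (any(late$hosts_domain) && any(!late$hosts_domain)) {
    h <- late[late$hosts_domain, ]; nh <- late[!late$hosts_domain, ]
    cmp$size <- compare_groups(h$size, nh$size, alpha)
    cmp$n_genes <- compare_groups(h$n_genes, nh$n_genes, alpha)
    cmp$mean_timing <- compare_groups(h$mean_timing, nh$mean_timing, alpha)
  }
  structure(list(
    domains = data.frame(dom[c("chrom", "start", "end")],
                         contained = contained, strict = strict,
                         host_segment = host_idx),
    late_segments = late,
    containment_fraction = if (nrow(dom)) mean(contained) else NA_real_,
    strict_containment_fraction = if (nrow(dom)) mean(strict) else NA_real_,
    comparisons = cmp), class = "late_region_report")
}

#' @export
print.late_region_report <- function(x, ...) {
  cat(sprintf("late-region containment: %d/%d domains (%.0f%%; strict %.0f%%)\n",
              sum(x$domains$contained), nrow(x$domains),
              100 * x$containment_fraction,
              100 * x$strict_containment_fraction))
  cat(sprintf("late segments: %d hosting, %d non-hosting\n",
              sum(x$late_segments$hosts_domain),
              sum(!x$late_segments$hosts_domain)))
  for (nm in names(x$comparisons)) {
    cc <- x$comparisons[[nm]]
    cat(sprintf("  %s: median %.3g (hosting) vs %.3g (non-hosting), p = %.3g%s\n",
                nm, cc$median_a, cc$median_b, cc$p_value,
                if (cc$significant) " *" else ""))
  }
  invisible(x)
}

#' Join gene expression with representation and domain membership
#'
#' For each gene: its mean representation (normalized log2) over its extent,
#' whether it lies in a UR domain (>= 1 bp overlap), and its normalized
#' expression. Summarized as the in-domain versus out-of-domain median
#' expression with a rank-sum p. Genes absent from the expression table are
#' excluded and counted.
#'
#' @param expression data.frame with `gene_id` and `expression` columns.
#' @param genes Interval data.frame with a `gene_id` column.
#' @param representation Normalized log2-ratio [binned_track()].
#' @param domains Interval data.frame of UR domains.
#' @param alpha Significance level (default 0.01).
#' @return List with `table` (per-gene join), `n_unjoined`,
#'   `median_in`, `median_out`, `p_value`.
#' @export
expression_by_domain <- function(expression, genes, representation, domains,
                                 alpha = 0.01) {
  if (!all(c("gene_id", "expression") %in% names(expression)))
    stop("expression needs columns gene_id, expression")
  if (!"gene_id" %in% names(genes))
    stop("genes need a gene_id column")
  idx <- match(genes$gene_id, expression$gene_id)
  n_unjoined <- sum(is.na(idx))
  if (n_unjoined)
    message(sprintf("expression_by_domain: %d genes without expression excluded",
                    n_unjoined))
  g <- as.data.frame(genes)[!is.na(idx), , drop = FALSE]
  expr <- expression$expression[idx[!is.na(idx)]]
  rep_val <- vapply(seq_len(nrow(g)), function(i) {
    s <- try(summarize_domain(g[i, , drop = FALSE], representation),
             silent = TRUE)
    if (inherits(s, "try-error")) NA_real_ else s$mean_log2
  }, 0)
  in_dom <- overlaps_any(g, domains)
  tab <- data.frame(gene_id = g$gene_id, chrom = g$chrom, start = g$start,
                    end = g$end, nlog2 = rep_val, in_domain = in_dom,
                    expression = expr, stringsAsFactors = FALSE)
  p <- if (any(in_dom) && any(!in_dom))
    compare_groups(expr[in_dom], expr[!in_dom], alpha)$p_value else NA_real_
  list(table = tab, n_unjoined = n_unjoined,
       median_in = if (any(in_dom)) stats::median(expr[in_dom]) else NA_real_,
       median_out = if (any(!in_dom)) stats::median(expr[!in_dom])
         else NA_real_,
       p_value = p)
}
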