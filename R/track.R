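#' Construct a fixed-width binned track
#'
#' A binned track holds one value per fixed-width bin along each chromosome of
#' a genome, plus a per-bin usability mask. The last bin of a chromosome may
#' be partial; there are `ceiling(length / bin_size)` bins per chromosome.
#' Masked bins are excluded from every statistic the package computes.
#'
#' @param genome A [genome()] object.
#' @param bin_size Bin width in bp (> 0).
#' @param values Named list (one numeric vector per chromosome) or a single
#'   value to fill with; lengths must equal the bin count per chromosome.
#' @param mask Named list of logical vectors (`TRUE` = usable) or `NULL` for
#'   all usable.
#' @param kind One of `"raw-count"`, `"normalized-log2-ratio"`,
#'   `"fold-enrichment"`, `"timing"`.
#' @return Object of class `binned_track`.
#' @export
binned_track <- function(genome, bin_size, values = 0, mask = NULL,
                         kind = c("raw-count", "normalized-log2-ratio",
                                  "fold-enrichment", "timing")) {
  kind <- match.arg(kind)
  if (bin_size <= 0) stop("bin_size must be positive")
  nb <- n_bins(genome, bin_size)
  chroms <- genome$chrom$chrom
  if (!is.list(values))
    values <- stats::setNames(lapply(nb, function(n) rep(values, n)), chroms)
  if (is.null(mask))
    mask <- stats::setNames(lapply(nb, function(n) rep(TRUE, n)), chroms)
  if (!setequal(names(values), chroms) || !setequal(names(mask), chroms))
    stop("values/mask must be named by the genome's chromosomes")
  for (ch in chroms) {
    if (length(values[[ch]]) != nb[[ch]] || length(mask[[ch]]) != nb[[ch]])
      stop(sprintf("wrong number of bins for %s (expected %d)", ch, nb[[ch]]))
  }
  structure(list(genome = genome, bin_size = bin_size,
                 values = values[chroms], mask = mask[chroms], kind = kind),
            class = "binned_track")
}

n_bins <- function(genome, bin_size) {
  stats::setNames(as.integer(ceiling(genome$chrom$length / bin_size)),
                  genome$chrom$chrom)
}

#' @export
print.binned_track <- function(x, ...) {
  tot <- sum(vapply(x$values, length, 0L))
  used <- sum(vapply(x$mask, sum, 0L))
  cat(sprintf("<binned_track [%s]: %d bins of %s bp (%d usable) on '%s'>\n",
              x$kind, tot, format(x$bin_size, big.mark = ","), used,
              x$genome$name))
  invisible(x)
}

#' Unmasked values of a track as one vector
#' @param track A [binned_track()].
#' @export
track_values <- function(track) {
  unlist(lapply(track$genome$chrom$chrom, function(ch)
    track$values[[ch]][track$mask[[ch]]]), use.names = FALSE)
}

#' Bin fragment intervals into raw counts
#'
#' Each fragment is counted exactly once, in the bin containing its midpoint
#' (a fragment straddling a bin boundary goes to the midpoint's bin only).
#' Fragments on chromosomes not in the genome are skipped and tallied.
#'
#' @param fragments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open); e.g. fragment BED intervals.
#' @param genome A [genome()] object.
#' @param bin_size Bin width in bp.
#' @return A `binned_track` of kind `raw-count`, with attribute
#'   `n_skipped` giving the number of fragments on unknown chromosomes.
#' @examples
#' g <- genome("chr1", 25e3)
#' f <- data.frame(chrom = "chr1", start = c(0, 100, 12000),
#'                 end = c(200, 300, 12100))
#' bin_counts(f, g, 5000)$values$chr1
#' @export
bin_counts <- function(fragments, genome, bin_size) {
  if (bin_size <= 0) stop("bin_size must be positive")
  nb <- n_bins(genome, bin_size)
  chroms <- genome$chrom$chrom
  vals <- stats::setNames(lapply(nb, function(n) numeric(n)), chroms)
  skipped <- 0L
  if (nrow(fragments)) {
    known <- fragments$chrom %in% chroms
    skipped <- sum(!known)
    if (skipped) {
      message(sprintf("bin_counts: skipped %d fragments on unknown chromosomes",
                      skipped))
      fragments <- fragments[known, , drop = FALSE]
    }
    if (nrow(fragments)) {
      mid <- (fragments$start + fragments$end) / 2
      bin <- pmin(floor(mid / bin_size) + 1L, nb[fragments$chrom])
      for (ch in unique(fragments$chrom)) {
        sel <- fragments$chrom == ch
        tab <- tabulate(bin[sel], nbins = nb[[ch]])
        vals[[ch]] <- vals[[ch]] + tab
      }
    }
  }
  out <- binned_track(genome, bin_size, values = vals, kind = "raw-count")
  attr(out, "n_skipped") <- skipped
  out
}

#' Estimate fold coverage of a sequencing library
#'
#' Fold coverage = read length x mapped reads / haploid genome size. The
#' mouse haploid genome is taken as 2.7e9 bp when only a genome label is
#' known; pass a [genome()] to use its actual size.
#'
#' @param total_mapped_reads Number of mapped reads.
#' @param read_length Read length in bp (default 101).
#' @param genome A [genome()] object or a genome size in bp (default 2.7e9).
#' @return Fold coverage (numeric scalar).
#' @examples
#' estimate_coverage(2.7e7, 101)  # ~1.01x on a 2.7 Gb genome
#' @export
estimate_coverage <- function(total_mapped_reads, read_length = 101,
                              genome = 2.7e9) {
  if (read_length <= 0) stop("read_length must be positive")
  if (total_mapped_reads < 0) stop("total_mapped_reads must be >= 0")
  gsize <- if (inherits(genome, "genome")) genome_size(genome) else genome
  read_length * total_mapped_reads / gsize
}

#' Normalized log2 ratio track of test over control counts
#'
#' Per bin i, `r_i = log2(((t_i + pseudocount)/T) / ((c_i + pseudocount)/C))`
#' with T and C the total counts over unmasked bins (library-size scaling),
#' after which the genome-wide median over unmasked bins is subtracted so the
#' neutral state is exactly 0. Bins with control counts below `min_control`
#' are masked before any statistic is computed (ratio explosions in
#' unmappable bins). The result is invariant to scaling all test counts by a
#' constant.
#'
#' @param test,control `binned_track`s of kind `raw-count` on the same genome
#'   and bin grid.
#' @param min_control Minimum control count for a usable bin (>= 1).
#' @param pseudocount Added to both counts before forming the ratio.
#' @return A `binned_track` of kind `normalized-log2-ratio`.
#' @export
log2_ratio_track <- function(test, control, min_control = 10,
                             pseudocount = 1) {
  stopifnot(inherits(test, "binned_track"), inherits(control, "binned_track"))
  if (min_control < 1) stop("min_control must be >= 1")
  if (test$bin_size != control$bin_size ||
      !identical(test$genome$chrom, control$genome$chrom))
    stop("test and control are on different bin grids")
  chroms <- test$genome$chrom$chrom
  mask <- stats::setNames(lapply(chroms, function(ch)
    test$mask[[ch]] & control$mask[[ch]] &
      control$values[[ch]] >= min_control), chroms)
  tot_t <- sum(unlist(lapply(chroms, function(ch)
    test$values[[ch]][mask[[ch]]])))
  tot_c <- sum(unlist(lapply(chroms, function(ch)
    control$values[[ch]][mask[[ch]]])))
  if (tot_t <= 0 || tot_c <= 0) stop("no usable counts in test or control")
  vals <- stats::setNames(lapply(chroms, function(ch) {
    r <- log2(((test$values[[ch]] + pseudocount) / tot_t) /
                ((control$values[[ch]] + pseudocount) / tot_c))
    r[!mask[[ch]]] <- NA_real_
    r
  }), chroms)
  med <- stats::median(unlist(lapply(chroms, function(ch)
    vals[[ch]][mask[[ch]]])))
  vals <- lapply(vals, function(v) v - med)
  binned_track(test$genome, test$bin_size, values = vals, mask = mask,
               kind = "normalized-log2-ratio")
}

#' Interval spanned by a run of bins
#'
#' Converts 1-based bin indices `[from, to]` on a chromosome into a 0-based
#' half-open genomic interval, clipped to the chromosome end.
#' @keywords internal
bins_to_interval <- function(chrom, from, to, bin_size, genome) {
  len <- chrom_lengths(genome)[[chrom]]
  as_intervals(chrom, (from - 1) * bin_size, pmin(to * bin_size, len))
}

#' Bin index range overlapped by an interval
#' @keywords internal
interval_to_bins <- function(interval, bin_size, genome) {
  nb <- n_bins(genome, bin_size)[[interval$chrom[1]]]
  from <- floor(interval$start[1] / bin_size) + 1L
  to <- min(as.integer(ceiling(interval$end[1] / bin_size)), nb)
  c(from = from, to = to)
}

#' Write a track as bedGraph
#'
#' Unmasked bins only; values printed at full precision. A provenance comment
#' header records the track kind and bin size.
#'
#' @param track A [binned_track()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# urdomains bedGraph kind=%s bin_size=%d",
                     track$kind, as.integer(track$bin_size)), con)
  len <- chrom_lengths(track$genome)
  for (ch in track$genome$chrom$chrom) {
    v <- track$values[[ch]]
    use <- track$mask[[ch]] & !is.na(v)
    if (!any(use)) next
    idx <- which(use)
    starts <- (idx - 1) * track$bin_size
    ends <- pmin(idx * track$bin_size, len[[ch]])
    writeLines(sprintf("%s\t%s\t%s\t%.10g", ch,
                       format(starts, scientific = FALSE, trim = TRUE),
                       format(ends, scientific = FALSE, trim = TRUE),
                       v[idx]), con)
  }
  invisible(path)
}

#' Read a bedGraph produced on a known bin grid into a track
#'
#' Bins not present in the file are masked.
#'
#' @param path bedGraph path (4 columns, 0-based half-open).
#' @param genome A [genome()] object.
#' @param bin_size Bin width the file was written on.
#' @param kind Track kind, see [binned_track()].
#' @export
read_bedgraph <- function(path, genome, bin_size, kind = "raw-count") {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track)", lines) & nzchar(lines)]
  nb <- n_bins(genome, bin_size)
  chroms <- genome$chrom$chrom
  vals <- stats::setNames(lapply(nb, function(n) rep(NA_real_, n)), chroms)
  mask <- stats::setNames(lapply(nb, function(n) rep(FALSE, n)), chroms)
  if (length(lines)) {
    f <- strsplit(lines, "\t", fixed = TRUE)
    ch <- vapply(f, `[[`, "", 1L)
    st <- as.numeric(vapply(f, `[[`, "", 2L))
    vv <- as.numeric(vapply(f, `[[`, "", 4L))
    keep <- ch %in% chroms
    ch <- ch[keep]; st <- st[keep]; vv <- vv[keep]
    bin <- floor(st / bin_size) + 1L
    for (c2 in unique(ch)) {
      sel <- ch == c2
      vals[[c2]][bin[sel]] <- vv[sel]
      mask[[c2]][bin[sel]] <- TRUE
    }
  }
  vals <- lapply(vals, function(v) { v[is.na(v)] <- 0; v })
  binned_track(genome, bin_size, values = vals, mask = mask, kind = kind)
}
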