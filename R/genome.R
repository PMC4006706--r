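#' Define a genome as an ordered set of chromosomes
#'
#' A genome is the coordinate system every other object in the package is
#' anchored to: an ordered list of uniquely named chromosomes with positive
#' lengths. All coordinates in the package are 0-based half-open (BED-like),
#' so an interval of size `s` satisfies `end - start == s`.
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length Integer vector of chromosome lengths in bp (positive).
#' @param name Label for the genome assembly (e.g. `"mm9"`).
#' @return An object of class `genome`: a list with elements `name` and
#'   `chrom` (a data.frame with columns `chrom`, `length`).
#' @examples
#' g <- genome(c("chr1", "chr2"), c(60e6, 60e6), name = "toy")
#' chrom_lengths(g)
#' @export
genome <- function(chrom, length, name = "genome") {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length))
    stop("'chrom' and 'length' must have the same length")
  if (anyDuplicated(chrom))
    stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("chromosome lengths must be positive")
  structure(list(name = name,
                 chrom = data.frame(chrom = chrom, length = length,
                                    stringsAsFactors = FALSE)),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome '%s': %d chromosomes, %.1f Mb>\n", x$name,
              nrow(x$chrom), sum(x$chrom$length) / 1e6))
  invisible(x)
}

#' Named vector of chromosome lengths
#' @param genome A [genome()] object.
#' @return Named numeric vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(genome$chrom$length, genome$chrom$chrom)
}

#' Total genome size in bp
#' @param genome A [genome()] object.
#' @export
genome_size <- function(genome) sum(genome$chrom$length)

#' Read a two-column chromosome-sizes file
#'
#' @param path Path to a TSV with columns name, length (no header).
#' @param name Genome label.
#' @return A [genome()] object.
#' @export
read_chrom_sizes <- function(path, name = basename(path)) {
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "length"))
  genome(x$chrom, x$length, name = name)
}

#' Normalize chromosome naming to one convention
#'
#' Accepts both `"chr1"` and `"1"` style names and maps them onto the naming
#' used by the bound genome, so interval sets from mixed sources can be
#' combined.
#'
#' @param chrom Character vector of chromosome names.
#' @param genome A [genome()] object giving the target convention.
#' @return Character vector of normalized names (unknown names unchanged).
#' @export
normalize_chrom <- function(chrom, genome) {
  chrom <- as.character(chrom)
  known <- genome$chrom$chrom
  bare <- sub("^chr", "", chrom)
  out <- chrom
  miss <- !(out %in% known)
  if (any(miss)) {
    cand <- paste0("chr", bare[miss])
    hit <- cand %in% known
    out[miss][hit] <- cand[hit]
  }
  miss <- !(out %in% known)
  if (any(miss)) {
    hit <- bare[miss] %in% known
    out[miss][hit] <- bare[miss][hit]
  }
  out
}

## ---- interval data.frames -------------------------------------------------

as_intervals <- function(chrom, start, end, ...) {
  data.frame(chrom = as.character(chrom), start = as.numeric(start),
             end = as.numeric(end), ..., stringsAsFactors = FALSE)
}

#' Validate an interval data.frame against a genome
#'
#' Intervals are plain data.frames with columns `chrom`, `start`, `end`
#' (0-based half-open). Validation checks `0 <= start < end <= chromosome
#' length` and, when a genome is supplied, that every interval lies on a known
#' chromosome.
#'
#' @param x data.frame with columns `chrom`, `start`, `end`.
#' @param genome Optional [genome()] object.
#' @return `x`, invisibly, after checks.
#' @export
validate_intervals <- function(x, genome = NULL) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x)))
    stop("intervals need columns chrom, start, end")
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$start < 0) || any(x$end <= x$start)) {
    bad <- which(x$start < 0 | x$end <= x$start)[1]
    stop(sprintf("invalid interval at row %d: start=%s end=%s",
                 bad, format(x$start[bad]), format(x$end[bad])))
  }
  if (!is.null(genome)) {
    len <- chrom_lengths(genome)
    unknown <- !(x$chrom %in% names(len))
    if (any(unknown))
      stop(sprintf("interval on unknown chromosome '%s' (row %d)",
                   x$chrom[which(unknown)[1]], which(unknown)[1]))
    over <- x$end > len[x$chrom]
    if (any(over))
      stop(sprintf("interval off chromosome end at row %d (%s:%s-%s)",
                   which(over)[1], x$chrom[which(over)[1]],
                   format(x$start[which(over)[1]]),
                   format(x$end[which(over)[1]])))
  }
  invisible(x)
}

#' Sort intervals canonically
#'
#' Sorts by chromosome (genome order when supplied, else lexicographic), then
#' start, then end.
#'
#' @inheritParams validate_intervals
#' @return The sorted data.frame.
#' @export
sort_intervals <- function(x, genome = NULL) {
  if (nrow(x) == 0) return(x)
  if (!is.null(genome)) {
    key <- match(x$chrom, genome$chrom$chrom)
  } else {
    key <- x$chrom
  }
  x[order(key, x$start, x$end), , drop = FALSE]
}

#' Sort and merge intervals, fusing those separated by at most a gap
#'
#' Any two intervals on the same chromosome whose separation is `<= gap` bp
#' (abutting half-open intervals have separation 0) are fused into one.
#' Covered bases are conserved or grown only by the bridged gaps.
#'
#' @inheritParams validate_intervals
#' @param gap Non-negative separation (bp) up to which intervals are fused.
#' @return data.frame of sorted, non-overlapping merged intervals.
#' @examples
#' sort_and_merge(data.frame(chrom = "chr1", start = c(0, 10), end = c(10, 20)))
#' @export
sort_and_merge <- function(x, gap = 0, genome = NULL) {
  stopifnot(gap >= 0)
  validate_intervals(x, genome)
  if (nrow(x) == 0)
    return(as_intervals(character(), numeric(), numeric()))
  x <- sort_intervals(x[c("chrom", "start", "end")], genome)
  # running merge: an interval starts a new block unless it is on the same
  # chromosome and starts within `gap` of the running maximum end
  chrom_out <- character(0); start_out <- numeric(0); end_out <- numeric(0)
  cur_chrom <- x$chrom[1]; cur_start <- x$start[1]; cur_end <- x$end[1]
  if (nrow(x) > 1) {
    for (i in 2:nrow(x)) {
      if (x$chrom[i] == cur_chrom && x$start[i] <= cur_end + gap) {
        cur_end <- max(cur_end, x$end[i])
      } else {
        chrom_out <- c(chrom_out, cur_chrom)
        start_out <- c(start_out, cur_start)
        end_out <- c(end_out, cur_end)
        cur_chrom <- x$chrom[i]; cur_start <- x$start[i]; cur_end <- x$end[i]
      }
    }
  }
  chrom_out <- c(chrom_out, cur_chrom)
  start_out <- c(start_out, cur_start)
  end_out <- c(end_out, cur_end)
  as_intervals(chrom_out, start_out, end_out)
}

#' Overlap length of two intervals
#'
#' @param a,b Single-row interval data.frames or lists with `chrom`, `start`,
#'   `end`.
#' @return Overlap in bp; 0 when disjoint or on different chromosomes.
#' @export
overlap_length <- function(a, b) {
  if (a$chrom[1] != b$chrom[1]) return(0)
  max(0, min(a$end[1], b$end[1]) - max(a$start[1], b$start[1]))
}

#' Per-query total overlap with a merged subject set
#'
#' For each interval in `query`, the number of its bases covered by the union
#' of `subject`.
#'
#' @param query,subject Interval data.frames.
#' @return Numeric vector, one value per row of `query`.
#' @export
interval_overlap_bp <- function(query, subject) {
  if (nrow(query) == 0) return(numeric())
  if (nrow(subject) == 0) return(rep(0, nrow(query)))
  subj <- sort_and_merge(subject)
  out <- numeric(nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    s <- subj[subj$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0) next
    for (j in qi) {
      out[j] <- sum(pmax(0, pmin(query$end[j], s$end) -
                            pmax(query$start[j], s$start)))
    }
  }
  out
}

#' Do intervals overlap a merged subject set?
#'
#' @inheritParams interval_overlap_bp
#' @param min_overlap Minimum overlap in bp to count (default 1).
#' @return Logical vector per row of `query`.
#' @export
overlaps_any <- function(query, subject, min_overlap = 1) {
  interval_overlap_bp(query, subject) >= min_overlap
}

#' Intersection of two interval sets
#' @param x,y Interval data.frames.
#' @return Merged data.frame of the bases present in both sets.
#' @export
intersect_intervals <- function(x, y) {
  x <- sort_and_merge(x); y <- sort_and_merge(y)
  pieces <- list()
  for (ch in intersect(unique(x$chrom), unique(y$chrom))) {
    a <- x[x$chrom == ch, ]; b <- y[y$chrom == ch, ]
    for (i in seq_len(nrow(a))) {
      s <- pmax(a$start[i], b$start); e <- pmin(a$end[i], b$end)
      keep <- e > s
      if (any(keep))
        pieces[[length(pieces) + 1L]] <- as_intervals(ch, s[keep], e[keep])
    }
  }
  if (!length(pieces)) return(as_intervals(character(), numeric(), numeric()))
  sort_and_merge(do.call(rbind, pieces))
}

#' Subtract one interval set from another
#' @param x,y Interval data.frames; returns bases of `x` not covered by `y`.
#' @export
subtract_intervals <- function(x, y) {
  x <- sort_and_merge(x); y <- sort_and_merge(y)
  pieces <- list()
  for (i in seq_len(nrow(x))) {
    ch <- x$chrom[i]
    cur_s <- x$start[i]; cur_e <- x$end[i]
    b <- y[y$chrom == ch & y$end > cur_s & y$start < cur_e, , drop = FALSE]
    pos <- cur_s
    if (nrow(b)) {
      for (j in seq_len(nrow(b))) {
        if (b$start[j] > pos)
          pieces[[length(pieces) + 1L]] <- as_intervals(ch, pos, b$start[j])
        pos <- max(pos, b$end[j])
      }
    }
    if (pos < cur_e)
      pieces[[length(pieces) + 1L]] <- as_intervals(ch, pos, cur_e)
  }
  if (!length(pieces)) return(as_intervals(character(), numeric(), numeric()))
  sort_and_merge(do.call(rbind, pieces))
}

## ---- feature sets ---------------------------------------------------------

#' Bundle intervals into a named feature set
#'
#' A feature set is an interval data.frame carrying a name and (optionally) a
#' bound genome; extra columns (gene id, strand, TSS position, ...) ride
#' along. Intervals are sorted canonically on construction.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and any extra
#'   columns.
#' @param name Label for the set.
#' @param genome Optional [genome()] to validate against and bind.
#' @return The sorted data.frame with class `feature_set` and attributes
#'   `set_name` and `genome`.
#' @export
feature_set <- function(intervals, name = "features", genome = NULL) {
  validate_intervals(intervals, genome)
  x <- sort_intervals(intervals, genome)
  rownames(x) <- NULL
  attr(x, "set_name") <- name
  attr(x, "genome") <- genome
  class(x) <- c("feature_set", "data.frame")
  x
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set '%s': %d intervals on %d chromosomes>\n",
              attr(x, "set_name"), nrow(x), length(unique(x$chrom))))
  NextMethod()
}

## ---- readers / writers ----------------------------------------------------

#' Read intervals from BED or TSV
#'
#' BED input is 0-based half-open (columns chrom, start, end, then optionally
#' name, score, strand). A 1-based fully-closed dialect (common in printed
#' coordinate tables) is converted by `one_based = TRUE`, which subtracts 1
#' from starts. Malformed lines and `end <= start` raise errors naming the
#' offending line.
#'
#' @param path File path.
#' @param format `"bed"` or `"tsv"`; `"tsv"` expects a header line.
#' @param one_based Input uses 1-based inclusive starts; convert on load.
#' @param genome Optional [genome()]; chromosome names are normalized to its
#'   convention and coordinates validated.
#' @param name Feature-set label (defaults to file name).
#' @return A [feature_set()].
#' @export
read_intervals <- function(path, format = c("bed", "tsv"), one_based = FALSE,
                           genome = NULL, name = basename(path)) {
  format <- match.arg(format)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (format == "tsv" && length(lines)) {
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    lines <- lines[-1]
    lineno <- lineno[-1]
  } else {
    header <- NULL
  }
  if (!length(lines)) {
    return(feature_set(as_intervals(character(), numeric(), numeric()),
                       name = name, genome = genome))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop(sprintf("malformed line %d in %s: fewer than 3 fields",
                 lineno[which(nf < 3)[1]], path))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop(sprintf("malformed line %d in %s: non-numeric coordinate",
                 lineno[which(is.na(start) | is.na(end))[1]], path))
  if (one_based) start <- start - 1
  bad <- end <= start
  if (any(bad))
    stop(sprintf("line %d in %s: end <= start", lineno[which(bad)[1]], path))
  x <- as_intervals(chrom, start, end)
  extras <- max(nf) - 3L
  if (extras > 0) {
    ecols <- if (!is.null(header) && length(header) >= 3 + extras) {
      header[4:(3 + extras)]
    } else {
      c("name", "score", "strand", paste0("V", seq_len(max(0, extras - 3))))[
        seq_len(extras)]
    }
    for (k in seq_len(extras)) {
      v <- vapply(fields, function(f) if (length(f) >= 3 + k) f[[3 + k]]
                  else NA_character_, "")
      num <- suppressWarnings(as.numeric(v))
      x[[ecols[k]]] <- if (!anyNA(num[!is.na(v)])) num else v
    }
  }
  if (!is.null(genome)) x$chrom <- normalize_chrom(x$chrom, genome)
  feature_set(x, name = name, genome = genome)
}

#' Write intervals as BED (0-based half-open)
#'
#' Round-trips with [read_intervals()]: writing and re-reading returns the
#' canonical (sorted) form identically.
#'
#' @param x Interval data.frame or [feature_set()].
#' @param path Output path.
#' @param extra_cols Extra columns to carry after chrom/start/end.
#' @export
write_intervals <- function(x, path, extra_cols = NULL) {
  cols <- c("chrom", "start", "end", intersect(extra_cols, names(x)))
  out <- as.data.frame(x)[cols]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- bundled catalogs -----------------------------------------------------

#' Published UR-domain catalog for e9.5 mouse TGCs
#'
#' The 47 underrepresented domains identified on the autosomes of e9.5 mouse
#' parietal trophoblast giant cells by whole-genome sequencing against matched
#' diploid embryos (mm9 coordinates, 0-based half-open), with their
#' across-sample mean and median normalized log2 coverage ratios and the
#' corresponding integer percent depletions.
#'
#' @return data.frame with columns `chrom`, `start`, `end`, `size`,
#'   `mean_log2`, `pct_depl_mean`, `median_log2`, `pct_depl_median`,
#'   `acgh_weak`.
#' @examples
#' cat47 <- ur_domain_catalog()
#' sum(cat47$size)  # 138,485,000 bp in total
#' @export
ur_domain_catalog <- function() {
  path <- system.file("extdata", "tgc_e95_ur_domain_catalog.tsv",
                      package = "urdomains", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Published histone-mark peak overlap tallies for UR domains
#'
#' Observed versus randomization-expected counts of ChIP-seq peaks (five
#' histone marks in TS cells and in vitro TGCs) overlapping the e9.5 UR
#' domains, with the published two-decimal enrichment ratios.
#'
#' @return data.frame with columns `cell`, `mark`, `mark_class`, `observed`,
#'   `expected`, `enrichment`.
#' @export
histone_mark_overlaps <- function() {
  path <- system.file("extdata", "histone_mark_domain_overlap.tsv",
                      package = "urdomains", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Published gene and gene-desert overlap summaries for UR domains
#'
#' Feature-level observed/expected overlap counts for Ensembl genes and 1 Mb
#' gene deserts, with the published enrichment values.
#'
#' @return data.frame with columns `feature`, `observed`, `expected`,
#'   `published_enrichment`.
#' @export
feature_overlap_summary <- function() {
  path <- system.file("extdata", "feature_overlap_summary.tsv",
                      package = "urdomains", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
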