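#' Configuration for the synthetic-genome generator
#'
#' The generator emulates the statistical structure the analysis assumes: a
#' polyploid/diploid pair of Poisson bin-count tracks with implanted
#' depletion domains (27-54% depletion, 75 kb - 9 Mb, growing with
#' developmental stage), domains hosted inside large gene-poor
#' late-replicating blocks, repressive-mark peaks enriched and active-mark
#' peaks depleted inside domains, near-zero expression of domain genes, and
#' 1 Mb gene-desert tiles concentrated in the hosting blocks.
#'
#' @param n_chromosomes Chromosomes carrying domains (default 2).
#' @param chrom_length Chromosome length in bp (default 60 Mb).
#' @param n_null_chromosomes Extra chromosomes without any implanted domain
#'   (default 0).
#' @param bin_size Bin width in bp (default 5000, the analysis grid).
#' @param lambda Expected control counts per bin (default 500: ~10x
#'   coverage of 101 bp reads on 5 kb bins).
#' @param n_domains Number of implanted UR domains (default 10).
#' @param d_range Depletion range, `d` = fraction of copies missing
#'   (default 0.27-0.54, the reported mean-depletion span).
#' @param size_range Domain size range in bp (default 75 kb - 9 Mb).
#' @param size_meanlog,size_sdlog Log-normal size distribution (truncated
#'   to `size_range`); defaults `log(1e6)` and 0.9 resemble the reported
#'   catalog's spread.
#' @param stage_size_mult,stage_depl_mult Named multipliers applied to
#'   domain extent and depletion for earlier stages (defaults: e9.5 = 1,
#'   e8.0 = 0.6x size and 0.8x depletion).
#' @param host_block_mult Range of the hosting-late-block size as a
#'   multiple of its domain's size (default 2-3: domains strictly inside,
#'   smaller than their blocks).
#' @param nonhost_meanlog,nonhost_sdlog Log-normal size distribution of
#'   late blocks without domains (defaults `log(5e5)`, 0.4: smaller than
#'   hosting blocks).
#' @param n_nonhost_late Non-hosting late blocks (default = `n_domains`).
#' @param gene_density Genes per Mb outside deserts (default 15).
#' @param host_gene_mult Gene-density multiplier inside hosting blocks
#'   (default 0.05: hosting blocks are gene-poor).
#' @param gene_len_meanlog,gene_len_sdlog Log-normal gene length
#'   distribution (defaults `log(2e4)`, 0.8; truncated 1 kb - 200 kb).
#' @param n_desert_tiles 1 Mb zero-gene tiles to designate (default 8).
#' @param frac_desert_in_host Fraction of desert tiles placed inside
#'   hosting blocks (default 0.6).
#' @param timing_early,timing_late,timing_sd Timing-track segment means
#'   and per-bin noise SD (defaults +1, -1, 0.3).
#' @param marks Named list of mark configurations, each a list with
#'   `class` (`"active"`/`"repressive"`), `ratio` (in-domain : out-domain
#'   placement density ratio), `n_peaks` and `peak_len`.
#' @param expr_meanlog,expr_sdlog Expression distribution of genes outside
#'   domains (defaults `log(100)`, 1).
#' @param in_domain_zero_frac,in_domain_expr_meanlog Fraction of in-domain
#'   genes with zero expression (default 0.8) and the low log-mean for the
#'   rest (default `log(2)`).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2, chrom_length = 60e6,
                       n_null_chromosomes = 0, bin_size = 5000,
                       lambda = 500, n_domains = 10,
                       d_range = c(0.27, 0.54),
                       size_range = c(75e3, 9e6),
                       size_meanlog = log(1e6), size_sdlog = 0.9,
                       stage_size_mult = c("e9.5" = 1, "e8.0" = 0.6),
                       stage_depl_mult = c("e9.5" = 1, "e8.0" = 0.8),
                       host_block_mult = c(2, 3),
                       nonhost_meanlog = log(5e5), nonhost_sdlog = 0.4,
                       n_nonhost_late = max(8, n_domains),
                       gene_density = 15, host_gene_mult = 0.05,
                       gene_len_meanlog = log(2e4), gene_len_sdlog = 0.8,
                       n_desert_tiles = 8, frac_desert_in_host = 0.6,
                       timing_early = 1, timing_late = -1, timing_sd = 0.3,
                       marks = list(
                         H3K9me3 = list(class = "repressive", ratio = 1.45,
                                        n_peaks = 2000, peak_len = 1000),
                         H3K27me3 = list(class = "repressive", ratio = 1.36,
                                         n_peaks = 1200, peak_len = 1000),
                         H3K4me3 = list(class = "active", ratio = 0.10,
                                        n_peaks = 1000, peak_len = 1000),
                         H3K27ac = list(class = "active", ratio = 0.10,
                                        n_peaks = 1000, peak_len = 1000)),
                       expr_meanlog = log(100), expr_sdlog = 1,
                       in_domain_zero_frac = 0.8,
                       in_domain_expr_meanlog = log(2)) {
  cfg <- as.list(environment())
  if (cfg$bin_size <= 0 || cfg$chrom_length <= 0 || cfg$lambda <= 0)
    stop("bin_size, chrom_length and lambda must be positive")
  if (cfg$n_domains < 0) stop("n_domains must be >= 0")
  if (any(cfg$d_range <= 0) || any(cfg$d_range >= 1))
    stop("d_range must lie inside (0, 1)")
  class(cfg) <- "sim_config"
  cfg
}

#' Preset for the stage-comparison study
#'
#' A larger synthetic genome (12 chromosomes x 80 Mb, 150 domains with a
#' smaller median size) giving the unpaired rank-sum comparisons of domain
#' size and depletion between stages adequate power at the default 0.6x /
#' 0.8x stage multipliers.
#'
#' @param ... Overrides passed to [sim_config()].
#' @export
sim_config_stage_study <- function(...) {
  sim_config(n_chromosomes = 12, chrom_length = 80e6, n_domains = 150,
             size_meanlog = log(6e5), size_sdlog = 0.9,
             n_nonhost_late = 50, n_desert_tiles = 20, ...)
}

rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

snap <- function(x, unit) round(x / unit) * unit

#' Generate a synthetic genome with ground truth
#'
#' Builds, reproducibly under `seed`: chromosome layout; late-replicating
#' blocks (one large gene-poor hosting block per implanted UR domain, plus
#' smaller non-hosting late blocks) separated by early regions; UR domains
#' strictly inside their hosting blocks, snapped to the bin grid; 1 Mb
#' desert tiles; and genes placed outside deserts, thinned inside hosting
#' blocks.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return List of class `synthetic_truth` with elements `genome`,
#'   `ur_domains` (with depletion `d` per domain), `late_blocks` (with
#'   `hosts_domain`), `genes`, `desert_tiles`, `tss`, `cfg`, `seed`.
#' @export
simulate_reference <- function(cfg = sim_config(), seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(seed)
  n_chr <- cfg$n_chromosomes + cfg$n_null_chromosomes
  chroms <- paste0("chr", seq_len(n_chr))
  g <- genome(chroms, rep(cfg$chrom_length, n_chr), name = "synthetic")
  dom_chroms <- chroms[seq_len(cfg$n_chromosomes)]

  # domain sizes and depths
  dom_size <- snap(rtrunc_lnorm(cfg$n_domains, cfg$size_meanlog,
                                cfg$size_sdlog, cfg$size_range[1],
                                cfg$size_range[2]), cfg$bin_size)
  dom_size <- pmax(dom_size, cfg$size_range[1])
  dom_d <- stats::runif(cfg$n_domains, cfg$d_range[1], cfg$d_range[2])

  # late blocks: one hosting block per domain + non-hosting blocks
  host_size <- snap(dom_size * stats::runif(cfg$n_domains,
                                            cfg$host_block_mult[1],
                                            cfg$host_block_mult[2]),
                    cfg$bin_size)
  nh_size <- snap(rtrunc_lnorm(cfg$n_nonhost_late, cfg$nonhost_meanlog,
                               cfg$nonhost_sdlog, 5 * cfg$bin_size,
                               cfg$chrom_length / 4), cfg$bin_size)
  # assign blocks to chromosomes greedily, largest first onto the least
  # loaded chromosome, so heavy size draws cannot overload one chromosome
  load <- stats::setNames(numeric(length(dom_chroms)), dom_chroms)
  assign_chrom <- function(sizes) {
    out <- character(length(sizes))
    for (i in order(sizes, decreasing = TRUE)) {
      ch <- names(which.min(load))
      out[i] <- ch
      load[[ch]] <<- load[[ch]] + sizes[i]
    }
    out
  }
  dom_chr <- if (cfg$n_domains) assign_chrom(host_size) else character()
  nh_chr <- if (cfg$n_nonhost_late) assign_chrom(nh_size) else character()

  blocks <- rbind(
    if (cfg$n_domains) data.frame(chrom = dom_chr, size = host_size,
                                  hosts_domain = TRUE,
                                  domain_idx = seq_len(cfg$n_domains)),
    if (cfg$n_nonhost_late) data.frame(chrom = nh_chr, size = nh_size,
                                       hosts_domain = FALSE,
                                       domain_idx = NA_integer_))
  late_rows <- list(); dom_rows <- list()
  for (ch in dom_chroms) {
    if (is.null(blocks)) break
    b <- blocks[blocks$chrom == ch, , drop = FALSE]
    if (!nrow(b)) next
    b <- b[sample.int(nrow(b)), , drop = FALSE]
    total <- sum(b$size)
    if (total > 0.8 * cfg$chrom_length)
      stop(sprintf("infeasible packing on %s: late blocks cover %.0f%%",
                   ch, 100 * total / cfg$chrom_length))
    slack <- cfg$chrom_length - total
    gaps <- stats::rexp(nrow(b) + 1)
    gaps <- snap(gaps / sum(gaps) * slack, cfg$bin_size)
    pos <- 0
    for (i in seq_len(nrow(b))) {
      pos <- min(pos + gaps[i], cfg$chrom_length - sum(b$size[i:nrow(b)]))
      start <- pos; end <- pos + b$size[i]
      late_rows[[length(late_rows) + 1L]] <- data.frame(
        chrom = ch, start = start, end = end,
        hosts_domain = b$hosts_domain[i], domain_idx = b$domain_idx[i])
      if (b$hosts_domain[i]) {
        j <- b$domain_idx[i]
        off <- snap(stats::runif(1, 0, b$size[i] - dom_size[j]),
                    cfg$bin_size)
        dom_rows[[length(dom_rows) + 1L]] <- data.frame(
          chrom = ch, start = start + off, end = start + off + dom_size[j],
          d = dom_d[j], domain_idx = j)
      }
      pos <- end
    }
  }
  late <- if (length(late_rows)) sort_intervals(do.call(rbind, late_rows))
          else data.frame(chrom = character(), start = numeric(),
                          end = numeric(), hosts_domain = logical(),
                          domain_idx = integer())
  doms <- if (length(dom_rows)) sort_intervals(do.call(rbind, dom_rows))
          else data.frame(chrom = character(), start = numeric(),
                          end = numeric(), d = numeric(),
                          domain_idx = integer())
  rownames(late) <- rownames(doms) <- NULL

  # desert tiles: 1 Mb grid tiles, preferentially inside hosting blocks
  tile <- 1e6
  host_iv <- late[late$hosts_domain, c("chrom", "start", "end")]
  all_tiles <- do.call(rbind, lapply(chroms, function(ch) {
    st <- seq(0, cfg$chrom_length - tile, by = tile)
    as_intervals(ch, st, st + tile)
  }))
  in_host <- nrow(host_iv) > 0 &
    interval_overlap_bp(all_tiles, host_iv) == tile
  late_any <- late[, c("chrom", "start", "end")]
  outside_late <- if (nrow(late_any))
    interval_overlap_bp(all_tiles, late_any) == 0 else rep(TRUE,
                                                           nrow(all_tiles))
  n_in <- min(round(cfg$n_desert_tiles * cfg$frac_desert_in_host),
              sum(in_host))
  n_out <- min(cfg$n_desert_tiles - n_in, sum(outside_late))
  pick <- c(if (n_in) sample(which(in_host), n_in),
            if (n_out) sample(which(outside_late), n_out))
  deserts <- if (length(pick)) all_tiles[sort(pick), , drop = FALSE]
             else all_tiles[0, , drop = FALSE]
  rownames(deserts) <- NULL

  # genes: density thinned inside hosting blocks, zero inside deserts
  n_genes_target <- round(cfg$gene_density * n_chr * cfg$chrom_length / 1e6)
  genes <- NULL
  if (n_genes_target > 0) {
    n_try <- 4 * n_genes_target
    glen <- pmin(pmax(rtrunc_lnorm(n_try, cfg$gene_len_meanlog,
                                   cfg$gene_len_sdlog, 1e3, 2e5), 1e3), 2e5)
    gch <- sample(chroms, n_try, replace = TRUE)
    gst <- floor(stats::runif(n_try, 0, cfg$chrom_length - glen))
    cand <- as_intervals(gch, gst, gst + glen)
    keep <- rep(TRUE, n_try)
    if (nrow(deserts)) keep <- interval_overlap_bp(cand, deserts) == 0
    if (nrow(host_iv)) {
      inh <- interval_overlap_bp(cand, host_iv) > 0
      keep <- keep & (!inh | stats::runif(n_try) < cfg$host_gene_mult)
    }
    cand <- cand[keep, , drop = FALSE]
    cand <- cand[seq_len(min(nrow(cand), n_genes_target)), , drop = FALSE]
    cand$gene_id <- sprintf("gene%05d", seq_len(nrow(cand)))
    cand$tss <- cand$start
    genes <- feature_set(cand, name = "genes", genome = g)
  } else {
    genes <- feature_set(as_intervals(character(), numeric(), numeric()),
                         name = "genes", genome = g)
  }
  tss <- data.frame(chrom = genes$chrom, pos = genes$tss,
                    stringsAsFactors = FALSE)

  structure(list(genome = g, ur_domains = doms, late_blocks = late,
                 genes = genes, desert_tiles = feature_set(
                   deserts, name = "desert_tiles", genome = g),
                 tss = tss, cfg = cfg, seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth: %d chromosomes, %d UR domains (%.1f Mb), %d late blocks, %d genes, seed %d>\n",
              nrow(x$genome$chrom), nrow(x$ur_domains),
              sum(x$ur_domains$end - x$ur_domains$start) / 1e6,
              nrow(x$late_blocks), nrow(x$genes), x$seed))
  invisible(x)
}

#' Stage-adjusted truth domains
#'
#' Earlier stages have smaller, shallower domains: each domain is shrunk
#' around its center by the stage's size multiplier (snapped to the bin
#' grid) and its depletion scaled by the depletion multiplier.
#'
#' @param truth A [simulate_reference()] result.
#' @param stage Stage label present in the config's multipliers.
#' @return data.frame like `truth$ur_domains` with adjusted coordinates and
#'   `d`.
#' @export
stage_truth_domains <- function(truth, stage = "e9.5") {
  cfg <- truth$cfg
  if (!stage %in% names(cfg$stage_size_mult))
    stop(sprintf("unknown stage '%s'", stage))
  sm <- cfg$stage_size_mult[[stage]]
  dm <- cfg$stage_depl_mult[[stage]]
  d <- truth$ur_domains
  if (!nrow(d) || (sm == 1 && dm == 1)) {
    d$d <- d$d * dm
    return(d)
  }
  ctr <- (d$start + d$end) / 2
  half <- (d$end - d$start) * sm / 2
  d$start <- pmax(0, snap(ctr - half, cfg$bin_size))
  d$end <- pmin(chrom_lengths(truth$genome)[d$chrom],
                snap(ctr + half, cfg$bin_size))
  keep <- d$end - d$start >= cfg$bin_size
  d <- d[keep, , drop = FALSE]
  d$d <- d$d * dm
  d
}

#' Simulate paired test/control read-depth tracks
#'
#' Control bins are Poisson(`lambda`); test bins are
#' Poisson(`lambda * (1 - d_i) * s`) with `d_i` the stage-adjusted local
#' truth depletion (0 outside domains) and `s` a global library-scale
#' nuisance factor that normalization must cancel.
#'
#' @param truth A [simulate_reference()] result.
#' @param stage Stage label (default `"e9.5"`).
#' @param seed Integer seed.
#' @param s Library-scale factor for the test sample (default 1).
#' @return List with `test` and `control` raw-count [binned_track()]s and
#'   `truth_domains` (the stage-adjusted truth used).
#' @export
simulate_depth <- function(truth, stage = "e9.5", seed, s = 1) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  cfg <- truth$cfg
  set.seed(seed)
  doms <- stage_truth_domains(truth, stage)
  g <- truth$genome
  nb <- n_bins(g, cfg$bin_size)
  len <- chrom_lengths(g)
  ctrl <- list(); test <- list()
  for (ch in g$chrom$chrom) {
    n <- nb[[ch]]
    # partial trailing bins get proportionally less coverage
    width <- pmin(seq_len(n) * cfg$bin_size, len[[ch]]) -
      (seq_len(n) - 1) * cfg$bin_size
    lam <- cfg$lambda * width / cfg$bin_size
    d_bin <- numeric(n)
    dd <- doms[doms$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(dd))) {
      from <- floor(dd$start[i] / cfg$bin_size) + 1L
      to <- min(n, ceiling(dd$end[i] / cfg$bin_size))
      d_bin[from:to] <- dd$d[i]
    }
    ctrl[[ch]] <- stats::rpois(n, lam)
    test[[ch]] <- stats::rpois(n, lam * (1 - d_bin) * s)
  }
  list(test = binned_track(g, cfg$bin_size, values = test,
                           kind = "raw-count"),
       control = binned_track(g, cfg$bin_size, values = ctrl,
                              kind = "raw-count"),
       truth_domains = doms)
}

#' Simulate a replication-timing track from the truth layout
#'
#' Early regions at `timing_early`, late blocks at `timing_late`, plus
#' Gaussian per-bin noise.
#'
#' @param truth A [simulate_reference()] result.
#' @param seed Integer seed.
#' @return A [binned_track()] of kind `timing`.
#' @export
simulate_timing_track <- function(truth, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  cfg <- truth$cfg
  set.seed(seed)
  g <- truth$genome
  nb <- n_bins(g, cfg$bin_size)
  vals <- list()
  for (ch in g$chrom$chrom) {
    n <- nb[[ch]]
    v <- rep(cfg$timing_early, n)
    lb <- truth$late_blocks[truth$late_blocks$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(lb))) {
      from <- floor(lb$start[i] / cfg$bin_size) + 1L
      to <- min(n, ceiling(lb$end[i] / cfg$bin_size))
      v[from:to] <- cfg$timing_late
    }
    vals[[ch]] <- v + stats::rnorm(n, 0, cfg$timing_sd)
  }
  binned_track(g, cfg$bin_size, values = vals, kind = "timing")
}

#' Simulate histone-mark peak sets and gene expression
#'
#' Peaks of each configured mark are placed with an in-domain : out-domain
#' density ratio (repressive marks > 1, active < 1): each peak falls inside
#' a UR domain with probability `ratio * f / (ratio * f + 1 - f)` where `f`
#' is the domains' genome fraction, then uniformly within the chosen
#' territory. Genes inside domains draw expression from a near-zero
#' component (a point mass at 0 plus a low log-normal); genes outside from
#' the main log-normal.
#'
#' @param truth A [simulate_reference()] result.
#' @param seed Integer seed.
#' @return List with `marks` (named list of peak [feature_set()]s) and
#'   `expression` (data.frame `gene_id`, `expression`, `in_domain`).
#' @export
simulate_marks_and_expression <- function(truth, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  cfg <- truth$cfg
  set.seed(seed)
  g <- truth$genome
  len <- chrom_lengths(g)
  doms <- truth$ur_domains
  dom_iv <- doms[c("chrom", "start", "end")]
  f <- if (nrow(doms)) sum(doms$end - doms$start) / genome_size(g) else 0
  out_iv <- subtract_intervals(
    do.call(rbind, lapply(g$chrom$chrom, function(ch)
      as_intervals(ch, 0, len[[ch]]))), dom_iv)
  place_uniform <- function(iv, k, peak_len) {
    w <- iv$end - iv$start
    seg <- sample.int(nrow(iv), k, replace = TRUE, prob = w)
    mid <- iv$start[seg] + stats::runif(k) * w[seg]
    st <- pmax(0, pmin(mid - peak_len / 2, len[iv$chrom[seg]] - peak_len))
    as_intervals(iv$chrom[seg], st, st + peak_len)
  }
  marks <- list()
  for (nm in names(cfg$marks)) {
    mc <- cfg$marks[[nm]]
    p_in <- if (f > 0) mc$ratio * f / (mc$ratio * f + 1 - f) else 0
    n_in <- stats::rbinom(1, mc$n_peaks, p_in)
    pk <- rbind(
      if (n_in > 0) place_uniform(dom_iv, n_in, mc$peak_len),
      if (mc$n_peaks - n_in > 0) place_uniform(out_iv, mc$n_peaks - n_in,
                                               mc$peak_len))
    marks[[nm]] <- feature_set(pk, name = nm, genome = g)
  }
  genes <- as.data.frame(truth$genes)
  expr <- numeric(nrow(genes))
  in_dom <- if (nrow(genes)) overlaps_any(genes, dom_iv) else logical()
  n_out <- sum(!in_dom)
  expr[!in_dom] <- stats::rlnorm(n_out, cfg$expr_meanlog, cfg$expr_sdlog)
  n_in_g <- sum(in_dom)
  if (n_in_g) {
    zero <- stats::runif(n_in_g) < cfg$in_domain_zero_frac
    low <- stats::rlnorm(n_in_g, cfg$in_domain_expr_meanlog, 0.7)
    expr[in_dom] <- ifelse(zero, 0, low)
  }
  list(marks = marks,
       expression = data.frame(gene_id = genes$gene_id, expression = expr,
                               in_domain = in_dom,
                               stringsAsFactors = FALSE))
}

#' Simulate paired-end records over a region
#'
#' Generates apparent (reference-mapped) paired-end spans at the pair rate
#' implied by `coverage` over a window around the region. Insert lengths
#' are Normal(`mean_insert`, `sd_insert`) truncated above twice the read
#' length. Under `scenario = "deletion"`, `fraction` of the genome copies
#' lack the region: their pairs whose insert crosses the junction come back
#' with the region's length added to their span; under
#' `scenario = "underreplication"`, `fraction` of the copies simply
#' contribute no fragments within the region (spans are never inflated);
#' `"none"` is a uniform diploid-like library.
#'
#' @param region Single-row interval data.frame.
#' @param model An [insert_model()].
#' @param coverage Fold coverage (default 10).
#' @param scenario `"deletion"`, `"underreplication"` or `"none"`.
#' @param fraction Fraction of copies affected (default 0.5).
#' @param flank Window extension on each side of the region (default
#'   25 kb).
#' @param seed Integer seed.
#' @return data.frame with `chrom`, `left_start`, `span` (reference
#'   coordinates).
#' @export
simulate_paired_inserts <- function(region, model, coverage = 10,
                                    scenario = c("deletion",
                                                 "underreplication",
                                                 "none"),
                                    fraction = 0.5, flank = 25e3, seed) {
  scenario <- match.arg(scenario)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(seed)
  rs <- region$start[1]; re <- region$end[1]; ch <- region$chrom[1]
  L <- re - rs
  if (scenario != "none" && L <= model$mean_insert)
    stop("region must be larger than the mean insert")
  win_lo <- max(0, rs - flank)
  win_hi <- re + flank
  pair_rate <- coverage / (2 * model$read_length)
  rinsert <- function(k) {
    x <- stats::rnorm(k, model$mean_insert, model$sd_insert)
    lo <- 2 * model$read_length + 1
    x[x < lo] <- lo
    x
  }
  if (scenario == "deletion") {
    # template genome of the deleted copies lacks [rs, re)
    n_del <- stats::rpois(1, pair_rate * fraction *
                            (win_hi - win_lo - L))
    st_t <- stats::runif(n_del, win_lo, win_hi - L -
                           model$mean_insert)
    ins <- round(rinsert(n_del))
    crosses <- st_t < rs & st_t + ins > rs
    left_start <- st_t
    span <- ifelse(crosses, ins + L, ins)
    left_start <- ifelse(!crosses & st_t >= rs, st_t + L, left_start)
    del_pairs <- data.frame(chrom = rep(ch, n_del),
                            left_start = round(left_start),
                            span = round(span))
    n_int <- stats::rpois(1, pair_rate * (1 - fraction) *
                            (win_hi - win_lo))
    st_i <- stats::runif(n_int, win_lo, win_hi - model$mean_insert)
    int_pairs <- data.frame(chrom = rep(ch, n_int),
                            left_start = round(st_i),
                            span = round(rinsert(n_int)))
    out <- rbind(del_pairs, int_pairs)
  } else {
    n <- stats::rpois(1, pair_rate * (win_hi - win_lo))
    st <- stats::runif(n, win_lo, win_hi - model$mean_insert)
    ins <- round(rinsert(n))
    keep <- rep(TRUE, n)
    if (scenario == "underreplication") {
      mid <- st + ins / 2
      inside <- mid >= rs & mid < re
      keep <- !inside | stats::runif(n) >= fraction
    }
    out <- data.frame(chrom = rep(ch, sum(keep)),
                      left_start = round(st[keep]), span = ins[keep])
  }
  rownames(out) <- NULL
  out
}

#' Write a synthetic data set in the pipeline's own input formats
#'
#' Emits chromosome sizes, truth domains (BED with depletion), late blocks,
#' genes, desert tiles, test/control bedGraph counts, timing bedGraph, mark
#' peak BEDs, expression TSV, and a truth JSON for test harnesses.
#'
#' @param truth A [simulate_reference()] result.
#' @param dir Output directory (created).
#' @param seed Integer seed for the depth/timing/mark draws.
#' @param stage Stage label.
#' @return The directory path, invisibly.
#' @export
write_synthetic_dataset <- function(truth, dir, seed, stage = "e9.5") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- truth$genome
  utils::write.table(g$chrom, file.path(dir, "chrom.sizes"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_intervals(truth$ur_domains, file.path(dir, "truth_domains.bed"),
                  extra_cols = "d")
  write_intervals(truth$late_blocks, file.path(dir, "late_blocks.bed"),
                  extra_cols = "hosts_domain")
  write_intervals(as.data.frame(truth$genes), file.path(dir, "genes.bed"),
                  extra_cols = "gene_id")
  write_intervals(as.data.frame(truth$desert_tiles),
                  file.path(dir, "desert_tiles.bed"))
  depth <- simulate_depth(truth, stage = stage, seed = seed)
  write_bedgraph(depth$test, file.path(dir, "test_counts.bedgraph"))
  write_bedgraph(depth$control, file.path(dir, "control_counts.bedgraph"))
  write_bedgraph(simulate_timing_track(truth, seed = seed + 1),
                 file.path(dir, "timing.bedgraph"))
  me <- simulate_marks_and_expression(truth, seed = seed + 2)
  for (nm in names(me$marks))
    write_intervals(as.data.frame(me$marks[[nm]]),
                    file.path(dir, sprintf("peaks_%s.bed", nm)))
  utils::write.table(me$expression, file.path(dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth_json <- list(seed = truth$seed, stage = stage,
                     n_domains = nrow(truth$ur_domains),
                     genome = list(name = g$name, chrom = g$chrom))
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
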