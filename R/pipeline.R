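#' Validate a pipeline configuration
#'
#' Accepts a list, or a path to a JSON (or YAML, when the yaml package is
#' available) file. All invariant violations are collected and reported at
#' once. A seed is mandatory: stochastic stages never fall back to a clock
#' seed.
#'
#' @param config List or file path.
#' @return The validated config (class `pipeline_config`); on failure an
#'   error whose message lists every problem.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s",
                                           config))
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML config given but the yaml package is not available")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  errs <- character()
  need_num <- function(name, value, min = NULL) {
    if (is.null(value) || !is.numeric(value) || length(value) != 1 ||
        !is.finite(value)) {
      errs <<- c(errs, sprintf("'%s' must be a single finite number", name))
    } else if (!is.null(min) && value < min) {
      errs <<- c(errs, sprintf("'%s' must be >= %g", name, min))
    }
  }
  if (is.null(config$bin_size)) config$bin_size <- 5000
  need_num("bin_size", config$bin_size, min = 1)
  if (is.null(config$seed)) {
    errs <- c(errs, "'seed' is required (no silent clock seeding)")
  } else need_num("seed", config$seed)
  if (is.null(config$caller)) config$caller <- list()
  cal <- config$caller
  cfg_try <- try(ur_caller_config(
    log2_threshold = if (is.null(cal$log2_threshold)) -0.3
      else cal$log2_threshold,
    p_value_max = if (is.null(cal$p_value_max)) 0.01 else cal$p_value_max,
    min_bins = if (is.null(cal$min_bins)) 15 else cal$min_bins,
    merge_gap_bins = if (is.null(cal$merge_gap_bins)) 2
      else cal$merge_gap_bins), silent = TRUE)
  if (inherits(cfg_try, "try-error")) {
    errs <- c(errs, sprintf("caller: %s",
                            trimws(attr(cfg_try, "condition")$message)))
  } else config$caller_config <- cfg_try
  if (is.null(config$n_shuffles)) config$n_shuffles <- 1000
  need_num("n_shuffles", config$n_shuffles, min = 100)
  if (is.null(config$window)) config$window <- 1e6
  need_num("window", config$window, min = 1)
  for (f in c("genome_file")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      errs <- c(errs, sprintf("'%s' does not exist: %s", f, config[[f]]))
  }
  if (!is.null(config$samples)) {
    if (is.data.frame(config$samples))
      config$samples <- split(config$samples, seq_len(nrow(config$samples)))
    for (i in seq_along(config$samples)) {
      s <- as.list(config$samples[[i]])
      if (is.null(s$sample_id))
        errs <- c(errs, sprintf("samples[%d]: missing sample_id", i))
      for (f in c("test", "control")) {
        if (!is.null(s[[f]]) && !file.exists(s[[f]]))
          errs <- c(errs, sprintf("samples[%d]: %s file does not exist: %s",
                                  i, f, s[[f]]))
      }
    }
  }
  if (length(errs))
    stop(paste(c("invalid pipeline config:",
                 paste0("  - ", errs)), collapse = "\n"))
  class(config) <- "pipeline_config"
  config
}

config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

provenance_header <- function(stage, config) {
  sprintf("# urdomains %s stage=%s config=%s seed=%s",
          as.character(utils::packageVersion("urdomains")), stage,
          config_hash(config), format(config$seed))
}

write_stage_table <- function(x, path, stage, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(stage, config), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_counts_file <- function(path, genome, bin_size) {
  if (grepl("\\.bedgraph$", path, ignore.case = TRUE)) {
    read_bedgraph(path, genome, bin_size, kind = "raw-count")
  } else {
    bin_counts(as.data.frame(read_intervals(path, genome = genome)),
               genome, bin_size)
  }
}

#' Run one pipeline stage
#'
#' Ties the analysis stages into a reproducible graph over a shared output
#' directory. Every output table carries a provenance header (package
#' version, config hash, seed) and identical config + seed always give
#' identical outputs. Dependent stages give an actionable error naming the
#' stage to run first.
#'
#' Stages: `simulate` (write a synthetic data set), `bin` (counts from
#' fragment BED or bedGraph per sample), `call` (normalized log2 track +
#' UR calls per sample), `stats` (per-domain report and size-depletion
#' correlation), `compare` (consensus and nestedness across samples),
#' `enrich` (feature-set randomization tests), `timing` (two-state
#' segmentation and late-region containment), `deletion-test` (discordant
#' paired-end verdicts).
#'
#' @param stage Stage name.
#' @param config A [validate_pipeline_config()] result (or list/path,
#'   validated on entry).
#' @param outdir Output directory (created).
#' @return A list of the stage's main results, invisibly; files under
#'   `outdir`.
#' @export
run_pipeline <- function(stage = c("simulate", "bin", "call", "stats",
                                   "compare", "enrich", "timing",
                                   "deletion-test"),
                         config, outdir) {
  stage <- match.arg(stage)
  if (!inherits(config, "pipeline_config"))
    config <- validate_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  if (stage == "simulate") {
    sc_args <- config$simulate
    sc <- if (is.null(sc_args)) sim_config() else do.call(sim_config, sc_args)
    truth <- simulate_reference(sc, seed = seed)
    write_synthetic_dataset(truth, outdir, seed = seed + 1)
    return(invisible(list(truth = truth)))
  }

  g <- if (!is.null(config$genome_file)) read_chrom_sizes(config$genome_file)
       else if (file.exists(file.path(outdir, "chrom.sizes")))
         read_chrom_sizes(file.path(outdir, "chrom.sizes"))
       else stop("no genome: set 'genome_file' or run 'simulate' first")

  samples <- config$samples
  if (is.null(samples) && file.exists(file.path(outdir,
                                                "test_counts.bedgraph"))) {
    samples <- list(list(sample_id = "synthetic", stage = "e9.5",
                         test = file.path(outdir, "test_counts.bedgraph"),
                         control = file.path(outdir,
                                             "control_counts.bedgraph")))
  }

  if (stage == "bin") {
    if (is.null(samples)) stop("no samples in config; run 'simulate' first")
    for (s in samples) {
      s <- as.list(s)
      for (side in c("test", "control")) {
        tr <- read_counts_file(s[[side]], g, config$bin_size)
        write_bedgraph(tr, file.path(outdir, sprintf("%s_%s.counts.bedgraph",
                                                     s$sample_id, side)))
      }
    }
    return(invisible(list(n_samples = length(samples))))
  }

  load_pair <- function(s) {
    s <- as.list(s)
    binned <- file.path(outdir, sprintf("%s_%s.counts.bedgraph",
                                        s$sample_id, c("test", "control")))
    if (all(file.exists(binned))) {
      list(test = read_bedgraph(binned[1], g, config$bin_size),
           control = read_bedgraph(binned[2], g, config$bin_size), meta = s)
    } else if (!is.null(s$test) && file.exists(s$test)) {
      list(test = read_counts_file(s$test, g, config$bin_size),
           control = read_counts_file(s$control, g, config$bin_size),
           meta = s)
    } else stop(sprintf("no binned counts for sample '%s': run 'bin' first",
                        s$sample_id))
  }

  if (stage == "call") {
    if (is.null(samples)) stop("no samples: run 'bin' first")
    calls <- list()
    for (s in samples) {
      pr <- load_pair(s)
      tr <- log2_ratio_track(pr$test, pr$control)
      cl <- call_ur_domains(tr, config$caller_config,
                            sample_id = pr$meta$sample_id)
      write_stage_table(domain_report(cl),
                        file.path(outdir, sprintf("%s.calls.tsv",
                                                  pr$meta$sample_id)),
                        "call", config)
      write_intervals(as.data.frame(cl),
                      file.path(outdir, sprintf("%s.calls.bed",
                                                pr$meta$sample_id)),
                      extra_cols = "sample_id")
      write_bedgraph(tr, file.path(outdir, sprintf("%s.nlog2.bedgraph",
                                                   pr$meta$sample_id)))
      calls[[pr$meta$sample_id]] <- cl
    }
    return(invisible(list(calls = calls)))
  }

  read_calls <- function() {
    files <- list.files(outdir, "\\.calls\\.tsv$", full.names = TRUE)
    if (!length(files)) stop("no call tables found: run 'call' first")
    stats::setNames(lapply(files, function(f)
      utils::read.table(f, header = TRUE, sep = "\t", comment.char = "#",
                        stringsAsFactors = FALSE)),
      sub("\\.calls\\.tsv$", "", basename(files)))
  }

  if (stage == "stats") {
    calls <- read_calls()
    all_rows <- do.call(rbind, calls)
    out <- list()
    if (nrow(all_rows) >= 3) {
      corr <- size_depletion_correlation(
        data.frame(size = all_rows$size,
                   pct_depl_median = all_rows$pct_depl_median))
      out$size_depletion <- corr
      write_stage_table(
        data.frame(r = corr$r, p_value = corr$p_value, slope = corr$slope,
                   n = corr$n),
        file.path(outdir, "size_depletion.tsv"), "stats", config)
    }
    write_stage_table(all_rows, file.path(outdir, "all_domains.tsv"),
                      "stats", config)
    return(invisible(out))
  }

  if (stage == "compare") {
    calls <- read_calls()
    if (length(calls) < 2)
      stop("'compare' needs >= 2 samples with calls: run 'call' first")
    sets <- lapply(names(calls), function(id)
      sample_call_set(calls[[id]], sample_id = id))
    cons <- consensus_domains(sets, min_support = length(sets))
    nest <- nestedness(sets)
    write_stage_table(cons, file.path(outdir, "consensus.tsv"),
                      "compare", config)
    nest_df <- as.data.frame(as.table(nest$fractions))
    names(nest_df) <- c("query", "reference", "fraction")
    write_stage_table(nest_df, file.path(outdir, "nestedness.tsv"),
                      "compare", config)
    return(invisible(list(consensus = cons, nestedness = nest)))
  }

  if (stage == "enrich") {
    calls <- read_calls()
    doms <- sort_and_merge(do.call(rbind, calls))
    genes_file <- config$genes_file %||% file.path(outdir, "genes.bed")
    if (!file.exists(genes_file))
      stop("no gene annotations: set 'genes_file' or run 'simulate' first")
    genes <- read_intervals(genes_file, genome = g)
    tss <- data.frame(chrom = genes$chrom, pos = genes$start)
    peak_files <- config$feature_files
    if (is.null(peak_files))
      peak_files <- list.files(outdir, "^peaks_.*\\.bed$",
                               full.names = TRUE)
    terr <- class_territories(g, tss)
    rows <- list()
    feats <- c(list(genes = genes),
               stats::setNames(lapply(peak_files, read_intervals,
                                      genome = g),
                               sub("^peaks_(.*)\\.bed$", "\\1",
                                   basename(peak_files))))
    deserts <- find_gene_deserts(genes, g, window = config$window)
    if (nrow(deserts)) feats$gene_deserts <- deserts
    for (nm in names(feats)) {
      if (!nrow(feats[[nm]])) next
      rows[[nm]] <- enrichment_test(feats[[nm]], doms, g, tss,
                                    n_shuffles = config$n_shuffles,
                                    seed = seed, feature_name = nm,
                                    territories = terr)
    }
    res <- do.call(rbind, rows)
    write_stage_table(as.data.frame(res),
                      file.path(outdir, "enrichment.tsv"), "enrich", config)
    return(invisible(list(enrichment = res)))
  }

  if (stage == "timing") {
    calls <- read_calls()
    doms <- sort_and_merge(do.call(rbind, calls))
    tf <- config$timing_file %||% file.path(outdir, "timing.bedgraph")
    if (!file.exists(tf))
      stop("no timing track: set 'timing_file' or run 'simulate' first")
    timing <- read_bedgraph(tf, g, config$bin_size, kind = "timing")
    seg <- segment_timing(timing)
    genes_file <- config$genes_file %||% file.path(outdir, "genes.bed")
    genes <- if (file.exists(genes_file))
      read_intervals(genes_file, genome = g)
      else as_intervals(character(), numeric(), numeric())
    rep_file <- list.files(outdir, "\\.nlog2\\.bedgraph$",
                           full.names = TRUE)
    report <- late_region_analysis(doms, seg, genes,
                                   tolerance_bp = config$bin_size)
    write_stage_table(as.data.frame(seg),
                      file.path(outdir, "timing_segments.tsv"),
                      "timing", config)
    write_stage_table(report$late_segments,
                      file.path(outdir, "late_regions.tsv"),
                      "timing", config)
    out <- list(segments = seg, late_report = report)
    if (length(rep_file)) {
      rep_tr <- read_bedgraph(rep_file[1], g, config$bin_size,
                              kind = "normalized-log2-ratio")
      cp <- try(correlation_profile(rep_tr, timing,
                                    window = config$window), silent = TRUE)
      if (!inherits(cp, "try-error")) {
        write_stage_table(
          data.frame(r = cp$r, p_value = cp$p_value,
                     n_windows = cp$n_windows),
          file.path(outdir, "timing_correlation.tsv"), "timing", config)
        out$correlation <- cp
      }
    }
    return(invisible(out))
  }

  if (stage == "deletion-test") {
    pf <- config$pairs_file
    rf <- config$regions_file
    if (is.null(pf) || !file.exists(pf))
      stop("'deletion-test' needs 'pairs_file' (chrom, left_start, span TSV)")
    if (is.null(rf) || !file.exists(rf))
      stop("'deletion-test' needs 'regions_file' (BED)")
    pairs <- utils::read.table(pf, header = TRUE, sep = "\t",
                               comment.char = "#",
                               stringsAsFactors = FALSE)
    regions <- as.data.frame(read_intervals(rf, genome = g))
    model <- do.call(insert_model, config$insert_model %||% list())
    coverage <- config$coverage %||% 10
    rows <- lapply(seq_len(nrow(regions)), function(i) {
      r <- regions[i, , drop = FALSE]
      n <- count_discordant_spanning(pairs, r, model)
      v <- classify_region(n, coverage, r, model)
      data.frame(chrom = r$chrom, start = r$start, end = r$end,
                 discordant = n, expected_if_deleted = v$expected_if_deleted,
                 verdict = v$verdict,
                 p_no_deletion_missed = v$p_no_deletion_missed)
    })
    res <- do.call(rbind, rows)
    write_stage_table(res, file.path(outdir, "deletion_verdicts.tsv"),
                      "deletion-test", config)
    return(invisible(list(verdicts = res)))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
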