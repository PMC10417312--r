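#' End-to-end run configuration
#'
#' Bundles either a simulation configuration or paths to two contact maps
#' with the stage parameters of the full pipeline (differential map, window
#' scan, threshold, coverage control, decay contrast, pileups, enrichment).
#'
#' @param sim a [sim_config()] to simulate input from, or NULL.
#' @param control_path,treated_path TSV contact maps (used when `sim` is
#'   NULL; requires `genome`).
#' @param genome a `genome_model` for file input.
#' @param features_path optional BED of feature peaks for enrichment (file
#'   input only; simulated runs use the planted peaks).
#' @param w window size in bins.
#' @param threshold_method,threshold_param see [choose_threshold()].
#' @param direction calling direction.
#' @param zero_policy zero handling for the log2-ratio map.
#' @param min_valid_fraction window validity guard.
#' @param coarsen_factor optional integer to coarsen the input maps before
#'   calling (e.g. simulate at 10 kb, call at 100 kb).
#' @param pileup a [pileup_config()].
#' @param enrichment_unit `"bin"` or `"peak"`.
#' @param coverage_bound flagging bound for the coverage control.
#' @param decay_probes_bp probe separations for the decay contrast.
#' @param seed seed recorded in the report (the simulation carries its
#'   own seed).
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = NULL, control_path = NULL, treated_path = NULL,
                       genome = NULL, features_path = NULL, w = 10,
                       threshold_method = "quantile", threshold_param = 0.01,
                       direction = "decrease", zero_policy = "mask",
                       min_valid_fraction = 0.5, coarsen_factor = NULL,
                       pileup = pileup_config(), enrichment_unit = "bin",
                       coverage_bound = 0.3, decay_probes_bp = c(1e6, 1e7),
                       seed = 7) {
  if (is.null(sim)) {
    if (is.null(control_path) || is.null(treated_path) || is.null(genome)) {
      stop("either `sim` or control_path + treated_path + genome is required")
    }
    for (p in c(control_path, treated_path, features_path)) {
      if (!is.null(p) && !file.exists(p)) stop("input file does not exist: ", p)
    }
  } else {
    stopifnot(inherits(sim, "sim_config"))
  }
  structure(list(sim = sim, control_path = control_path,
                 treated_path = treated_path, genome = genome,
                 features_path = features_path, w = w,
                 threshold_method = threshold_method,
                 threshold_param = threshold_param, direction = direction,
                 zero_policy = zero_policy,
                 min_valid_fraction = min_valid_fraction,
                 coarsen_factor = coarsen_factor, pileup = pileup,
                 enrichment_unit = enrichment_unit,
                 coverage_bound = coverage_bound,
                 decay_probes_bp = decay_probes_bp, seed = as.integer(seed)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from YAML
#'
#' A thin adapter for the CLI: simulation runs are described by a
#' `simulate:` block (genome, tad sizes, planted pairs, rates), file runs
#' by `control`/`treated`/`chrom_sizes` entries; remaining keys map to
#' [run_config()] arguments.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL; genome <- NULL
  if (!is.null(y$simulate)) {
    s <- y$simulate
    g <- genome_model(vapply(s$chromosomes, `[[`, "", "name"),
                      vapply(s$chromosomes, function(x) as.numeric(x$length_bp), 0),
                      as.numeric(s$bin_size_bp))
    part <- lapply(s$chromosomes, function(x) as.integer(unlist(x$tad_bins)))
    names(part) <- g$chrom_names
    if (!all(lengths(part) > 0)) part <- NULL
    planted <- if (!is.null(s$planted_pairs)) {
      data.frame(chrom = vapply(s$planted_pairs, `[[`, "", "chrom"),
                 left_domain = vapply(s$planted_pairs,
                                      function(x) as.integer(x$left_domain), 0L),
                 stringsAsFactors = FALSE)
    } else NULL
    sim <- sim_config(g, alpha = s$alpha %||% 1, tad_partition = part,
                      beta = s$beta %||% 3, planted_pairs = planted,
                      delta = s$delta %||% 0.5,
                      compaction = s$compaction,
                      total_contacts = s$total_contacts %||% 2e6,
                      peak_density_in = s$peak_density_in %||% 50,
                      peak_density_out = s$peak_density_out %||% 10,
                      seed = s$seed %||% (y$seed %||% 7))
  } else if (!is.null(y$chrom_sizes)) {
    cs <- utils::read.table(y$chrom_sizes, header = FALSE, sep = "\t",
                            col.names = c("chrom", "length"))
    genome <- genome_model(cs$chrom, cs$length, as.numeric(y$bin_size_bp))
  }
  run_config(sim = sim, control_path = y$control, treated_path = y$treated,
             genome = genome, features_path = y$features,
             w = y$w %||% 10,
             threshold_method = y$threshold_method %||% "quantile",
             threshold_param = y$threshold_param %||% 0.01,
             direction = y$direction %||% "decrease",
             zero_policy = y$zero_policy %||% "mask",
             min_valid_fraction = y$min_valid_fraction %||% 0.5,
             coarsen_factor = y$coarsen_factor,
             seed = y$seed %||% 7)
}

#' Run the full differential Hi-C pipeline
#'
#' Executes simulate/load, optional coarsening, log2-ratio construction,
#' window scan, threshold selection, region calling, coverage control,
#' decay contrast, region pileups on both maps, feature enrichment and
#' (for simulated input) recovery evaluation against the planted truth.
#' All outputs are written under `out_dir` and listed with md5 checksums
#' in the JSON run report; identical configurations produce
#' checksum-identical reports.
#'
#' @param config a `run_config`.
#' @param out_dir output directory (created if missing).
#' @return the run report (list), also written to `out_dir/report.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage %s: %s", name, conditionMessage(e)),
                 failed_marker)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  report <- list(seed = config$seed, parameters = list(
    w = config$w, threshold_method = config$threshold_method,
    threshold_param = config$threshold_param, direction = config$direction,
    zero_policy = config$zero_policy,
    min_valid_fraction = config$min_valid_fraction,
    coarsen_factor = config$coarsen_factor,
    enrichment_unit = config$enrichment_unit,
    coverage_bound = config$coverage_bound))
  files <- character()

  inp <- stage("input", {
    if (!is.null(config$sim)) {
      pair <- simulate_pair(config$sim)
      write_contact_tsv(pair$control, file.path(out_dir, "control.tsv"))
      write_contact_tsv(pair$treated, file.path(out_dir, "treated.tsv"))
      write_bed(pair$truth_regions, file.path(out_dir, "truth_regions.bed"))
      write_bed(pair$truth_tads, file.path(out_dir, "truth_tads.bed"))
      write_bed(pair$feature_peaks, file.path(out_dir, "feature_peaks.bed"))
      files <- c(files, "control.tsv", "treated.tsv", "truth_regions.bed",
                 "truth_tads.bed", "feature_peaks.bed")
      list(control = pair$control, treated = pair$treated,
           truth = pair$truth_regions, peaks = pair$feature_peaks,
           files = files)
    } else {
      list(control = read_contact_tsv(config$control_path, config$genome),
           treated = read_contact_tsv(config$treated_path, config$genome),
           truth = NULL,
           peaks = if (!is.null(config$features_path))
             read_bed(config$features_path) else NULL,
           files = files)
    }
  })
  files <- inp$files
  control <- inp$control; treated <- inp$treated
  if (!is.null(config$coarsen_factor)) {
    control <- stage("coarsen", coarsen_map(control, config$coarsen_factor))
    treated <- stage("coarsen", coarsen_map(treated, config$coarsen_factor))
  }
  diff <- stage("diffmap",
                log2_ratio(treated, control, policy = config$zero_policy))
  track <- stage("window_scan", window_scores(diff, w = config$w))
  thr <- stage("threshold",
               choose_threshold(track, method = config$threshold_method,
                                param = config$threshold_param,
                                direction = config$direction))
  regions <- stage("call_regions",
                   call_regions(track, thr, direction = config$direction,
                                min_valid_fraction = config$min_valid_fraction))
  stage("track_outputs", {
    utils::write.table(as.data.frame(track),
                       file.path(out_dir, "window_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_regions_bed(regions, file.path(out_dir, "regions.bed"))
  })
  files <- c(files, "window_scores.tsv", "regions.bed")
  report$n_windows <- nrow(track)
  report$threshold <- as.numeric(thr)
  report$n_regions <- nrow(regions)
  # a run where no call clears twice the genome-wide score SD is flagged as
  # consistent with the null (pure quantile-rule calls)
  report$null_like <- nrow(regions) == 0 ||
    stats::median(abs(regions$score)) < 2 * stats::sd(track$score)

  cov <- stage("coverage",
               suppressWarnings(coverage_report(control, treated, regions,
                                                bound = config$coverage_bound)))
  stage("coverage_outputs", {
    utils::write.table(cov$per_region,
                       file.path(out_dir, "coverage_regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })
  files <- c(files, "coverage_regions.tsv")
  report$coverage <- list(
    n_flagged = sum(cov$per_region$flagged, na.rm = TRUE),
    max_abs_region_log2 = if (nrow(cov$per_region))
      max(abs(cov$per_region$mean_log2_scaled), na.rm = TRUE) else NA)

  decay <- stage("decay", {
    dc <- decay_curve(control, normalize = TRUE)
    dt_ <- decay_curve(treated, normalize = TRUE)
    cmp <- compare_decay(dt_, dc, probe_distances_bp = config$decay_probes_bp)
    utils::write.table(cbind(as.data.frame(dc)[, c("mid_bp", "freq")],
                             treated_freq = dt_$freq,
                             log2_ratio = cmp$curve$log2_ratio),
                       file.path(out_dir, "decay.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cmp
  })
  files <- c(files, "decay.tsv")
  report$decay_probes <- as.list(decay$probes)

  if (nrow(regions)) {
    pil <- stage("pileup", {
      pc <- pileup_regions(control, regions, config$pileup)
      pt <- pileup_regions(treated, regions, config$pileup)
      write_pileup_tsv(pc, file.path(out_dir, "pileup_control.tsv"))
      write_pileup_tsv(pt, file.path(out_dir, "pileup_treated.tsv"))
      list(control = pc, treated = pt)
    })
    files <- c(files, "pileup_control.tsv", "pileup_treated.tsv")
    report$relative_insulation <- list(
      control = pil$control$relative_insulation,
      treated = pil$treated$relative_insulation,
      gain = pil$treated$relative_insulation - pil$control$relative_insulation,
      n_stacked = pil$control$n_stacked)
  }

  if (!is.null(inp$peaks) && nrow(inp$peaks) && nrow(regions)) {
    enr <- stage("enrichment",
                 enrichment_test(inp$peaks, regions, control$genome,
                                 unit = config$enrichment_unit))
    report$enrichment <- list(N = enr$N, m = enr$m, k = enr$k, q = enr$q,
                              fold = enr$fold, p_exclusive = enr$p_exclusive,
                              p_inclusive = enr$p_inclusive)
  }

  if (!is.null(inp$truth)) {
    rec <- stage("recovery", evaluate_recovery(regions, inp$truth))
    report$recovery <- list(recall = rec$recall, precision = rec$precision,
                            mean_truth_jaccard = mean(rec$truth_jaccard$jaccard))
  }

  report$files <- stage("manifest", {
    sums <- tools::md5sum(file.path(out_dir, files))
    stats::setNames(as.list(unname(sums)), files)
  })
  stage("report", {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  })
  report
}
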