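#' Configuration for the synthetic Hi-C pair generator
#'
#' Describes paired control/treated contact maps: a power-law distance
#' decay with exponent `alpha`, block TADs tiling each chromosome with a
#' within-domain enrichment `beta`, planted adjacent-domain pairs whose
#' inter-domain rectangle is multiplied by `delta` in the treated
#' condition, an optional multiplicative compaction tilt of the decay
#' curve, Poisson sampling at a target depth, and clustered feature peaks
#' inside the planted regions.
#'
#' @param genome a `genome_model`.
#' @param alpha decay exponent (> 0 for decaying maps; 0 gives a flat map).
#' @param tad_partition named list (per chromosome) of integer domain
#'   lengths in bins, each summing to the chromosome's bin count.
#' @param beta within-TAD enrichment factor (>= 1).
#' @param planted_pairs data.frame with columns `chrom` and `left_domain`
#'   (1-based index of the left domain of an adjacent pair whose
#'   inter-domain contacts are depleted in the treated map). May be empty.
#' @param delta depletion factor in (0, 1]; 1 plants nothing measurable.
#' @param compaction optional `list(s_pivot_bp=, gamma=)` multiplying the
#'   treated expected counts by `(s/s_pivot)^(-gamma)` at genomic
#'   separation `s = d * bin_size` for off-diagonal pixels (d >= 1); the
#'   main diagonal, which no downstream statistic uses, is left untouched.
#' @param total_contacts target sampled count sum per map.
#' @param peak_density_in feature peaks per Mb inside planted regions.
#' @param peak_density_out feature peaks per Mb elsewhere.
#' @param peak_width_bp width of each planted peak.
#' @param seed RNG seed; every generator output is a pure function of the
#'   configuration including this seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(genome, alpha = 1, tad_partition = NULL, beta = 3,
                       planted_pairs = NULL, delta = 0.5, compaction = NULL,
                       total_contacts = 2e6, peak_density_in = 50,
                       peak_density_out = 10, peak_width_bp = 1000, seed = 7) {
  stopifnot(inherits(genome, "genome_model"))
  if (is.null(tad_partition)) {
    tad_partition <- lapply(genome$chrom_names, function(ch) genome$n_bins[[ch]])
    names(tad_partition) <- genome$chrom_names
  }
  for (ch in genome$chrom_names) {
    sizes <- tad_partition[[ch]]
    if (is.null(sizes) || any(sizes < 1) ||
        sum(sizes) != genome$n_bins[[ch]]) {
      stop(sprintf("tad_partition for %s must tile its %d bins",
                   ch, genome$n_bins[[ch]]))
    }
  }
  if (is.null(planted_pairs)) {
    planted_pairs <- data.frame(chrom = character(), left_domain = integer(),
                                stringsAsFactors = FALSE)
  }
  if (nrow(planted_pairs)) {
    for (i in seq_len(nrow(planted_pairs))) {
      ch <- planted_pairs$chrom[i]
      if (!ch %in% genome$chrom_names) stop("planted pair on unknown chromosome")
      nd <- length(tad_partition[[ch]])
      ld <- planted_pairs$left_domain[i]
      if (ld < 1 || ld >= nd) {
        stop("planted domain pair is not a pair of adjacent domains")
      }
    }
  }
  if (!(delta > 0 && delta <= 1)) stop("delta must be in (0, 1]")
  if (beta < 1) stop("beta must be >= 1")
  if (alpha < 0) stop("alpha must be >= 0")
  if (peak_density_in < 0 || peak_density_out < 0) stop("peak densities must be >= 0")
  if (!is.null(compaction)) {
    stopifnot(is.list(compaction), compaction$s_pivot_bp > 0,
              is.finite(compaction$gamma))
  }
  structure(list(genome = genome, alpha = alpha, tad_partition = tad_partition,
                 beta = beta, planted_pairs = planted_pairs, delta = delta,
                 compaction = compaction, total_contacts = total_contacts,
                 peak_density_in = peak_density_in,
                 peak_density_out = peak_density_out,
                 peak_width_bp = peak_width_bp, seed = as.integer(seed)),
            class = "sim_config")
}

domain_table <- function(config, chrom) {
  sizes <- config$tad_partition[[chrom]]
  ends <- cumsum(sizes)
  data.frame(domain = seq_along(sizes), start_bin = c(0L, ends[-length(ends)]),
             end_bin = ends)
}

#' Planted truth regions of a configuration
#'
#' Each planted adjacent-domain pair contributes one truth region spanning
#' both domains.
#'
#' @param config a `sim_config`.
#' @return an `interval_set` (possibly empty).
#' @export
truth_regions <- function(config) {
  pp <- config$planted_pairs
  if (!nrow(pp)) return(interval_set())
  bs <- config$genome$bin_size_bp
  rows <- lapply(seq_len(nrow(pp)), function(i) {
    dt <- domain_table(config, pp$chrom[i])
    a <- dt[pp$left_domain[i], ]; b <- dt[pp$left_domain[i] + 1, ]
    data.frame(chrom = pp$chrom[i], start_bp = a$start_bin * bs,
               end_bp = min(b$end_bin * bs,
                            config$genome$chrom_lengths_bp[[pp$chrom[i]]]),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  sort_intervals(interval_set(df$chrom, df$start_bp, df$end_bp,
                              name = paste0("truth_", seq_len(nrow(df)))),
                 config$genome)
}

#' TAD intervals of a configuration
#' @param config a `sim_config`.
#' @return an `interval_set` of all domains.
#' @export
truth_tads <- function(config) {
  bs <- config$genome$bin_size_bp
  rows <- lapply(config$genome$chrom_names, function(ch) {
    dt <- domain_table(config, ch)
    data.frame(chrom = ch, start_bp = dt$start_bin * bs,
               end_bp = pmin(dt$end_bin * bs, config$genome$chrom_lengths_bp[[ch]]),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  interval_set(df$chrom, df$start_bp, df$end_bp,
               name = paste0("tad_", seq_len(nrow(df))))
}

#' Build noiseless expected matrices for one condition
#'
#' `E[i,j] = (|i-j|+1)^(-alpha) * beta^[same TAD] * delta^[treated and in a
#' planted inter-domain rectangle] * tilt` where the compaction tilt (only
#' in the treated condition, off-diagonal pixels) is
#' `(d*bin_size/s_pivot)^(-gamma)`.
#'
#' @param config a `sim_config`.
#' @param condition `"control"` or `"treated"`.
#' @return named list of dense non-negative matrices, one per chromosome.
#' @export
build_expected <- function(config, condition = c("control", "treated")) {
  condition <- match.arg(condition)
  g <- config$genome
  out <- lapply(g$chrom_names, function(ch) {
    n <- g$n_bins[[ch]]
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    e <- (d + 1)^(-config$alpha)
    dt <- domain_table(config, ch)
    dom_of_bin <- rep(dt$domain, dt$end_bin - dt$start_bin)
    same <- outer(dom_of_bin, dom_of_bin, "==")
    e <- e * ifelse(same, config$beta, 1)
    if (condition == "treated") {
      pp <- config$planted_pairs
      pp <- pp[pp$chrom == ch, , drop = FALSE]
      if (nrow(pp)) {
        for (i in seq_len(nrow(pp))) {
          a <- dt[pp$left_domain[i], ]; b <- dt[pp$left_domain[i] + 1, ]
          ra <- (a$start_bin + 1):a$end_bin
          rb <- (b$start_bin + 1):b$end_bin
          e[ra, rb] <- e[ra, rb] * config$delta
          e[rb, ra] <- e[rb, ra] * config$delta
        }
      }
      if (!is.null(config$compaction)) {
        tilt <- (d * g$bin_size_bp / config$compaction$s_pivot_bp)^(-config$compaction$gamma)
        tilt[d == 0] <- 1
        e <- e * tilt
      }
    }
    e
  })
  names(out) <- g$chrom_names
  out
}

#' Sample a contact map from expected matrices
#'
#' Upper-triangle pixels (diagonal included) are drawn independently
#' Poisson with mean `total_contacts * E[i,j] / sum(E)` (sum over the
#' upper triangle of all chromosomes), then mirrored.
#'
#' @param expected named list of non-negative matrices (see
#'   [build_expected()]).
#' @param genome the `genome_model` the matrices belong to.
#' @param total_contacts target total; must be positive.
#' @param seed RNG seed; identical seeds give identical maps.
#' @return a `contact_map` of integer counts.
#' @export
sample_counts <- function(expected, genome, total_contacts, seed = 1) {
  if (!is.finite(total_contacts) || total_contacts <= 0) {
    stop("total_contacts must be positive")
  }
  z <- sum(vapply(expected, function(m) sum(m[upper.tri(m, diag = TRUE)]), 0))
  if (z <= 0) stop("expected matrices sum to zero")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  cis <- lapply(genome$chrom_names, function(ch) {
    m <- expected[[ch]]
    ut <- upper.tri(m, diag = TRUE)
    lam <- total_contacts * m[ut] / z
    cnt <- stats::rpois(length(lam), lam)
    out <- matrix(0, nrow(m), ncol(m))
    out[ut] <- cnt
    out <- out + t(out)
    diag(out) <- diag(out) / 2
    out
  })
  names(cis) <- genome$chrom_names
  contact_map(genome, cis, metadata = list(simulated = TRUE, seed = as.integer(seed),
                                           target_total = total_contacts))
}

#' Plant feature peaks at contrasting densities
#'
#' Places fixed-width non-overlapping peaks by a seeded homogeneous
#' process: intensity `peak_density_in` per Mb inside the planted truth
#' regions and `peak_density_out` per Mb elsewhere.
#'
#' @param config a `sim_config`.
#' @param seed RNG seed (defaults to a value derived from the config seed).
#' @return an `interval_set` of peaks.
#' @export
plant_features <- function(config, seed = config$seed + 3L) {
  g <- config$genome
  tr <- truth_regions(config)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  w <- config$peak_width_bp
  place_in_segment <- function(ch, s, e, density_per_mb) {
    len <- e - s
    if (len < w || density_per_mb <= 0) return(NULL)
    n <- stats::rpois(1, density_per_mb * len / 1e6)
    if (n == 0) return(NULL)
    if (n * w > 0.8 * len) {
      stop("peak density too high for non-overlapping placement")
    }
    for (try in seq_len(100)) {
      starts <- sort(stats::runif(n, min = s, max = e - w))
      if (n == 1 || all(diff(starts) >= w)) {
        return(data.frame(chrom = ch, start_bp = floor(starts),
                          end_bp = floor(starts) + w, stringsAsFactors = FALSE))
      }
    }
    stop("failed to place non-overlapping peaks after bounded retries")
  }
  rows <- list()
  for (ch in g$chrom_names) {
    len <- g$chrom_lengths_bp[[ch]]
    reg <- tr[tr$chrom == ch, , drop = FALSE]
    reg <- reg[order(reg$start_bp), , drop = FALSE]
    # inside planted regions
    if (nrow(reg)) {
      for (i in seq_len(nrow(reg))) {
        rows[[length(rows) + 1]] <- place_in_segment(
          ch, reg$start_bp[i], reg$end_bp[i], config$peak_density_in)
      }
    }
    # complement segments
    bounds <- c(0, as.vector(rbind(reg$start_bp, reg$end_bp)), len)
    for (i in seq(1, length(bounds) - 1, by = 2)) {
      if (bounds[i + 1] > bounds[i]) {
        rows[[length(rows) + 1]] <- place_in_segment(
          ch, bounds[i], bounds[i + 1], config$peak_density_out)
      }
    }
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(interval_set())
  df <- do.call(rbind, rows)
  sort_intervals(interval_set(df$chrom, df$start_bp, df$end_bp,
                              name = paste0("peak_", seq_len(nrow(df)))), g)
}

#' Simulate a paired control/treated experiment
#'
#' Composes [build_expected()], [sample_counts()] (with distinct derived
#' seeds per condition) and [plant_features()], returning the maps together
#' with full ground truth.
#'
#' @param config a `sim_config`.
#' @return list of class `simulated_pair` with elements `control`,
#'   `treated` (contact maps), `truth_regions`, `truth_tads`,
#'   `feature_peaks` (interval sets) and `config`.
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ec <- build_expected(config, "control")
  et <- build_expected(config, "treated")
  control <- sample_counts(ec, config$genome, config$total_contacts,
                           seed = config$seed + 1L)
  treated <- sample_counts(et, config$genome, config$total_contacts,
                           seed = config$seed + 2L)
  structure(list(control = control, treated = treated,
                 truth_regions = truth_regions(config),
                 truth_tads = truth_tads(config),
                 feature_peaks = plant_features(config),
                 config = config), class = "simulated_pair")
}

#' Default planted demo configuration
#'
#' Two 20 Mb chromosomes at 100 kb resolution tiled by uniform 0.5 Mb
#' TADs; four planted adjacent-domain pairs (two per chromosome) with the
#' inter-domain rectangle halved in the treated map; 2e6 contacts per map.
#' Peak densities emulate promoter-mark clustering inside the planted
#' regions (50/Mb inside vs 10/Mb outside, 1 kb peaks).
#'
#' @param seed RNG seed.
#' @return a `sim_config`.
#' @export
demo_config <- function(seed = 7) {
  g <- genome_model(c("chr1", "chr2"), c(2e7, 2e7), 1e5)
  part <- list(chr1 = rep(5L, 40), chr2 = rep(5L, 40))
  planted <- data.frame(chrom = c("chr1", "chr1", "chr2", "chr2"),
                        left_domain = c(8L, 24L, 12L, 32L),
                        stringsAsFactors = FALSE)
  sim_config(g, alpha = 1, tad_partition = part, beta = 3,
             planted_pairs = planted, delta = 0.5, total_contacts = 2e6,
             peak_density_in = 50, peak_density_out = 10, seed = seed)
}

#' Compaction-shift demo configuration
#'
#' One 60 Mb chromosome at 100 kb resolution with no TAD enrichment and no
#' planted regions; the treated expected map carries a multiplicative tilt
#' `(s / 3 Mb)^(-0.3)` that raises short-range and depletes long-range
#' contacts, emulating a global chromatin-compaction change.
#'
#' @param seed RNG seed.
#' @param gamma tilt exponent.
#' @return a `sim_config`.
#' @export
compaction_config <- function(seed = 7, gamma = 0.3) {
  g <- genome_model("chr1", 6e7, 1e5)
  sim_config(g, alpha = 1, beta = 1, delta = 1,
             compaction = list(s_pivot_bp = 3e6, gamma = gamma),
             total_contacts = 2e6, peak_density_in = 0, peak_density_out = 0,
             seed = seed)
}
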