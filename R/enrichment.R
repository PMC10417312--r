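#' Hypergeometric probability mass
#'
#' Probability of drawing exactly `x` marked units in a sample of `k`
#' drawn without replacement from `N` units of which `m` are marked:
#' `C(m, x) C(N - m, k - x) / C(N, k)`. Out-of-support `x` returns 0.
#'
#' @param x observed successes.
#' @param N population size.
#' @param m marked units in the population.
#' @param k sample size.
#' @return probability.
#' @export
hypergeom_pmf <- function(x, N, m, k) {
  check_hyper_params(N, m, k)
  stats::dhyper(x, m, N - m, k)
}

#' Hypergeometric upper-tail probability
#'
#' The default matches the exclusive convention `P(X > q)` (the R idiom
#' `1 - phyper(q, ...)`); `inclusive = TRUE` gives `P(X >= q)`, which is
#' the usual enrichment p-value and exceeds the exclusive tail by one pmf
#' term.
#'
#' @param q observed successes.
#' @param N population size.
#' @param m marked units in the population.
#' @param k sample size.
#' @param inclusive use `P(X >= q)` instead of `P(X > q)`.
#' @return tail probability.
#' @export
hypergeom_upper_tail <- function(q, N, m, k, inclusive = FALSE) {
  check_hyper_params(N, m, k)
  stats::phyper(if (inclusive) q - 1 else q, m, N - m, k, lower.tail = FALSE)
}

check_hyper_params <- function(N, m, k) {
  if (any(N < 0) || any(m < 0) || any(m > N) || any(k < 0) || any(k > N)) {
    stop("require 0 <= m <= N and 0 <= k <= N")
  }
  invisible(TRUE)
}

#' Count overlap units for an enrichment test
#'
#' With `unit = "bin"` (default) the sampling unit is the autosomal map
#' bin: `N` = autosomal bins, `m` = bins overlapping a feature, `k` = bins
#' inside the query regions, `q` = feature bins inside the regions. With
#' `unit = "peak"` the unit is a peak from a background universe: `N` =
#' background peaks, `m` = background peaks with midpoint inside the
#' regions, `k` = query feature peaks (a subset of the background), `q` =
#' query peaks with midpoint inside the regions.
#'
#' @param features an `interval_set` of feature intervals (the query peak
#'   set under `unit = "peak"`).
#' @param regions an `interval_set` of query regions (must be non-empty).
#' @param genome a `genome_model`.
#' @param unit `"bin"` or `"peak"`.
#' @param background peak universe required for `unit = "peak"`.
#' @return list of class `enrichment_input` with `N`, `m`, `k`, `q`,
#'   `unit`.
#' @export
count_overlap_units <- function(features, regions, genome,
                                unit = c("bin", "peak"), background = NULL) {
  unit <- match.arg(unit)
  if (!nrow(regions)) stop("empty region set")
  if (unit == "bin") {
    fm <- intervals_to_bins(features, genome)
    rm_ <- intervals_to_bins(regions, genome)
    auto <- genome$chrom_names[genome$autosome]
    N <- sum(genome$n_bins[auto])
    m <- sum(vapply(auto, function(ch) sum(fm[[ch]]), 0))
    k <- sum(vapply(auto, function(ch) sum(rm_[[ch]]), 0))
    q <- sum(vapply(auto, function(ch) sum(fm[[ch]] & rm_[[ch]]), 0))
  } else {
    if (is.null(background)) stop("unit = 'peak' requires a background peak universe")
    midpoint_inside <- function(peaks) {
      if (!nrow(peaks)) return(logical())
      mid <- (peaks$start_bp + peaks$end_bp) / 2
      vapply(seq_len(nrow(peaks)), function(i) {
        any(regions$chrom == peaks$chrom[i] & regions$start_bp <= mid[i] &
              regions$end_bp > mid[i])
      }, TRUE)
    }
    N <- nrow(background)
    m <- sum(midpoint_inside(background))
    k <- nrow(features)
    q <- sum(midpoint_inside(features))
  }
  structure(list(N = N, m = m, k = k, q = q, unit = unit),
            class = "enrichment_input")
}

#' Hypergeometric enrichment of features in regions
#'
#' Composes [count_overlap_units()] with the hypergeometric tail. Reports
#' the fold enrichment `(q/k) / (m/N)` and both tail conventions.
#'
#' @inheritParams count_overlap_units
#' @param inclusive which tail convention is reported as `p` (the other is
#'   always included in the result).
#' @return list of class `enrichment_result` with `p`, `p_exclusive`,
#'   `p_inclusive`, `fold` and the counts.
#' @export
enrichment_test <- function(features, regions, genome, unit = c("bin", "peak"),
                            inclusive = FALSE, background = NULL) {
  cnt <- count_overlap_units(features, regions, genome, unit = unit,
                             background = background)
  p_ex <- hypergeom_upper_tail(cnt$q, cnt$N, cnt$m, cnt$k, inclusive = FALSE)
  p_in <- hypergeom_upper_tail(cnt$q, cnt$N, cnt$m, cnt$k, inclusive = TRUE)
  fold <- if (cnt$k > 0 && cnt$m > 0) (cnt$q / cnt$k) / (cnt$m / cnt$N) else NA_real_
  structure(c(cnt, list(p = if (inclusive) p_in else p_ex,
                        p_exclusive = p_ex, p_inclusive = p_in,
                        fold = fold, inclusive = inclusive)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(paste0("<enrichment_result> unit=%s N=%d m=%d k=%d q=%d\n",
                     "  fold = %s, P(X>q) = %.3g, P(X>=q) = %.3g\n"),
              x$unit, x$N, x$m, x$k, x$q, format(x$fold, digits = 4),
              x$p_exclusive, x$p_inclusive))
  invisible(x)
}
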