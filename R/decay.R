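#' Expected contact count by distance
#'
#' For each chromosome and each integer bin separation `s` (including 0),
#' the mean over all pixels at that separation, zeros included. This is
#' the per-map expected model used for observed/expected pileups.
#'
#' @param map a `contact_map`.
#' @return named list of numeric vectors, element `s + 1` holding the mean
#'   at separation `s`.
#' @export
expected_by_distance <- function(map) {
  out <- lapply(map$genome$chrom_names, function(ch) {
    m <- map$cis[[ch]]
    n <- nrow(m)
    vapply(0:(n - 1), function(s) {
      i <- seq_len(n - s)
      mean(m[cbind(i, i + s)])
    }, 0)
  })
  names(out) <- map$genome$chrom_names
  out
}

#' Distance-decay (P(s)) curve
#'
#' Pools cis pixels across autosomes and bins genomic separations into
#' log-spaced distance bins; each bin's frequency is total contacts at
#' those separations divided by total pixels (zeros included). Optionally
#' normalized so that `sum(freq * n_pixels) = 1`.
#'
#' @param map a `contact_map`.
#' @param n_logbins number of log-spaced distance bins.
#' @param s_min_bp smallest separation included (default one bin; the main
#'   diagonal is never included).
#' @param s_max_bp largest separation included (default the largest
#'   autosomal span).
#' @param normalize normalize to unit mass over the covered range.
#' @return data.frame of class `decay_curve` with columns `edge_lo_bp`,
#'   `edge_hi_bp`, `mid_bp` (geometric mid), `freq`, `n_pixels`,
#'   `n_contacts`, `empty`.
#' @export
decay_curve <- function(map, n_logbins = 50, s_min_bp = NULL, s_max_bp = NULL,
                        normalize = FALSE) {
  g <- map$genome
  bs <- g$bin_size_bp
  auto <- g$chrom_names[g$autosome]
  if (!length(auto)) stop("no autosomes in genome model")
  max_n <- max(g$n_bins[auto])
  if (is.null(s_min_bp)) s_min_bp <- bs
  if (is.null(s_max_bp)) s_max_bp <- (max_n - 1) * bs
  if (s_min_bp < bs) stop("s_min_bp must be at least one bin")
  d_min <- ceiling(s_min_bp / bs)
  d_max <- floor(s_max_bp / bs)
  if (d_max < d_min) stop("empty separation range")
  counts <- numeric(d_max - d_min + 1)
  pixels <- numeric(d_max - d_min + 1)
  for (ch in auto) {
    m <- map$cis[[ch]]
    n <- nrow(m)
    for (d in d_min:min(d_max, n - 1)) {
      i <- seq_len(n - d)
      counts[d - d_min + 1] <- counts[d - d_min + 1] + sum(m[cbind(i, i + d)])
      pixels[d - d_min + 1] <- pixels[d - d_min + 1] + (n - d)
    }
  }
  s_bp <- (d_min:d_max) * bs
  edges <- exp(seq(log(s_min_bp), log(s_max_bp), length.out = n_logbins + 1))
  # assign separations to bins; the last edge is inclusive
  bin <- findInterval(s_bp, edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1
  bin[bin > n_logbins] <- n_logbins
  agg_c <- vapply(seq_len(n_logbins), function(b) sum(counts[bin == b]), 0)
  agg_p <- vapply(seq_len(n_logbins), function(b) sum(pixels[bin == b]), 0)
  freq <- ifelse(agg_p > 0, agg_c / pmax(agg_p, 1), 0)
  if (normalize) {
    mass <- sum(freq * agg_p)
    if (mass > 0) freq <- freq / mass
  }
  out <- data.frame(edge_lo_bp = edges[-length(edges)], edge_hi_bp = edges[-1],
                    mid_bp = sqrt(edges[-length(edges)] * edges[-1]),
                    freq = freq, n_pixels = agg_p, n_contacts = agg_c,
                    empty = agg_p == 0)
  structure(out, class = c("decay_curve", "data.frame"),
            normalized = normalize, edges = edges, bin_size_bp = bs)
}

#' Contrast two decay curves
#'
#' Per-bin `log2(a/b)` with zero-frequency bins masked, plus probe values
#' linearly interpolated in log distance at the requested separations.
#' The default probes (1 Mb and 10 Mb) bracket the scales at which a
#' compaction change shows opposite signs.
#'
#' @param a,b `decay_curve`s with identical distance-bin edges.
#' @param probe_distances_bp separations at which to read off the
#'   log2-ratio.
#' @return list with `curve` (data.frame: mid_bp, log2_ratio) and `probes`
#'   (named numeric).
#' @export
compare_decay <- function(a, b, probe_distances_bp = c(1e6, 1e7)) {
  ea <- attr(a, "edges"); eb <- attr(b, "edges")
  if (length(ea) != length(eb) || !isTRUE(all.equal(ea, eb))) {
    stop("decay curves have different distance-bin edges")
  }
  lr <- ifelse(a$freq > 0 & b$freq > 0, log2(a$freq / b$freq), NA_real_)
  curve <- data.frame(mid_bp = a$mid_bp, log2_ratio = lr)
  ok <- is.finite(lr)
  if (sum(ok) < 2) stop("fewer than two valid bins; cannot interpolate probes")
  probes <- stats::approx(x = log(a$mid_bp[ok]), y = lr[ok],
                          xout = log(probe_distances_bp), rule = 2)$y
  names(probes) <- format(probe_distances_bp, scientific = FALSE, trim = TRUE)
  list(curve = curve, probes = probes)
}

#' Fit the log-log slope of a decay curve
#'
#' Ordinary least squares of `log(freq)` on `log(s)` over the requested
#' central range, skipping empty or zero bins.
#'
#' @param curve a `decay_curve`.
#' @param s_range_bp range of separations to fit over.
#' @return the fitted slope (numeric scalar).
#' @export
fit_decay_slope <- function(curve, s_range_bp = c(min(curve$mid_bp), max(curve$mid_bp))) {
  keep <- curve$freq > 0 & !curve$empty &
    curve$mid_bp >= s_range_bp[1] & curve$mid_bp <= s_range_bp[2]
  if (sum(keep) < 3) stop("fewer than 3 usable bins in fit range")
  fit <- stats::lm(log(freq) ~ log(mid_bp), data = curve[keep, , drop = FALSE])
  unname(stats::coef(fit)[2])
}
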