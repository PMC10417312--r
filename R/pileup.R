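#' Pileup configuration
#'
#' @param flank_bp flank added on each side of a region or anchor
#'   (default 1 Mb).
#' @param grid_n output grid size for rescaled region pileups (odd, >= 9).
#' @param oe divide pixels by the map's own expected-by-distance model
#'   (default TRUE); `FALSE` stacks raw counts.
#' @param min_valid_fraction windows with a smaller fraction of usable
#'   pixels are skipped.
#' @return list of class `pileup_config`.
#' @export
pileup_config <- function(flank_bp = 1e6, grid_n = 99, oe = TRUE,
                          min_valid_fraction = 0) {
  if (grid_n < 9 || grid_n %% 2 == 0) stop("grid_n must be odd and >= 9")
  if (flank_bp <= 0) stop("flank_bp must be positive")
  structure(list(flank_bp = flank_bp, grid_n = as.integer(grid_n), oe = oe,
                 min_valid_fraction = min_valid_fraction),
            class = "pileup_config")
}

#' Observed/expected submatrix over a genomic window
#'
#' Extracts the cis submatrix covering `[start_bp, end_bp)` and divides
#' each pixel by the expected value at its separation; pixels with zero
#' expected are masked (NA).
#'
#' @param map a `contact_map`.
#' @param chrom chromosome name.
#' @param start_bp,end_bp half-open window; must lie inside the chromosome.
#' @param expected the map's [expected_by_distance()] model; computed on
#'   the fly when NULL.
#' @param oe set FALSE to return the raw submatrix.
#' @return square numeric matrix (NA where masked).
#' @export
oe_window <- function(map, chrom, start_bp, end_bp, expected = NULL, oe = TRUE) {
  g <- map$genome
  if (!chrom %in% g$chrom_names) stop("unknown chromosome: ", chrom)
  bs <- g$bin_size_bp
  n <- g$n_bins[[chrom]]
  b0 <- floor(start_bp / bs); b1 <- ceiling(end_bp / bs)
  if (b0 < 0 || b1 > n || b1 <= b0) {
    stop(sprintf("window [%s, %s) is outside chromosome %s",
                 format(start_bp, scientific = FALSE),
                 format(end_bp, scientific = FALSE), chrom))
  }
  idx <- (b0 + 1):b1
  sub <- map$cis[[chrom]][idx, idx, drop = FALSE]
  if (!oe) return(sub)
  if (is.null(expected)) expected <- expected_by_distance(map)
  ev <- expected[[chrom]]
  d <- abs(outer(idx, idx, "-"))
  e <- matrix(ev[d + 1], nrow(sub), ncol(sub))
  out <- sub / e
  out[e == 0] <- NA_real_
  out
}

band_weight_matrix <- function(bands_in, bands_out) {
  stopifnot(length(bands_in) == length(bands_out))
  blocks <- mapply(function(n_in, n_out) {
    w <- matrix(0, n_out, n_in)
    step <- n_in / n_out
    for (k in seq_len(n_out)) {
      lo <- (k - 1) * step; hi <- k * step
      cells <- floor(lo):min(ceiling(hi) - 1, n_in - 1)
      for (cc in cells) {
        w[k, cc + 1] <- max(0, min(hi, cc + 1) - max(lo, cc))
      }
    }
    w
  }, bands_in, bands_out, SIMPLIFY = FALSE)
  n_in <- sum(bands_in); n_out <- sum(bands_out)
  W <- matrix(0, n_out, n_in)
  ro <- 0L; co <- 0L
  for (b in blocks) {
    W[ro + seq_len(nrow(b)), co + seq_len(ncol(b))] <- b
    ro <- ro + nrow(b); co <- co + ncol(b)
  }
  W
}

#' Rescale a square matrix onto a fixed grid by block means
#'
#' Area-weighted block-mean interpolation; masked (NA) input pixels are
#' excluded from block means and cells with no valid coverage stay NA.
#' With `bands_in`/`bands_out` the input and output are partitioned into
#' corresponding bands (e.g. flank/region/flank) that are rescaled
#' independently, keeping band boundaries aligned across inputs of
#' different sizes.
#'
#' @param mat square input matrix (NA allowed).
#' @param grid_n output size (ignored when `bands_out` is given).
#' @param bands_in,bands_out optional integer band widths partitioning the
#'   input and output axes; both must sum to their axis sizes.
#' @return `grid_n x grid_n` (or `sum(bands_out)` squared) matrix.
#' @export
rescale_grid <- function(mat, grid_n, bands_in = NULL, bands_out = NULL) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat), nrow(mat) >= 2)
  if (is.null(bands_in)) bands_in <- nrow(mat)
  if (is.null(bands_out)) bands_out <- as.integer(grid_n)
  if (sum(bands_in) != nrow(mat)) stop("bands_in must sum to the matrix size")
  W <- band_weight_matrix(bands_in, bands_out)
  valid <- !is.na(mat)
  m0 <- mat
  m0[!valid] <- 0
  num <- W %*% m0 %*% t(W)
  den <- W %*% (valid + 0) %*% t(W)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

stack_mean <- function(acc_sum, acc_n, grid) {
  ok <- !is.na(grid)
  acc_sum[ok] <- acc_sum[ok] + grid[ok]
  acc_n[ok] <- acc_n[ok] + 1
  list(acc_sum, acc_n)
}

#' Rescaled-region pileup
#'
#' For each region, the window `[start - flank, end + flank)` is extracted
#' as observed/expected, the flank and region parts are rescaled
#' independently onto fixed side and central bands of the grid, and all
#' windows are averaged pixelwise (ignoring masked pixels). The flank band
#' width is proportional to the flank's share of the mean stacked window
#' and is recorded in the result.
#'
#' @param map a `contact_map`.
#' @param regions an `interval_set`; regions whose flanked window leaves
#'   the chromosome are skipped with a reason.
#' @param cfg a [pileup_config()].
#' @return list of class `pileup_result`: `grid`, `n_stacked`, `skipped`,
#'   `relative_insulation`, `quadrant_means`, `region_span_cols`,
#'   `flank_band`, `mode`, `config`.
#' @export
pileup_regions <- function(map, regions, cfg = pileup_config()) {
  if (!nrow(regions)) stop("no regions to pile up")
  g <- map$genome
  expected <- if (cfg$oe) expected_by_distance(map) else NULL
  fl <- cfg$flank_bp
  if (fl %% g$bin_size_bp != 0) stop("flank_bp must be a multiple of the bin size")
  usable <- logical(nrow(regions))
  reason <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]
    if (!ch %in% g$chrom_names) { reason[i] <- "unknown chromosome"; next }
    if (regions$start_bp[i] - fl < 0 ||
        regions$end_bp[i] + fl > g$chrom_lengths_bp[[ch]]) {
      reason[i] <- "flanked window outside chromosome"; next
    }
    usable[i] <- TRUE
  }
  if (!any(usable)) stop("no usable regions after flanking")
  mean_len <- mean(regions$end_bp[usable] - regions$start_bp[usable])
  fb <- round(cfg$grid_n * fl / (2 * fl + mean_len))
  fb <- max(1L, min(as.integer(fb), (cfg$grid_n - 1L) %/% 2L))
  rb <- cfg$grid_n - 2L * fb
  acc_sum <- matrix(0, cfg$grid_n, cfg$grid_n)
  acc_n <- matrix(0, cfg$grid_n, cfg$grid_n)
  fl_bins <- as.integer(fl / g$bin_size_bp)
  for (i in which(usable)) {
    ch <- regions$chrom[i]
    win <- oe_window(map, ch, regions$start_bp[i] - fl, regions$end_bp[i] + fl,
                     expected = expected, oe = cfg$oe)
    reg_bins <- nrow(win) - 2L * fl_bins
    if (reg_bins < 1) { usable[i] <- FALSE; reason[i] <- "region shorter than one bin"; next }
    if (mean(!is.na(win)) < cfg$min_valid_fraction) {
      usable[i] <- FALSE; reason[i] <- "too few valid pixels"; next
    }
    grid <- rescale_grid(win, bands_in = c(fl_bins, reg_bins, fl_bins),
                         bands_out = c(fb, rb, fb))
    res <- stack_mean(acc_sum, acc_n, grid)
    acc_sum <- res[[1]]; acc_n <- res[[2]]
  }
  if (!any(usable)) stop("no usable regions after windowing")
  grid <- acc_sum / acc_n
  grid[acc_n == 0] <- NA_real_
  span <- (fb + 1L):(fb + rb)
  ri <- ri_from_grid(grid, span)
  structure(list(grid = grid, n_stacked = sum(usable),
                 skipped = data.frame(name = regions$name[!usable],
                                      reason = reason[!usable],
                                      stringsAsFactors = FALSE),
                 relative_insulation = ri$ri, quadrant_means = ri$quadrants,
                 region_span_cols = span, flank_band = fb,
                 mode = "rescaled_region", config = cfg),
            class = "pileup_result")
}

#' Fixed-window anchor pileup
#'
#' Stacks fixed-size observed/expected windows of width `2 * flank`
#' centered on each anchor's midpoint, without rescaling. Anchors whose
#' window leaves the chromosome are skipped with a reason.
#'
#' @param map a `contact_map`.
#' @param anchors an `interval_set`; midpoints are used.
#' @param cfg a [pileup_config()].
#' @return a `pileup_result` (the relative insulation uses the central
#'   half of the grid).
#' @export
pileup_anchors <- function(map, anchors, cfg = pileup_config()) {
  if (!nrow(anchors)) stop("no anchors to pile up")
  g <- map$genome
  expected <- if (cfg$oe) expected_by_distance(map) else NULL
  bs <- g$bin_size_bp
  if (cfg$flank_bp %% bs != 0) stop("flank_bp must be a multiple of the bin size")
  half <- as.integer(cfg$flank_bp / bs)
  size <- 2L * half + 1L
  acc_sum <- matrix(0, size, size)
  acc_n <- matrix(0, size, size)
  usable <- logical(nrow(anchors)); reason <- character(nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    ch <- anchors$chrom[i]
    if (!ch %in% g$chrom_names) { reason[i] <- "unknown chromosome"; next }
    mid <- floor((anchors$start_bp[i] + anchors$end_bp[i]) / 2)
    cbin <- floor(mid / bs)
    if (cbin - half < 0 || cbin + half >= g$n_bins[[ch]]) {
      reason[i] <- "window clipped by chromosome edge"; next
    }
    win <- oe_window(map, ch, (cbin - half) * bs, (cbin + half + 1) * bs,
                     expected = expected, oe = cfg$oe)
    if (mean(!is.na(win)) < cfg$min_valid_fraction) {
      reason[i] <- "too few valid pixels"; next
    }
    usable[i] <- TRUE
    res <- stack_mean(acc_sum, acc_n, win)
    acc_sum <- res[[1]]; acc_n <- res[[2]]
  }
  if (!any(usable)) stop("all anchors were skipped")
  grid <- acc_sum / acc_n
  grid[acc_n == 0] <- NA_real_
  q <- size %/% 4L
  span <- (q + 1L):(size - q)
  ri <- ri_from_grid(grid, span)
  structure(list(grid = grid, n_stacked = sum(usable),
                 skipped = data.frame(name = anchors$name[!usable],
                                      reason = reason[!usable],
                                      stringsAsFactors = FALSE),
                 relative_insulation = ri$ri, quadrant_means = ri$quadrants,
                 region_span_cols = span, flank_band = q,
                 mode = "fixed_anchor", config = cfg),
            class = "pileup_result")
}

ri_from_grid <- function(grid, span_cols) {
  len <- length(span_cols)
  if (len < 2) return(list(ri = NA_real_, quadrants = c(intra = NA, inter = NA)))
  a <- span_cols[seq_len(len %/% 2)]
  b <- span_cols[(len %/% 2 + 1):len]
  intra_vals <- c(grid[a, a], grid[b, b])
  inter_vals <- grid[a, b]
  intra <- mean(intra_vals, na.rm = TRUE)
  inter <- mean(inter_vals, na.rm = TRUE)
  ri <- if (is.finite(intra) && is.finite(inter) && intra > 0 && inter > 0) {
    log2(intra / inter)
  } else NA_real_
  list(ri = ri, quadrants = c(intra = intra, inter = inter))
}

#' Relative insulation strength of a pileup
#'
#' Splits the central span (the region band in rescaled mode, the central
#' half in anchor mode) at its midpoint into halves A and B and returns
#' `log2(mean o/e over A x A and B x B / mean o/e over A x B)`. Higher
#' values mean stronger insulation between the two halves. The raw
#' quadrant means are returned alongside so alternative summary statistics
#' can be recomputed.
#'
#' @param result a `pileup_result`.
#' @return list with `ri`, `intra`, `inter`.
#' @export
relative_insulation <- function(result) {
  stopifnot(inherits(result, "pileup_result"))
  r <- ri_from_grid(result$grid, result$region_span_cols)
  list(ri = r$ri, intra = unname(r$quadrants["intra"]),
       inter = unname(r$quadrants["inter"]))
}

#' @export
print.pileup_result <- function(x, ...) {
  cat(sprintf("<pileup_result> %s, %d window(s) stacked, grid %dx%d, RI = %s\n",
              x$mode, x$n_stacked, nrow(x$grid), ncol(x$grid),
              format(x$relative_insulation, digits = 4)))
  invisible(x)
}

#' Write a pileup grid as TSV
#' @param result a `pileup_result`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_pileup_tsv <- function(result, path) {
  lines <- apply(result$grid, 1, function(r) {
    paste(ifelse(is.na(r), "NA", sprintf("%.6g", r)), collapse = "\t")
  })
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
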