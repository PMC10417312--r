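#' Diagonal sliding-window scores of a differential map
#'
#' A window of `w` bins slides along the matrix diagonal with step 1 bin;
#' the score of each window is the sum of the log2-ratio values over the
#' upper triangle of the `w x w` diagonal-anchored square (main diagonal
#' excluded, so no pixel is double counted). Masked pixels contribute 0
#' and the valid pixel fraction of each window is recorded.
#'
#' @param diff a `diff_map`.
#' @param w window size in bins (>= 2). Chromosomes shorter than `w` are
#'   skipped with a warning.
#' @return data.frame of class `window_score_track` with columns `chrom`,
#'   `start_bin` (0-based), `score`, `valid_fraction`; attributes `w` and
#'   `genome`.
#' @export
window_scores <- function(diff, w = 10) {
  stopifnot(inherits(diff, "diff_map"))
  if (w < 2) stop("w must be >= 2")
  w <- as.integer(w)
  n_px <- w * (w - 1) / 2
  rows <- list()
  for (ch in diff$genome$chrom_names) {
    n <- diff$genome$n_bins[[ch]]
    if (n < w) {
      warning(sprintf("chromosome %s (%d bins) shorter than window (%d bins); skipped",
                      ch, n, w))
      next
    }
    v <- diff$values[[ch]]
    ok <- diff$mask[[ch]]
    v0 <- v
    v0[!ok | is.na(v)] <- 0
    n_win <- n - w + 1L
    score <- numeric(n_win)
    vfrac <- numeric(n_win)
    ut <- upper.tri(matrix(0, w, w))
    for (i in seq_len(n_win)) {
      idx <- i:(i + w - 1L)
      score[i] <- sum(v0[idx, idx][ut])
      vfrac[i] <- sum(ok[idx, idx][ut]) / n_px
    }
    rows[[ch]] <- data.frame(chrom = ch, start_bin = seq_len(n_win) - 1L,
                             score = score, valid_fraction = vfrac,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no chromosome is long enough for the window")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("window_score_track", "data.frame"),
            w = w, genome = diff$genome)
}

#' Choose a calling threshold from the score distribution
#'
#' The genome-wide window-score distribution defines the threshold:
#' either an empirical quantile (default: the 1st percentile of the lower
#' tail for decrease calling) or a mean +/- k*SD rule.
#'
#' @param track a `window_score_track`.
#' @param method `"quantile"` (needs >= 100 scores) or `"mean_sd"`.
#' @param param quantile level (default 0.01) or the SD multiple.
#' @param direction `"decrease"` (lower tail) or `"increase"` (upper tail).
#' @return numeric threshold with attributes recording method, param and
#'   direction.
#' @export
choose_threshold <- function(track, method = c("quantile", "mean_sd"),
                             param = if (method[1] == "quantile") 0.01 else 3,
                             direction = c("decrease", "increase")) {
  method <- match.arg(method)
  direction <- match.arg(direction)
  s <- track$score
  if (method == "quantile") {
    if (length(s) < 100) {
      stop("fewer than 100 window scores genome-wide; use method = 'mean_sd'")
    }
    if (param < 0 || param > 1) stop("quantile param must be in [0, 1]")
    thr <- unname(stats::quantile(s, if (direction == "decrease") param else 1 - param))
  } else {
    thr <- mean(s) + (if (direction == "decrease") -1 else 1) * param * stats::sd(s)
    if (length(s) == 1 || stats::sd(s) == 0) thr <- mean(s)
  }
  structure(thr, method = method, param = param, direction = direction)
}

#' Call differential regions from a score track
#'
#' Windows passing the threshold (`score <= threshold` for decrease,
#' `>=` for increase) with enough valid pixels are selected; overlapping
#' or adjacent selected windows are merged and each merged run becomes one
#' region spanning `[first start * bin, (last start + w) * bin)`.
#'
#' @param track a `window_score_track`.
#' @param threshold numeric threshold (see [choose_threshold()]).
#' @param direction `"decrease"` or `"increase"`.
#' @param min_valid_fraction windows with a smaller valid-pixel fraction
#'   are never selected (guards against masked zero-count deserts).
#' @return an `interval_set` of class `differential_regions` with one row
#'   per region (score column = extreme window score); attributes record
#'   threshold, w, direction and per-region extreme scores.
#' @export
call_regions <- function(track, threshold, direction = c("decrease", "increase"),
                         min_valid_fraction = 0.5) {
  direction <- match.arg(direction)
  w <- attr(track, "w")
  g <- attr(track, "genome")
  bs <- g$bin_size_bp
  pass <- if (direction == "decrease") track$score <= as.numeric(threshold)
          else track$score >= as.numeric(threshold)
  pass <- pass & track$valid_fraction >= min_valid_fraction
  sel <- track[pass, , drop = FALSE]
  empty <- interval_set()
  if (!nrow(sel)) {
    out <- empty
  } else {
    rows <- list()
    for (ch in g$chrom_names) {
      d <- sel[sel$chrom == ch, , drop = FALSE]
      if (!nrow(d)) next
      d <- d[order(d$start_bin), , drop = FALSE]
      run_id <- cumsum(c(1, diff(d$start_bin) > w))
      for (r in unique(run_id)) {
        dd <- d[run_id == r, , drop = FALSE]
        ext <- if (direction == "decrease") min(dd$score) else max(dd$score)
        rows[[length(rows) + 1]] <- data.frame(
          chrom = ch,
          start_bp = dd$start_bin[1] * bs,
          end_bp = min((dd$start_bin[nrow(dd)] + w) * bs, g$chrom_lengths_bp[[ch]]),
          score = ext, stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    out <- interval_set(df$chrom, df$start_bp, df$end_bp,
                        name = sprintf("region_%03d", seq_len(nrow(df))),
                        score = df$score)
  }
  structure(out, class = c("differential_regions", class(empty)),
            threshold = as.numeric(threshold),
            threshold_method = attr(threshold, "method"),
            threshold_param = attr(threshold, "param"),
            w = w, direction = direction,
            min_valid_fraction = min_valid_fraction)
}

#' Write called regions as BED6-like output
#'
#' The BED score column rescales each region's extreme window score to
#' `[0, 1000]` relative to the genome-wide extreme.
#'
#' @param regions a `differential_regions` object.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_regions_bed <- function(regions, path) {
  out <- regions
  if (nrow(out)) {
    ext <- if (identical(attr(regions, "direction"), "increase")) max(out$score)
           else min(out$score)
    out$score <- if (ext == 0) rep(0, nrow(out))
                 else round(1000 * pmin(1, out$score / ext))
  }
  write_bed(out, path)
}

jaccard_against <- function(targets, others) {
  vapply(seq_len(nrow(targets)), function(i) {
    ch <- targets$chrom[i]
    ts <- targets$start_bp[i]; te <- targets$end_bp[i]
    ov <- others[others$chrom == ch & others$end_bp > ts & others$start_bp < te, ,
                 drop = FALSE]
    if (!nrow(ov)) return(0)
    inter <- sum(pmin(ov$end_bp, te) - pmax(ov$start_bp, ts))
    union <- (te - ts) + sum(ov$end_bp - ov$start_bp) - inter
    inter / union
  }, 0)
}

#' Evaluate recovery of truth regions by calls
#'
#' For each truth region, the Jaccard index against the union of
#' overlapping calls is computed (calls are disjoint after merging);
#' recall is the fraction of truth regions reaching `j0`, precision the
#' analogous fraction of calls against the truth set.
#'
#' @param called,truth `interval_set`s on the same genome.
#' @param j0 Jaccard threshold counting a region as recovered.
#' @return list with `recall`, `precision`, `truth_jaccard` and
#'   `call_jaccard` (per-region data.frames).
#' @export
evaluate_recovery <- function(called, truth, j0 = 0.25) {
  tj <- if (nrow(truth)) jaccard_against(truth, called) else numeric()
  cj <- if (nrow(called)) jaccard_against(called, truth) else numeric()
  recall <- if (nrow(truth)) mean(tj >= j0) else NA_real_
  precision <- if (nrow(called)) mean(cj >= j0) else NA_real_
  list(recall = recall, precision = precision,
       truth_jaccard = data.frame(name = truth$name, jaccard = tj,
                                  stringsAsFactors = FALSE),
       call_jaccard = data.frame(name = called$name, jaccard = cj,
                                 stringsAsFactors = FALSE),
       j0 = j0)
}
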