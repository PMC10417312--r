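#' Overall autosomal contact sum of a map
#'
#' Sums cis upper-triangle off-diagonal pixels of autosomes (each
#' unordered pair once) plus all trans autosome-autosome pixels when
#' present. Main-diagonal pixels and non-autosomes are excluded. This is
#' the scaling total used before forming the log2-ratio map.
#'
#' @param map a `contact_map`.
#' @return positive number; an all-zero total is an error (cannot scale).
#' @export
overall_sum <- function(map) {
  g <- map$genome
  auto <- g$chrom_names[g$autosome]
  if (!length(auto)) stop("no autosomes in genome model")
  s <- 0
  for (ch in auto) {
    m <- map$cis[[ch]]
    s <- s + sum(m[upper.tri(m)])
  }
  if (!is.null(map$trans)) {
    for (key in names(map$trans)) {
      chs <- strsplit(key, "|", fixed = TRUE)[[1]]
      if (all(chs %in% auto)) s <- s + sum(map$trans[[key]])
    }
  }
  if (s <= 0) stop("overall autosomal off-diagonal sum is zero; cannot scale")
  s
}

#' Scale a map by its overall sum
#'
#' Divides every pixel (cis and trans) by [overall_sum()], so the scaled
#' map's overall sum is 1 and any constant depth factor cancels.
#'
#' @param map a `contact_map`.
#' @return a scaled `contact_map`.
#' @export
scale_map <- function(map) {
  s <- overall_sum(map)
  cis <- lapply(map$cis, function(m) m / s)
  trans <- if (!is.null(map$trans)) lapply(map$trans, function(m) m / s) else NULL
  contact_map(map$genome, cis, trans = trans,
              metadata = c(map$metadata, list(scaling_total = s)))
}

#' Masked log2-ratio differential map
#'
#' Both maps are sum-scaled, then each cis pixel becomes
#' `log2(treated/control)`. Under the default `"mask"` policy pixels where
#' either raw count is zero are masked out; under `"pseudocount"` a small
#' constant is added to both scaled values and every pixel is valid.
#'
#' @param treated,control `contact_map`s on the same genome.
#' @param policy zero handling: `"mask"` (default) or `"pseudocount"`.
#' @param pseudocount value added to scaled pixels under the pseudocount
#'   policy; default is the reciprocal harmonic mean of the two scaling
#'   totals (roughly one raw count on the scaled scale).
#' @return object of class `diff_map` with per-chromosome `values`
#'   (NA where masked) and logical `mask` matrices.
#' @export
log2_ratio <- function(treated, control, policy = c("mask", "pseudocount"),
                       pseudocount = NULL) {
  policy <- match.arg(policy)
  if (!same_genome(treated$genome, control$genome)) {
    stop("treated and control maps are on different genomes")
  }
  g <- treated$genome
  st <- overall_sum(treated)
  sc <- overall_sum(control)
  if (policy == "pseudocount" && is.null(pseudocount)) {
    pseudocount <- (1 / st + 1 / sc) / 2
  }
  values <- list(); mask <- list()
  for (ch in g$chrom_names) {
    t_ <- treated$cis[[ch]] / st
    c_ <- control$cis[[ch]] / sc
    if (policy == "mask") {
      ok <- t_ > 0 & c_ > 0
      v <- matrix(NA_real_, nrow(t_), ncol(t_))
      v[ok] <- log2(t_[ok] / c_[ok])
    } else {
      ok <- matrix(TRUE, nrow(t_), ncol(t_))
      v <- log2((t_ + pseudocount) / (c_ + pseudocount))
    }
    values[[ch]] <- v
    mask[[ch]] <- ok
  }
  structure(list(genome = g, values = values, mask = mask,
                 scaling_totals = c(control = sc, treated = st),
                 policy = policy, pseudocount = pseudocount),
            class = "diff_map")
}

#' @export
print.diff_map <- function(x, ...) {
  nv <- sum(vapply(x$mask, sum, 0))
  cat(sprintf("<diff_map> %d chromosome(s), %s valid pixels, policy=%s\n",
              length(x$values), format(nv, big.mark = ","), x$policy))
  invisible(x)
}

#' Export a differential map as TSV triples with a mask column
#' @param diff a `diff_map`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_diffmap_tsv <- function(diff, path) {
  lines <- "chrom\tbin1\tbin2\tlog2_ratio\tvalid"
  for (ch in diff$genome$chrom_names) {
    v <- diff$values[[ch]]; ok <- diff$mask[[ch]]
    sel <- which(upper.tri(v, diag = TRUE) & (ok | !is.na(v)), arr.ind = TRUE)
    if (nrow(sel)) {
      o <- order(sel[, 1], sel[, 2])
      sel <- sel[o, , drop = FALSE]
      val <- v[sel]
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s\t%d", ch, sel[, 1] - 1L,
                                sel[, 2] - 1L,
                                ifelse(is.na(val), "NA", sprintf("%.6g", val)),
                                as.integer(ok[sel])))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Coverage control report
#'
#' Computes per-bin marginal sums (cis row sums) of both maps, raw and
#' sum-scaled, and for each query region the mean per-bin log2 marginal
#' ratio (treated/control). Regions whose absolute scaled ratio exceeds
#' `bound` are flagged: calls driven by a sequencing-coverage artefact
#' rather than contact redistribution would fail this control.
#'
#' @param control,treated `contact_map`s on the same genome.
#' @param regions an `interval_set` of regions to check (may be empty).
#' @param bound flagging bound on `|mean log2 ratio|` (default 0.3).
#' @return list of class `coverage_report` with `per_bin` and `per_region`
#'   data.frames.
#' @export
coverage_report <- function(control, treated, regions = interval_set(),
                            bound = 0.3) {
  if (!same_genome(control$genome, treated$genome)) {
    stop("maps are on different genomes")
  }
  g <- control$genome
  sc <- overall_sum(control); st <- overall_sum(treated)
  per_bin <- do.call(rbind, lapply(g$chrom_names, function(ch) {
    cr <- rowSums(control$cis[[ch]])
    tr <- rowSums(treated$cis[[ch]])
    data.frame(chrom = ch, bin = seq_along(cr) - 1L,
               start_bp = (seq_along(cr) - 1L) * g$bin_size_bp,
               control_raw = cr, treated_raw = tr,
               control_scaled = cr / sc, treated_scaled = tr / st,
               stringsAsFactors = FALSE)
  }))
  rownames(per_bin) <- NULL
  if (!nrow(regions)) {
    warning("empty region set: coverage report has no per-region component")
    per_region <- data.frame(chrom = character(), start_bp = numeric(),
                             end_bp = numeric(), name = character(),
                             mean_log2_scaled = numeric(),
                             mean_log2_raw = numeric(), flagged = logical(),
                             stringsAsFactors = FALSE)
  } else {
    masks <- intervals_to_bins(regions, g)
    per_region <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
      ch <- regions$chrom[i]
      one <- intervals_to_bins(regions[i, , drop = FALSE], g)[[ch]]
      sub <- per_bin[per_bin$chrom == ch, ][one, , drop = FALSE]
      ok_s <- sub$control_scaled > 0 & sub$treated_scaled > 0
      ok_r <- sub$control_raw > 0 & sub$treated_raw > 0
      m_s <- if (any(ok_s)) mean(log2(sub$treated_scaled[ok_s] / sub$control_scaled[ok_s])) else NA_real_
      m_r <- if (any(ok_r)) mean(log2(sub$treated_raw[ok_r] / sub$control_raw[ok_r])) else NA_real_
      data.frame(chrom = ch, start_bp = regions$start_bp[i],
                 end_bp = regions$end_bp[i], name = regions$name[i],
                 mean_log2_scaled = m_s, mean_log2_raw = m_r,
                 flagged = is.finite(m_s) && abs(m_s) > bound,
                 stringsAsFactors = FALSE)
    }))
    rownames(per_region) <- NULL
  }
  structure(list(per_bin = per_bin, per_region = per_region, bound = bound,
                 scaling_totals = c(control = sc, treated = st)),
            class = "coverage_report")
}
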