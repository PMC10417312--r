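#' Construct an interval set
#'
#' A plain data.frame of genomic intervals in 0-based half-open
#' coordinates (the BED convention), optionally carrying a name and score.
#'
#' @param chrom chromosome names.
#' @param start_bp 0-based start coordinates.
#' @param end_bp end coordinates (exclusive); must exceed `start_bp`.
#' @param name optional record names.
#' @param score optional numeric scores.
#' @return data.frame of class `interval_set`.
#' @export
interval_set <- function(chrom = character(), start_bp = numeric(),
                         end_bp = numeric(), name = NULL, score = NULL) {
  n <- length(chrom)
  if (length(start_bp) != n || length(end_bp) != n) {
    stop("chrom, start_bp and end_bp must have equal length")
  }
  if (is.null(name)) name <- if (n) paste0("iv_", seq_len(n)) else character()
  if (is.null(score)) score <- rep(0, n)
  if (n && any(!is.finite(start_bp) | !is.finite(end_bp))) {
    stop("non-finite interval coordinates")
  }
  if (n && any(start_bp >= end_bp)) {
    stop("interval start must be < end (0-based half-open)")
  }
  if (n && any(start_bp < 0)) stop("negative interval start")
  structure(data.frame(chrom = as.character(chrom), start_bp = as.numeric(start_bp),
                       end_bp = as.numeric(end_bp), name = as.character(name),
                       score = as.numeric(score), stringsAsFactors = FALSE),
            class = c("interval_set", "data.frame"))
}

as_interval_set <- function(df) {
  interval_set(df$chrom, df$start_bp, df$end_bp,
               name = if ("name" %in% names(df)) df$name else NULL,
               score = if ("score" %in% names(df)) df$score else NULL)
}

#' Sort an interval set by chromosome then start
#' @param set an `interval_set`.
#' @param genome optional `genome_model` fixing the chromosome order.
#' @return sorted `interval_set`.
#' @export
sort_intervals <- function(set, genome = NULL) {
  lv <- if (is.null(genome)) sort(unique(set$chrom)) else genome$chrom_names
  o <- order(factor(set$chrom, levels = lv), set$start_bp, set$end_bp)
  as_interval_set(set[o, , drop = FALSE])
}

#' Read a BED3+ file
#'
#' Accepts BED3 minimum with optional name and score columns; `track`,
#' `browser` and `#` comment lines are skipped. Coordinates are kept
#' 0-based half-open exactly as stored.
#'
#' @param path path to a BED file.
#' @return an `interval_set`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(#|track\\b|browser\\b)", lines)
  idx <- which(keep)
  if (!length(idx)) return(interval_set())
  fields <- strsplit(lines[idx], "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("BED line %d has fewer than 3 fields", idx[which(nf < 3)[1]]))
  }
  chrom <- vapply(fields, `[`, "", 1L)
  s_chr <- vapply(fields, `[`, "", 2L)
  e_chr <- vapply(fields, `[`, "", 3L)
  bad <- !grepl("^[0-9]+$", s_chr) | !grepl("^[0-9]+$", e_chr)
  if (any(bad)) {
    stop(sprintf("non-integer coordinate on BED line %d", idx[which(bad)[1]]))
  }
  start <- as.numeric(s_chr); end <- as.numeric(e_chr)
  rev <- start >= end
  if (any(rev)) {
    stop(sprintf("start >= end on BED line %d", idx[which(rev)[1]]))
  }
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))], ""), NA)
  name <- ifelse(is.na(name) | name == "", paste0("iv_", seq_along(chrom)), name)
  score <- ifelse(nf >= 5, suppressWarnings(
    as.numeric(vapply(fields, function(f) f[min(5, length(f))], ""))), 0)
  score[is.na(score)] <- 0
  interval_set(chrom, start, end, name = name, score = score)
}

#' Write an interval set as BED
#'
#' Emits BED5 (chrom, start, end, name, score) with deterministic
#' formatting; byte-identical output for identical input.
#'
#' @param set an `interval_set`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_bed <- function(set, path) {
  fmt_int <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- if (nrow(set)) {
    sprintf("%s\t%s\t%s\t%s\t%s", set$chrom, fmt_int(set$start_bp),
            fmt_int(set$end_bp), set$name, fmt_int(set$score))
  } else character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Merge overlapping or adjacent intervals
#' @param set an `interval_set`.
#' @param gap_bp merge intervals separated by at most this many bp (0 =
#'   touching intervals merge).
#' @return merged, sorted `interval_set`.
#' @export
merge_intervals <- function(set, gap_bp = 0) {
  if (!nrow(set)) return(set)
  out <- lapply(split(set, set$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start_bp + 1, end = d$end_bp),
                          min.gapwidth = gap_bp + 1)
    data.frame(chrom = d$chrom[1], start_bp = IRanges::start(ir) - 1,
               end_bp = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  sort_intervals(interval_set(df$chrom, df$start_bp, df$end_bp))
}

#' Mark bins overlapped by intervals
#'
#' A bin is marked when it overlaps at least one interval by at least 1 bp
#' under the half-open convention, so the interval `[0, bin_size)` marks
#' bin 0 only. Intervals extending past the chromosome end are clipped
#' with a warning.
#'
#' @param set an `interval_set`.
#' @param genome a `genome_model`; all interval chromosomes must be known.
#' @return named list of logical vectors, one per chromosome.
#' @export
intervals_to_bins <- function(set, genome) {
  stopifnot(inherits(genome, "genome_model"))
  masks <- lapply(genome$chrom_names, function(ch) logical(genome$n_bins[[ch]]))
  names(masks) <- genome$chrom_names
  if (!nrow(set)) return(masks)
  unknown <- setdiff(unique(set$chrom), genome$chrom_names)
  if (length(unknown)) stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  bs <- genome$bin_size_bp
  clipped <- FALSE
  for (i in seq_len(nrow(set))) {
    ch <- set$chrom[i]
    len <- genome$chrom_lengths_bp[[ch]]
    s <- set$start_bp[i]; e <- set$end_bp[i]
    if (e > len) { clipped <- TRUE; e <- len }
    if (s >= len) { clipped <- TRUE; next }
    b0 <- floor(s / bs); b1 <- ceiling(e / bs) - 1
    masks[[ch]][(b0:b1) + 1] <- TRUE
  }
  if (clipped) warning("interval(s) beyond chromosome end were clipped")
  masks
}
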