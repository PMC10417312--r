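#' Construct a binned contact map
#'
#' Per-chromosome symmetric non-negative count matrices (cis blocks) with
#' optional inter-chromosomal (trans) blocks. Counts need not be integers:
#' scaled and expected maps reuse the same container.
#'
#' @param genome a `genome_model`.
#' @param cis named list of square symmetric matrices, one per chromosome,
#'   dimension equal to the chromosome's bin count. Missing chromosomes are
#'   filled with zeros.
#' @param trans optional named list of matrices keyed `"chromA|chromB"`
#'   (genome order), rows = first chromosome's bins.
#' @param metadata free-form provenance list.
#' @return object of class `contact_map`.
#' @export
contact_map <- function(genome, cis = list(), trans = NULL, metadata = list()) {
  stopifnot(inherits(genome, "genome_model"))
  full <- lapply(genome$chrom_names, function(ch) {
    n <- genome$n_bins[[ch]]
    m <- cis[[ch]]
    if (is.null(m)) m <- matrix(0, n, n)
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != n) {
      stop(sprintf("cis block for %s must be %d x %d", ch, n, n))
    }
    if (any(!is.finite(m)) || any(m < 0)) {
      stop(sprintf("cis block for %s has non-finite or negative entries", ch))
    }
    if (!identical(dim(m), dim(t(m))) || any(m != t(m))) {
      stop(sprintf("cis block for %s is not symmetric", ch))
    }
    dimnames(m) <- NULL
    m
  })
  names(full) <- genome$chrom_names
  if (!is.null(trans)) {
    for (key in names(trans)) {
      chs <- strsplit(key, "|", fixed = TRUE)[[1]]
      if (length(chs) != 2 || !all(chs %in% genome$chrom_names)) {
        stop("bad trans block key: ", key)
      }
      m <- trans[[key]]
      if (nrow(m) != genome$n_bins[[chs[1]]] || ncol(m) != genome$n_bins[[chs[2]]]) {
        stop("trans block dimensions do not match genome: ", key)
      }
      if (any(!is.finite(m)) || any(m < 0)) {
        stop("trans block has non-finite or negative entries: ", key)
      }
    }
  }
  structure(list(genome = genome, cis = full, trans = trans,
                 metadata = metadata), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d chromosome(s), %d bins, total cis count %s\n",
              length(x$cis), total_bins(x$genome),
              format(sum(vapply(x$cis, sum, 0)), digits = 6)))
  invisible(x)
}

trans_key <- function(genome, ch1, ch2) {
  o <- match(c(ch1, ch2), genome$chrom_names)
  if (o[1] <= o[2]) paste0(ch1, "|", ch2) else paste0(ch2, "|", ch1)
}

#' Read a contact map from the TSV triple format
#'
#' The format is one header line `chrom1 bin1 chrom2 bin2 count` followed
#' by tab-separated pixels with 0-based per-chromosome bin indices.
#' Unlisted pixels are zero; each unordered pixel pair may appear once and
#' is mirrored on loading.
#'
#' @param path input file.
#' @param genome a `genome_model` naming every chromosome in the file.
#' @return a `contact_map`.
#' @export
read_contact_tsv <- function(path, genome) {
  stopifnot(inherits(genome, "genome_model"))
  lines <- readLines(path)
  if (!length(lines)) stop("empty contact file (missing header): ", path)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  cis <- lapply(genome$chrom_names, function(ch) {
    n <- genome$n_bins[[ch]]; matrix(0, n, n)
  })
  names(cis) <- genome$chrom_names
  trans <- list()
  if (length(body)) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 5)) {
      stop(sprintf("malformed contact line %d (expected 5 tab-separated fields)",
                   which(nf != 5)[1] + 1L))
    }
    c1 <- vapply(fields, `[`, "", 1L); c2 <- vapply(fields, `[`, "", 3L)
    b1 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
    b2 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4L)))
    cnt <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
    bad_ch <- !(c1 %in% genome$chrom_names) | !(c2 %in% genome$chrom_names)
    if (any(bad_ch)) {
      stop(sprintf("unknown chromosome on line %d: %s", which(bad_ch)[1] + 1L,
                   body[which(bad_ch)[1]]))
    }
    if (any(is.na(b1) | is.na(b2))) {
      stop(sprintf("non-integer bin index on line %d", which(is.na(b1) | is.na(b2))[1] + 1L))
    }
    oob <- b1 < 0 | b2 < 0 | b1 >= genome$n_bins[c1] | b2 >= genome$n_bins[c2]
    if (any(oob)) stop(sprintf("bin index out of range on line %d", which(oob)[1] + 1L))
    if (any(is.na(cnt))) stop(sprintf("non-numeric count on line %d", which(is.na(cnt))[1] + 1L))
    if (any(cnt < 0)) stop(sprintf("negative count on line %d", which(cnt < 0)[1] + 1L))
    if (any(cnt == 0)) stop(sprintf("zero count on line %d (omit zero pixels)",
                                    which(cnt == 0)[1] + 1L))
    # canonical unordered key for duplicate detection
    swap <- match(c1, genome$chrom_names) > match(c2, genome$chrom_names) |
      (c1 == c2 & b1 > b2)
    k1 <- ifelse(swap, c2, c1); k2 <- ifelse(swap, c1, c2)
    j1 <- ifelse(swap, b2, b1); j2 <- ifelse(swap, b1, b2)
    key <- paste(k1, j1, k2, j2, sep = ":")
    if (anyDuplicated(key)) {
      stop(sprintf("duplicate pixel on line %d: %s",
                   which(duplicated(key))[1] + 1L, key[which(duplicated(key))[1]]))
    }
    is_cis <- k1 == k2
    for (ch in unique(k1[is_cis])) {
      i <- which(is_cis & k1 == ch)
      m <- cis[[ch]]
      m[cbind(j1[i] + 1, j2[i] + 1)] <- cnt[i]
      m[cbind(j2[i] + 1, j1[i] + 1)] <- cnt[i]
      cis[[ch]] <- m
    }
    if (any(!is_cis)) {
      tk <- paste0(k1, "|", k2)
      for (key2 in unique(tk[!is_cis])) {
        i <- which(!is_cis & tk == key2)
        chs <- strsplit(key2, "|", fixed = TRUE)[[1]]
        m <- matrix(0, genome$n_bins[[chs[1]]], genome$n_bins[[chs[2]]])
        m[cbind(j1[i] + 1, j2[i] + 1)] <- cnt[i]
        trans[[key2]] <- m
      }
    }
  }
  contact_map(genome, cis, trans = if (length(trans)) trans else NULL,
              metadata = list(source = path))
}

#' Write a contact map in the TSV triple format
#'
#' Emits non-zero upper-triangle cis pixels (`bin1 <= bin2`) and trans
#' pixels once each, sorted by genome order; output is byte-deterministic.
#'
#' @param map a `contact_map`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_contact_tsv <- function(map, path) {
  fmt <- function(x) sprintf("%.15g", x)
  lines <- "chrom1\tbin1\tchrom2\tbin2\tcount"
  for (ch in map$genome$chrom_names) {
    m <- map$cis[[ch]]
    sel <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
    if (nrow(sel)) {
      o <- order(sel[, 1], sel[, 2])
      sel <- sel[o, , drop = FALSE]
      lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t%s", ch, sel[, 1] - 1L,
                                ch, sel[, 2] - 1L, fmt(m[sel])))
    }
  }
  if (!is.null(map$trans)) {
    keys <- names(map$trans)
    ord <- order(match(vapply(strsplit(keys, "|", fixed = TRUE), `[`, "", 1L),
                       map$genome$chrom_names),
                 match(vapply(strsplit(keys, "|", fixed = TRUE), `[`, "", 2L),
                       map$genome$chrom_names))
    for (key in keys[ord]) {
      chs <- strsplit(key, "|", fixed = TRUE)[[1]]
      m <- map$trans[[key]]
      sel <- which(m != 0, arr.ind = TRUE)
      if (nrow(sel)) {
        o <- order(sel[, 1], sel[, 2])
        sel <- sel[o, , drop = FALSE]
        lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t%s", chs[1], sel[, 1] - 1L,
                                  chs[2], sel[, 2] - 1L, fmt(m[sel])))
      }
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Coarsen a contact map to a larger bin size
#'
#' Sums counts over `factor x factor` blocks; the total count is conserved
#' exactly. The last, possibly smaller, block of each chromosome is kept.
#'
#' @param map a `contact_map`.
#' @param factor integer >= 2.
#' @return a `contact_map` on a genome with bin size multiplied by `factor`.
#' @export
coarsen_map <- function(map, factor) {
  if (length(factor) != 1 || !is.finite(factor) || factor < 2 ||
      factor != as.integer(factor)) {
    stop("factor must be an integer >= 2")
  }
  factor <- as.integer(factor)
  g <- map$genome
  g2 <- genome_model(g$chrom_names, g$chrom_lengths_bp, g$bin_size_bp * factor,
                     autosome = unname(g$autosome))
  cis2 <- lapply(g$chrom_names, function(ch) {
    m <- map$cis[[ch]]
    grp <- floor((seq_len(nrow(m)) - 1) / factor)
    m2 <- rowsum(m, grp)
    m2 <- t(rowsum(t(m2), grp))
    dimnames(m2) <- NULL
    m2
  })
  names(cis2) <- g$chrom_names
  trans2 <- NULL
  if (!is.null(map$trans)) {
    trans2 <- lapply(names(map$trans), function(key) {
      chs <- strsplit(key, "|", fixed = TRUE)[[1]]
      m <- map$trans[[key]]
      m2 <- rowsum(m, floor((seq_len(nrow(m)) - 1) / factor))
      m2 <- t(rowsum(t(m2), floor((seq_len(ncol(m)) - 1) / factor)))
      dimnames(m2) <- NULL
      m2
    })
    names(trans2) <- names(map$trans)
  }
  contact_map(g2, cis2, trans = trans2,
              metadata = c(map$metadata, list(coarsened_by = factor)))
}

#' Iterative-correction balancing (plumbing)
#'
#' A simple iterative proportional fitting of each cis block so that all
#' row/column sums become equal, in the spirit of ICE matrix balancing.
#' Provided for inspection and display only; the region-calling pipeline
#' operates on raw sum-scaled maps.
#'
#' @param map a `contact_map`.
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on the coefficient of variation of the
#'   non-zero marginals.
#' @return a `contact_map` with balanced (non-count) cis blocks.
#' @export
ic_balance <- function(map, max_iter = 200, tol = 1e-6) {
  cis2 <- lapply(map$genome$chrom_names, function(ch) {
    m <- map$cis[[ch]]
    if (sum(m) == 0) return(m)
    for (i in seq_len(max_iter)) {
      s <- rowSums(m)
      nz <- s > 0
      if (!any(nz)) break
      cv <- stats::sd(s[nz]) / mean(s[nz])
      if (is.na(cv) || cv < tol) break
      s_norm <- s / mean(s[nz])
      s_norm[!nz] <- 1
      m <- m / outer(s_norm, s_norm)
    }
    m
  })
  names(cis2) <- map$genome$chrom_names
  contact_map(map$genome, cis2, trans = map$trans,
              metadata = c(map$metadata, list(balanced = "iterative_correction")))
}
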