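#' Genome model with a fixed bin grid
#'
#' Holds chromosome names, lengths and a single bin size that together
#' define a genome-wide bin index. Bins are half-open intervals
#' `[k*bin_size, (k+1)*bin_size)`; the last bin of each chromosome may be
#' shorter than `bin_size_bp`. Chromosomes flagged as autosomes are the
#' only ones that contribute to map scaling totals downstream.
#'
#' @param chrom_names character vector of unique chromosome identifiers.
#' @param chrom_lengths_bp positive chromosome lengths in bp.
#' @param bin_size_bp positive bin size in bp.
#' @param autosome logical per chromosome; defaults to all `TRUE`.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chrom_names, chrom_lengths_bp, bin_size_bp,
                         autosome = rep(TRUE, length(chrom_names))) {
  chrom_names <- as.character(chrom_names)
  if (length(chrom_names) == 0L) stop("at least one chromosome is required")
  if (anyDuplicated(chrom_names)) stop("duplicated chromosome names")
  if (length(chrom_lengths_bp) != length(chrom_names) ||
      length(autosome) != length(chrom_names)) {
    stop("chrom_lengths_bp and autosome must match chrom_names in length")
  }
  if (any(!is.finite(chrom_lengths_bp)) || any(chrom_lengths_bp <= 0)) {
    stop("all chromosome lengths must be positive")
  }
  if (!is.finite(bin_size_bp) || bin_size_bp <= 0) {
    stop("bin_size_bp must be positive")
  }
  n_bins <- as.integer(ceiling(chrom_lengths_bp / bin_size_bp))
  structure(list(
    chrom_names      = chrom_names,
    chrom_lengths_bp = stats::setNames(as.numeric(chrom_lengths_bp), chrom_names),
    bin_size_bp      = as.numeric(bin_size_bp),
    autosome         = stats::setNames(as.logical(autosome), chrom_names),
    n_bins           = stats::setNames(n_bins, chrom_names),
    bin_offset       = stats::setNames(
      as.integer(c(0L, cumsum(n_bins))[seq_along(chrom_names)]), chrom_names)
  ), class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %d chromosome(s), bin size %s bp, %d bins total\n",
              length(x$chrom_names), format(x$bin_size_bp, scientific = FALSE),
              sum(x$n_bins)))
  invisible(x)
}

#' Total number of bins in a genome model
#' @param genome a `genome_model`.
#' @param autosomes_only count only autosomal bins.
#' @return integer bin count.
#' @export
total_bins <- function(genome, autosomes_only = FALSE) {
  stopifnot(inherits(genome, "genome_model"))
  if (autosomes_only) sum(genome$n_bins[genome$autosome]) else sum(genome$n_bins)
}

#' Map (chromosome, local bin) to a global bin id
#'
#' Global ids are 0-based and run over chromosomes in genome order.
#'
#' @param genome a `genome_model`.
#' @param chrom chromosome name(s).
#' @param local_bin 0-based bin index within the chromosome.
#' @return 0-based global bin id(s).
#' @export
global_bin_id <- function(genome, chrom, local_bin) {
  stopifnot(inherits(genome, "genome_model"))
  if (!all(chrom %in% genome$chrom_names)) stop("unknown chromosome")
  nb <- genome$n_bins[chrom]
  if (any(local_bin < 0) || any(local_bin >= nb)) stop("bin index out of range")
  unname(genome$bin_offset[chrom] + as.integer(local_bin))
}

#' Locate a global bin id
#'
#' Inverse of [global_bin_id()]: returns the chromosome, local bin index and
#' half-open genomic span of each global id.
#'
#' @param genome a `genome_model`.
#' @param bin_id 0-based global bin id(s).
#' @return data.frame with columns chrom, local_bin, start_bp, end_bp.
#' @export
locate_bin <- function(genome, bin_id) {
  stopifnot(inherits(genome, "genome_model"))
  tot <- total_bins(genome)
  if (any(bin_id < 0) || any(bin_id >= tot)) stop("bin id out of range")
  breaks <- c(unname(genome$bin_offset), tot)
  idx <- findInterval(bin_id, breaks, rightmost.closed = FALSE)
  chrom <- genome$chrom_names[idx]
  local <- as.integer(bin_id - genome$bin_offset[chrom])
  bs <- genome$bin_size_bp
  data.frame(chrom = chrom, local_bin = local,
             start_bp = local * bs,
             end_bp = pmin((local + 1) * bs, genome$chrom_lengths_bp[chrom]),
             row.names = NULL, stringsAsFactors = FALSE)
}

same_genome <- function(a, b) {
  identical(a$chrom_names, b$chrom_names) &&
    isTRUE(all.equal(a$chrom_lengths_bp, b$chrom_lengths_bp)) &&
    isTRUE(all.equal(a$bin_size_bp, b$bin_size_bp)) &&
    identical(a$autosome, b$autosome)
}
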