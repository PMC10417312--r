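test_that("genome model validates input and derives the bin grid", {
  g <- genome_model(c("chr1", "chr2"), c(1.05e6, 2e6), 1e5)
  expect_equal(unname(g$n_bins), c(11L, 20L))
  expect_equal(unname(g$bin_offset), c(0L, 11L))
  expect_equal(total_bins(g), 31L)
  expect_error(genome_model(c("a", "a"), c(1, 1), 1), "duplicated")
  expect_error(genome_model("a", -5, 1), "positive")
  expect_error(genome_model("a", 10, 0), "positive")
  expect_error(genome_model(character(), numeric(), 1), "at least one")
})

test_that("global bin ids and locate_bin are inverse bijections", {
  g <- genome_model(c("chr1", "chr2", "chrX"), c(7e5, 3e5, 4e5), 1e5,
                    autosome = c(TRUE, TRUE, FALSE))
  ids <- 0:(total_bins(g) - 1)
  loc <- locate_bin(g, ids)
  expect_identical(global_bin_id(g, loc$chrom, loc$local_bin), ids)
  expect_equal(loc$start_bp, loc$local_bin * 1e5)
  expect_error(global_bin_id(g, "chr1", 7), "out of range")
  expect_error(locate_bin(g, 14), "out of range")
  expect_equal(total_bins(g, autosomes_only = TRUE), 10L)
})

test_that("interval sets enforce 0-based half-open validity", {
  s <- interval_set("chr1", 0, 100)
  expect_s3_class(s, "interval_set")
  expect_error(interval_set("chr1", 100, 100), "start must be <")
  expect_error(interval_set("chr1", -1, 5), "negative")
  expect_error(interval_set("chr1", c(0, 1), 5), "equal length")
})

test_that("BED round-trips byte-identically and rejects malformed lines", {
  s <- interval_set(c("chr2", "chr1"), c(100, 0), c(900, 500),
                    name = c("b", "a"), score = c(7, 0))
  p <- withr::local_tempfile(fileext = ".bed")
  write_bed(s, p)
  r <- read_bed(p)
  expect_equal(r$start_bp, s$start_bp)
  expect_equal(r$name, s$name)
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(r, p2)
  expect_identical(readBin(p, "raw", file.size(p)),
                   readBin(p2, "raw", file.size(p2)))

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# comment", "chr1\t0\t100", "chr1\t50"), bad)
  expect_error(read_bed(bad), "line 3.*fewer than 3")
  writeLines(c("chr1\t0\tx"), bad)
  expect_error(read_bed(bad), "non-integer.*line 1")
  writeLines(c("chr1\t0\t10", "chr1\t20\t20"), bad)
  expect_error(read_bed(bad), "start >= end.*line 2")
  writeLines(c("track name=x", "browser pos", "#c"), bad)
  expect_equal(nrow(read_bed(bad)), 0)
})

test_that("interval-to-bin marking follows the half-open convention", {
  g <- genome_model("chr1", 1e6, 1e5)
  m <- intervals_to_bins(interval_set("chr1", 0, 1e5), g)
  expect_identical(which(m$chr1), 1L)               # [0, bin) marks bin 0 only
  m <- intervals_to_bins(interval_set("chr1", 99999, 100001), g)
  expect_identical(which(m$chr1), c(1L, 2L))        # 1 bp in each bin
  m <- intervals_to_bins(interval_set("chr1", 1e5, 2e5), g)
  expect_identical(which(m$chr1), 2L)
  expect_warning(intervals_to_bins(interval_set("chr1", 9.5e5, 2e6), g),
                 "clipped")
  expect_error(intervals_to_bins(interval_set("chrZ", 0, 10), g), "unknown")
})

test_that("interval merging joins overlapping and touching intervals", {
  s <- interval_set(rep("chr1", 3), c(0, 50, 200), c(60, 100, 300))
  m <- merge_intervals(s)
  expect_equal(m$start_bp, c(0, 200))
  expect_equal(m$end_bp, c(100, 300))
  m2 <- merge_intervals(s, gap_bp = 100)
  expect_equal(nrow(m2), 1)
})

test_that("contact TSV round-trips byte-identically", {
  tp <- tiny_pair()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_contact_tsv(tp$control, p)
  r <- read_contact_tsv(p, tp$genome)
  expect_equal(r$cis, tp$control$cis)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_contact_tsv(r, p2)
  expect_identical(readBin(p, "raw", file.size(p)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("contact TSV reader rejects malformed input with line numbers", {
  g <- genome_model(c("chr1", "chr2"), c(3e5, 3e5), 1e5)
  hdr <- "chrom1\tbin1\tchrom2\tbin2\tcount"
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hdr, "chr1\t0\tchr9\t0\t5"), p)
  expect_error(read_contact_tsv(p, g), "unknown chromosome on line 2")
  writeLines(c(hdr, "chr1\t0\tchr1\t1\t5", "chr1\t5\tchr1\t0\t2"), p)
  expect_error(read_contact_tsv(p, g), "out of range on line 3")
  writeLines(c(hdr, "chr1\t0\tchr1\t1\t5", "chr1\t1\tchr1\t0\t2"), p)
  expect_error(read_contact_tsv(p, g), "duplicate pixel on line 3")
  writeLines(c(hdr, "chr1\t0\tchr1\t1\t0"), p)
  expect_error(read_contact_tsv(p, g), "zero count on line 2")
  writeLines(c(hdr, "chr1\t0\tchr1\t1\t-3"), p)
  expect_error(read_contact_tsv(p, g), "negative count on line 2")
  writeLines(c(hdr, "chr1\t0\tchr1\t5"), p)
  expect_error(read_contact_tsv(p, g), "malformed contact line 2")
  writeLines(hdr, p)
  expect_equal(sum(read_contact_tsv(p, g)$cis$chr1), 0)
})

test_that("trans pixels round-trip and contribute to overall sums", {
  g <- genome_model(c("chr1", "chr2"), c(2e5, 2e5), 1e5)
  tr <- list("chr1|chr2" = matrix(c(3, 0, 0, 4), 2, 2))
  m <- contact_map(g, list(chr1 = diag(2) * 2, chr2 = matrix(1, 2, 2)), trans = tr)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_contact_tsv(m, p)
  r <- read_contact_tsv(p, g)
  expect_equal(r$trans[["chr1|chr2"]], tr[["chr1|chr2"]])
  # cis off-diagonal (chr2: 1 pixel) + trans (7); diagonals excluded
  expect_equal(overall_sum(r), 1 + 7)
})

test_that("coarsening conserves total counts exactly", {
  tp <- tiny_pair(seed = 9, n_bins = 41)
  cm <- coarsen_map(tp$control, 4)
  expect_equal(cm$genome$bin_size_bp, 4e5)
  expect_equal(unname(cm$genome$n_bins), 11L)
  expect_equal(sum(cm$cis$chrT), sum(tp$control$cis$chrT))
  expect_true(all(cm$cis$chrT == t(cm$cis$chrT)))
  expect_error(coarsen_map(tp$control, 1.5), "integer")
})

test_that("contact map constructor rejects invalid blocks", {
  g <- genome_model("chr1", 3e5, 1e5)
  expect_error(contact_map(g, list(chr1 = matrix(0, 2, 2))), "must be 3 x 3")
  bad <- matrix(0, 3, 3); bad[1, 2] <- 1
  expect_error(contact_map(g, list(chr1 = bad)), "not symmetric")
  bad2 <- matrix(-1, 3, 3)
  expect_error(contact_map(g, list(chr1 = bad2)), "negative")
})

test_that("iterative balancing equalizes marginals", {
  tp <- tiny_pair(seed = 5)
  b <- ic_balance(tp$control)
  s <- rowSums(b$cis$chrT)
  s <- s[s > 0]
  expect_lt(stats::sd(s) / mean(s), 1e-5)
})
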