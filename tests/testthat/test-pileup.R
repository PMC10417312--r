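test_that("pileup configuration is validated", {
  expect_error(pileup_config(grid_n = 10), "odd")
  expect_error(pileup_config(grid_n = 7), ">= 9")
  expect_error(pileup_config(flank_bp = 0), "positive")
})

test_that("observed/expected windows are flat on distance-only maps", {
  g <- genome_model("chr1", 2e6, 1e5)
  n <- 20
  M <- outer(1:n, 1:n, function(i, j) 2 / (abs(i - j) + 1))
  m <- contact_map(g, list(chr1 = M))
  w <- oe_window(m, "chr1", 5e5, 1.5e6)
  expect_equal(dim(w), c(10, 10))
  expect_true(all(abs(w - 1) < 1e-12))
  raw <- oe_window(m, "chr1", 5e5, 1.5e6, oe = FALSE)
  expect_equal(raw, M[6:15, 6:15])
  expect_error(oe_window(m, "chr1", -1e5, 5e5), "outside chromosome")
  expect_error(oe_window(m, "chr9", 0, 5e5), "unknown chromosome")
})

test_that("grid rescaling takes exact block means and respects bands", {
  m <- matrix(1:16, 4, 4)
  out <- rescale_grid(m, grid_n = 2)
  expect_equal(out, rbind(c(mean(m[1:2, 1:2]), mean(m[1:2, 3:4])),
                          c(mean(m[3:4, 1:2]), mean(m[3:4, 3:4]))))
  # identity when sizes match
  expect_equal(rescale_grid(m, grid_n = 4), m)
  # banded rescale keeps band boundaries: 1+2+1 input -> 1+1+1 output
  mb <- matrix(0, 4, 4); mb[2:3, 2:3] <- 6
  outb <- rescale_grid(mb, bands_in = c(1, 2, 1), bands_out = c(1, 1, 1))
  expect_equal(outb[2, 2], 6)
  expect_equal(outb[1, 1], 0)
  # masked pixels are excluded from block means
  mn <- matrix(c(1, NA, NA, 5), 2, 2)
  expect_equal(rescale_grid(mn, grid_n = 1)[1, 1], 3)
  allna <- matrix(NA_real_, 2, 2)
  expect_true(is.na(rescale_grid(allna, grid_n = 1)[1, 1]))
})

test_that("region pileups skip windows that leave the chromosome", {
  tp <- tiny_pair(seed = 13, n_bins = 60)
  regions <- interval_set(rep("chrT", 2), c(0, 2.5e6), c(1e6, 3.5e6),
                          name = c("edge", "ok"))
  cfg <- pileup_config(flank_bp = 1e6, grid_n = 9)
  res <- pileup_regions(tp$control, regions, cfg)
  expect_equal(res$n_stacked, 1)
  expect_equal(res$skipped$name, "edge")
  expect_match(res$skipped$reason, "outside chromosome")
  expect_equal(dim(res$grid), c(9, 9))
  expect_error(pileup_regions(tp$control, interval_set()), "no regions")
})

test_that("relative insulation recovers a constructed block contrast", {
  # grid with intra quadrants 4 and inter quadrant 1 -> RI = log2(4)
  grid <- matrix(1, 12, 12)
  grid[1:6, 1:6] <- 4; grid[7:12, 7:12] <- 4
  res <- structure(list(grid = grid, region_span_cols = 1:12,
                        relative_insulation = NA, mode = "rescaled_region"),
                   class = "pileup_result")
  ri <- relative_insulation(res)
  expect_equal(ri$ri, 2)
  expect_equal(ri$intra, 4)
  expect_equal(ri$inter, 1)
})

test_that("anchor pileups stack fixed windows centered on midpoints", {
  g <- genome_model("chr1", 4e6, 1e5)
  n <- 40
  M <- outer(1:n, 1:n, function(i, j) 1 / (abs(i - j) + 1))
  m <- contact_map(g, list(chr1 = M))
  anchors <- interval_set(rep("chr1", 3), c(1.9e6, 2.4e6, 0),
                          c(2.1e6, 2.6e6, 2e5),
                          name = c("a", "b", "edge"))
  cfg <- pileup_config(flank_bp = 5e5, grid_n = 9)
  res <- pileup_anchors(m, anchors, cfg)
  expect_equal(res$n_stacked, 2)
  expect_equal(dim(res$grid), c(11, 11))  # 2 * 5 bins + 1
  # on a distance-only map every o/e window is 1
  expect_true(all(abs(res$grid - 1) < 1e-12))
  expect_equal(res$skipped$name, "edge")
})

test_that("pileup TSV export is deterministic", {
  tp <- tiny_pair(seed = 14, n_bins = 60)
  regions <- interval_set("chrT", 2.5e6, 3.5e6)
  res <- pileup_regions(tp$control, regions, pileup_config(grid_n = 9))
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_pileup_tsv(res, p1); write_pileup_tsv(res, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_equal(length(readLines(p1)), 9)
})
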