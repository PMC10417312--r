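make_diff <- function(values, mask = NULL, bin = 1e5) {
  n <- nrow(values)
  g <- genome_model("chr1", n * bin, bin)
  if (is.null(mask)) mask <- !is.na(values)
  structure(list(genome = g, values = list(chr1 = values),
                 mask = list(chr1 = mask),
                 scaling_totals = c(control = 1, treated = 1),
                 policy = "mask", pseudocount = NULL),
            class = "diff_map")
}

test_that("window scores match a hand-computed example", {
  v <- matrix(0, 4, 4)
  v[1, 2] <- v[2, 1] <- 1
  v[1, 3] <- v[3, 1] <- 2
  v[2, 3] <- v[3, 2] <- 4
  v[3, 4] <- v[4, 3] <- -1
  d <- make_diff(v)
  tr <- window_scores(d, w = 3)
  # window at bin 0: pixels (1,2)+(1,3)+(2,3) = 1+2+4; window at bin 1:
  # (2,3)+(2,4)+(3,4) = 4+0-1
  expect_equal(tr$score, c(7, 3))
  expect_equal(tr$start_bin, c(0L, 1L))
  expect_equal(tr$valid_fraction, c(1, 1))
})

test_that("masked pixels contribute zero and lower the valid fraction", {
  v <- matrix(1, 4, 4)
  v[1, 3] <- v[3, 1] <- NA
  d <- make_diff(v)
  tr <- window_scores(d, w = 3)
  expect_equal(tr$score, c(2, 3))
  expect_equal(tr$valid_fraction, c(2 / 3, 1))
})

test_that("short chromosomes are skipped with a warning", {
  g <- genome_model(c("chr1", "chr2"), c(3e5, 20e5), 1e5)
  vals <- list(chr1 = matrix(0, 3, 3), chr2 = matrix(0, 20, 20))
  d <- structure(list(genome = g, values = vals,
                      mask = lapply(vals, function(m) !is.na(m)),
                      scaling_totals = c(control = 1, treated = 1),
                      policy = "mask", pseudocount = NULL), class = "diff_map")
  expect_warning(tr <- window_scores(d, w = 10), "chr1.*skipped")
  expect_true(all(tr$chrom == "chr2"))
  expect_error(window_scores(d, w = 1), ">= 2")
})

test_that("threshold selection follows the score distribution", {
  tr <- structure(data.frame(chrom = "chr1", start_bin = 0:199,
                             score = seq(-100, 99.5), valid_fraction = 1),
                  class = c("window_score_track", "data.frame"),
                  w = 10L, genome = genome_model("chr1", 2.1e7, 1e5))
  thr <- choose_threshold(tr, "quantile", 0.01, "decrease")
  expect_equal(as.numeric(thr), unname(quantile(tr$score, 0.01)))
  thr_up <- choose_threshold(tr, "quantile", 0.01, "increase")
  expect_equal(as.numeric(thr_up), unname(quantile(tr$score, 0.99)))
  ms <- choose_threshold(tr, "mean_sd", 2, "decrease")
  expect_equal(as.numeric(ms), mean(tr$score) - 2 * sd(tr$score))
  short <- tr[1:50, ]
  attr(short, "w") <- 10L
  expect_error(choose_threshold(short, "quantile", 0.01), "fewer than 100")
  expect_error(choose_threshold(tr, "quantile", 2), "in \\[0, 1\\]")
})

test_that("region calling merges overlapping windows and clips at chromosome ends", {
  g <- genome_model("chr1", 3e6, 1e5)  # 30 bins
  tr <- structure(data.frame(chrom = "chr1", start_bin = 0:20,
                             score = 0, valid_fraction = 1),
                  class = c("window_score_track", "data.frame"),
                  w = 10L, genome = g)
  tr$score[tr$start_bin %in% c(2, 3, 4)] <- -50   # one merged run
  tr$score[tr$start_bin == 20] <- -60             # touches the chromosome end
  reg <- call_regions(tr, threshold = -40, direction = "decrease")
  expect_equal(nrow(reg), 2)
  expect_equal(reg$start_bp, c(2e5, 2e6))
  # first region: [2, 4 + 10) bins; second clipped to the 30-bin chromosome
  expect_equal(reg$end_bp, c(1.4e6, 3e6))
  expect_equal(reg$score, c(-50, -60))
})

test_that("windows separated by more than w do not merge; low-validity windows never call", {
  g <- genome_model("chr1", 5e6, 1e5)  # 50 bins
  tr <- structure(data.frame(chrom = "chr1", start_bin = 0:40,
                             score = 0, valid_fraction = 1),
                  class = c("window_score_track", "data.frame"),
                  w = 10L, genome = g)
  tr$score[tr$start_bin %in% c(0, 11)] <- -50  # gap 11 > w: two regions
  reg <- call_regions(tr, -40)
  expect_equal(nrow(reg), 2)
  tr$score[tr$start_bin %in% c(0, 10)] <- -50  # gap 10 <= w: one region
  tr$score[tr$start_bin == 11] <- 0
  reg <- call_regions(tr, -40)
  expect_equal(nrow(reg), 1)
  tr$valid_fraction[tr$start_bin == 10] <- 0.2
  reg <- call_regions(tr, -40, min_valid_fraction = 0.5)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$end_bp, 1e6)  # run now ends at window 0
  # empty call set is a valid result
  none <- call_regions(tr, -1e9)
  expect_equal(nrow(none), 0)
  expect_s3_class(none, "differential_regions")
})

test_that("recovery evaluation computes exact Jaccard indices", {
  truth <- interval_set(rep("chr1", 2), c(0, 1000), c(100, 1100),
                        name = c("t1", "t2"))
  called <- interval_set(rep("chr1", 2), c(50, 5000), c(150, 5100),
                         name = c("c1", "c2"))
  rec <- evaluate_recovery(called, truth, j0 = 0.25)
  # t1 vs c1: intersection 50, union 150 -> J = 1/3; t2 untouched
  expect_equal(rec$truth_jaccard$jaccard, c(1 / 3, 0))
  expect_equal(rec$recall, 0.5)
  expect_equal(rec$precision, 0.5)
})
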