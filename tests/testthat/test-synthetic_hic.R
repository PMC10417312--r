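test_that("sim_config validates its parameters", {
  g <- genome_model("chr1", 1e6, 1e5)
  expect_error(sim_config(g, tad_partition = list(chr1 = c(5L, 4L))), "tile")
  expect_error(sim_config(g, delta = 0), "delta")
  expect_error(sim_config(g, delta = 1.2), "delta")
  expect_error(sim_config(g, beta = 0.5), "beta")
  expect_error(sim_config(g, alpha = -1), "alpha")
  expect_error(sim_config(g, tad_partition = list(chr1 = c(5L, 5L)),
                          planted_pairs = data.frame(chrom = "chr1",
                                                     left_domain = 2L)),
               "adjacent")
})

test_that("expected matrices encode decay, TAD blocks and planted depletion", {
  g <- genome_model("chr1", 1e6, 1e5)
  cfg <- sim_config(g, alpha = 1, tad_partition = list(chr1 = c(5L, 5L)),
                    beta = 3, delta = 0.5,
                    planted_pairs = data.frame(chrom = "chr1", left_domain = 1L))
  ec <- build_expected(cfg, "control")$chr1
  et <- build_expected(cfg, "treated")$chr1
  expect_true(all(ec == t(ec)))
  # decay with distance inside a domain: E[1,1]/E[1,2] = 2
  expect_equal(ec[1, 1] / ec[1, 2], 2)
  # same-domain enrichment: pixels (1,2) and (1,7) are both at distance
  # landmarks with E = beta * (d+1)^-1 and (d+1)^-1 respectively
  expect_equal(ec[1, 2], 3 * 2^-1)
  expect_equal(ec[1, 7], 7^-1)
  # planted inter-domain rectangle halved in treated only
  expect_equal(et[1:5, 6:10], ec[1:5, 6:10] * 0.5)
  expect_equal(et[1:5, 1:5], ec[1:5, 1:5])
  expect_equal(et[6:10, 6:10], ec[6:10, 6:10])
})

test_that("compaction tilt multiplies treated off-diagonal pixels only", {
  cfg <- compaction_config(seed = 1, gamma = 0.3)
  ec <- build_expected(cfg, "control")$chr1
  et <- build_expected(cfg, "treated")$chr1
  n <- nrow(ec)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  off <- d > 0
  tilt <- (d[off] * 1e5 / 3e6)^-0.3
  expect_equal(et[off], ec[off] * tilt)
  expect_equal(diag(et), diag(ec))
  # tilt raises short-range and depletes long-range expected counts
  expect_gt(et[1, 2] / ec[1, 2], 1)    # 100 kb < 3 Mb pivot
  expect_lt(et[1, 101] / ec[1, 101], 1) # 10 Mb > pivot
})

test_that("Poisson sampling is seed-deterministic and hits the target depth", {
  g <- genome_model("chr1", 3e6, 1e5)
  e <- build_expected(sim_config(g, seed = 1), "control")
  m1 <- sample_counts(e, g, 1e5, seed = 42)
  m2 <- sample_counts(e, g, 1e5, seed = 42)
  m3 <- sample_counts(e, g, 1e5, seed = 43)
  expect_identical(m1$cis, m2$cis)
  expect_false(identical(m1$cis, m3$cis))
  expect_true(all(m1$cis$chr1 == t(m1$cis$chr1)))
  expect_true(all(m1$cis$chr1 == round(m1$cis$chr1)))
  tot <- sum(m1$cis$chr1[upper.tri(m1$cis$chr1, diag = TRUE)])
  expect_lt(abs(tot - 1e5) / 1e5, 0.02)
  expect_error(sample_counts(e, g, 0, seed = 1), "positive")
})

test_that("sampling restores the caller's RNG state", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_pair(demo_config(seed = 3)))
  expect_identical(.Random.seed, before)
})

test_that("truth regions span each planted adjacent-domain pair", {
  cfg <- demo_config(seed = 7)
  tr <- truth_regions(cfg)
  expect_equal(nrow(tr), 4)
  # left_domain 8 with 5-bin domains at 100 kb: [7*5, 9*5) bins = 3.5-4.5 Mb
  expect_equal(tr$start_bp, c(3.5e6, 11.5e6, 5.5e6, 15.5e6))
  expect_equal(tr$end_bp - tr$start_bp, rep(1e6, 4))
  tads <- truth_tads(cfg)
  expect_equal(nrow(tads), 80)
  expect_true(all(tads$end_bp - tads$start_bp == 5e5))
})

test_that("planted feature peaks are non-overlapping, fixed width and denser inside", {
  pair <- demo_pair()
  pk <- pair$feature_peaks
  expect_true(all(pk$end_bp - pk$start_bp == 1000))
  by_ch <- split(pk, pk$chrom)
  for (d in by_ch) {
    d <- d[order(d$start_bp), ]
    expect_true(all(diff(d$start_bp) >= 1000))
  }
  tr <- pair$truth_regions
  inside <- sum(vapply(seq_len(nrow(pk)), function(i) {
    any(tr$chrom == pk$chrom[i] & tr$start_bp <= pk$start_bp[i] &
          tr$end_bp >= pk$end_bp[i])
  }, TRUE))
  len_in <- sum(tr$end_bp - tr$start_bp)
  len_out <- sum(pair$config$genome$chrom_lengths_bp) - len_in
  dens_in <- inside / (len_in / 1e6)
  dens_out <- (nrow(pk) - inside) / (len_out / 1e6)
  expect_gt(dens_in, 3 * dens_out)
  # determinism
  expect_identical(plant_features(pair$config), pk)
})
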