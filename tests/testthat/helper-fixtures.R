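# Shared fixtures, computed once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

demo_pair <- function() {
  fixture("demo_pair", function() simulate_pair(demo_config(seed = 7)))
}

# diff map, score track, default threshold and calls of the demo fixture
demo_calls <- function() {
  fixture("demo_calls", function() {
    pair <- demo_pair()
    diff <- log2_ratio(pair$treated, pair$control)
    track <- window_scores(diff, w = 10)
    thr <- choose_threshold(track, method = "quantile", param = 0.01,
                            direction = "decrease")
    list(diff = diff, track = track, threshold = thr,
         regions = call_regions(track, thr))
  })
}

compaction_pair <- function() {
  fixture("compaction_pair", function() simulate_pair(compaction_config(seed = 7)))
}

# a small random control/treated pair for plumbing tests
tiny_pair <- function(seed = 3, n_bins = 40) {
  g <- genome_model("chrT", n_bins * 1e5, 1e5)
  set.seed(seed)
  e <- list(chrT = outer(seq_len(n_bins), seq_len(n_bins),
                         function(i, j) (abs(i - j) + 1)^-1))
  list(genome = g,
       control = sample_counts(e, g, 5e4, seed = seed),
       treated = sample_counts(e, g, 5e4, seed = seed + 1))
}
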