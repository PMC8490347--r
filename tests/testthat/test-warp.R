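test_that("detect_boundaries recovers rectangular envelopes", {
  dt <- 0.001
  t <- seq(0, 0.5, by = dt)
  env <- as.numeric(t >= 0.1 & t < 0.2)
  b <- detect_boundaries(env, dt, threshold_frac = 0.5)
  expect_equal(nrow(b), 1)
  expect_lt(abs(b$onset - 0.1), 0.006)
  expect_lt(abs(b$offset - 0.2), 0.006)
  # two rectangles separated by 40 ms of silence
  env2 <- as.numeric((t >= 0.1 & t < 0.2) | (t >= 0.24 & t < 0.32))
  b2 <- detect_boundaries(env2, dt, threshold_frac = 0.5)
  expect_equal(nrow(b2), 2)
  # silence gives an empty table with a warning
  expect_warning(b0 <- detect_boundaries(rep(0, 100), dt), "silent")
  expect_equal(nrow(b0), 0)
  # sub-minimum blips are discarded
  blip <- as.numeric(t >= 0.1 & t < 0.105)
  expect_warning(bb <- detect_boundaries(blip, dt), "minimum syllable")
  expect_equal(nrow(bb), 0)
})

test_that("reference_timing takes the per-label maximum across positions", {
  durs <- list(c(0.10, 0.15, 0.12, 0.14), c(0.11, 0.13, 0.10, 0.15))
  set <- make_set(list(c(0.1), c(0.1)), rendition_durs = durs)
  ref <- reference_timing(set$renditions)
  expect_equal(unname(ref$durations["A"]), 0.12)  # max over both A positions
  expect_equal(unname(ref$durations["B"]), 0.15)
  ref_mean <- reference_timing(set$renditions, ref_stat = "mean")
  expect_equal(unname(ref_mean$durations["A"]), mean(c(0.10, 0.12, 0.11, 0.10)))
  # Same series: reference equals the single observed durations
  same <- make_set(list(c(0.1), c(0.1)))
  rs <- reference_timing(same$renditions)
  expect_equal(unname(rs$durations), c(0.12, 0.16))
})

test_that("warp maps are affine per segment and invert exactly", {
  durs <- list(c(0.10, 0.20, 0.10, 0.20), c(0.20, 0.10, 0.20, 0.10))
  set <- make_set(list(c(0.05), c(0.05)), rendition_durs = durs)
  ref <- reference_timing(set$renditions)
  r1 <- set$renditions[set$renditions$trial == 1, ]
  m <- warp_map(r1, ref)
  # syllable 1: 0.10 s warped to the 0.20 s reference; midpoint -> midpoint
  expect_equal(warp_spikes(0.05, m), 0.10, tolerance = 1e-12)
  # a spike in the first gap maps within the reference gap
  gap_spike <- 0.12   # inside [0.10, 0.14)
  w <- warp_spikes(gap_spike, m)
  expect_gte(w, 0.20); expect_lte(w, 0.24)
  # round trip through the inverse is the identity
  set.seed(5)
  ts <- sort(runif(50, 0, max(r1$offset)))
  expect_equal(warp_spikes(warp_spikes(ts, m), invert_warp_map(m)), ts,
               tolerance = 1e-9)
  # ordering and counts preserved
  expect_equal(length(warp_spikes(ts, m)), 50)
  expect_true(!is.unsorted(warp_spikes(ts, m)))
})

test_that("warping a rendition already at reference durations is the identity", {
  set <- make_set(rep(list(sort(runif(12, 0, 0.6))), 3))
  ref <- reference_timing(set$renditions)
  m <- warp_map(set$renditions[set$renditions$trial == 2, ], ref)
  ts <- spike_trains(set)[[2]]
  expect_equal(warp_spikes(ts, m), ts, tolerance = 1e-12)
})

test_that("warp_set preserves per-syllable spike counts exactly", {
  tm <- default_templates()
  spec <- series_spec("Var", n_renditions = 20, duration_jitter_cv = 0.15,
                      timing_jitter_sd = 0, seed = 6)
  set <- simulate_series(spec, tm, adaptation_model(1, 4, 5))
  warped <- warp_set(set)
  count_by_syll <- function(s) {
    trains <- spike_trains(s)
    purrr::map_dfr(seq_len(s$n_trials), function(k) {
      r <- s$renditions[s$renditions$trial == k, ]
      tibble::tibble(trial = k, syllable = r$syllable,
                     n = vapply(seq_len(nrow(r)), function(i) {
                       sum(trains[[k]] >= r$onset[i] & trains[[k]] < r$offset[i])
                     }, numeric(1)))
    })
  }
  expect_equal(count_by_syll(warped), count_by_syll(set))
  expect_equal(nrow(warped$spikes), nrow(set$spikes))
})

test_that("warping changes nothing when durations are fixed", {
  tm <- default_templates()
  spec <- series_spec("Var", n_renditions = 20, duration_jitter_cv = 0,
                      timing_jitter_sd = 0.01, seed = 13)
  set <- simulate_series(spec, tm, adaptation_model(1, 4, 5))
  wr <- warped_reliability(set, 10)
  expect_equal(wr$corrcoef_after, wr$corrcoef_before, tolerance = 1e-9)
})

test_that("warping restores reliability lost to duration variability", {
  tm <- default_templates()
  ad <- adaptation_model(1, 4, 5)
  vals <- sapply(1:4, function(s) {
    set <- simulate_series(
      series_spec("Var", n_renditions = 30, duration_jitter_cv = 0.2,
                  timing_jitter_sd = 0, seed = 400 + s), tm, ad)
    wr <- warped_reliability(set, 10, ref_stat = "mean")
    c(before = wr$corrcoef_before, after = wr$corrcoef_after)
  })
  expect_gt(mean(vals["after", ]), mean(vals["before", ]))
})
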