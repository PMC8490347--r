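test_that("pair windows split the sequence into its two AB pairs", {
  set <- make_set(list(c(0.1), c(0.1)))
  pw <- pair_windows(set)
  expect_equal(nrow(pw), 4)
  w1 <- pw[pw$trial == 1 & pw$pair == 1, ]
  w2 <- pw[pw$trial == 1 & pw$pair == 2, ]
  expect_equal(w1$t0, 0)
  expect_equal(w1$t1, 0.12 + 0.04 + 0.16)      # offset of syllable 2
  expect_lt(w1$t1, w2$t0 + 1e-9)
  expect_equal(w2$t1, max(set$renditions$offset))
})

test_that("identical spike patterns in both windows give identical pair statistics", {
  # same relative pattern in each pair window (pair 2 starts at 0.36)
  pat <- c(0.02, 0.05, 0.11, 0.2)
  trains <- lapply(1:10, function(k) c(pat, pat + 0.36))
  set <- make_set(trains)
  pm <- pair_metrics(set, 10)
  rs1 <- pm$trials$rs[pm$trials$pair == 1]
  rs2 <- pm$trials$rs[pm$trials$pair == 2]
  expect_equal(rs1, rs2)
  expect_equal(pm$corrcoef$corrcoef[1], pm$corrcoef$corrcoef[2],
               tolerance = 1e-12)
  # and the within-trial pair correlation is exactly 1
  wt <- within_trial_pair_correlation(set, 10)
  expect_true(all(abs(wt$trials$r - 1) < 1e-9))
})

test_that("reduced pair-2 drive is recovered as lower pair-2 RS", {
  tm <- default_templates(amplitude = 100)
  ad <- adaptation_model(1, 4, 2)
  diffs <- sapply(1:10, function(s) {
    set <- simulate_series(series_spec("Same", n_renditions = 30,
                                       seed = 500 + s), tm, ad)
    # thin the second pair window: drop ~40% of its spikes
    pw <- pair_windows(set)
    set.seed(600 + s)
    sp <- set$spikes
    w2 <- pw[pw$pair == 2, ]
    in2 <- vapply(seq_len(nrow(sp)), function(i) {
      w <- w2[w2$trial == sp$trial[i], ]
      sp$time_s[i] >= w$t0 && sp$time_s[i] < w$t1
    }, logical(1))
    drop <- in2 & runif(nrow(sp)) < 0.4
    thin <- spike_train_set(sp[!drop, ], set$renditions,
                            unit_id = set$unit_id, series_type = "Same",
                            n_trials = set$n_trials)
    pm <- pair_metrics(thin, 10)$trials
    mean(pm$rs[pm$pair == 1], na.rm = TRUE) -
      mean(pm$rs[pm$pair == 2], na.rm = TRUE)
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("pair RS difference is centred at zero without evoked structure", {
  tm <- default_templates(amplitude = 0)
  ad <- adaptation_model(1, 4, baseline_rate = 20)
  d <- sapply(1:20, function(s) {
    set <- simulate_series(series_spec("Same", n_renditions = 20,
                                       seed = 700 + s), tm, ad)
    pm <- pair_metrics(set, 10)$trials
    mean(pm$rs[pm$pair == 1], na.rm = TRUE) -
      mean(pm$rs[pm$pair == 2], na.rm = TRUE)
  })
  ci <- mean(d) + c(-1, 1) * 2 * sd(d) / sqrt(length(d))
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("within-trial pair correlation is null for independent activity and flags empty windows", {
  tm <- default_templates(amplitude = 0)
  ad <- adaptation_model(1, 4, baseline_rate = 25)
  rs <- sapply(1:20, function(s) {
    set <- simulate_series(series_spec("Same", n_renditions = 15,
                                       seed = 800 + s), tm, ad)
    within_trial_pair_correlation(set, 10)$summary$mean_r
  })
  expect_lt(abs(mean(rs)), 2 * sd(rs) / sqrt(length(rs)) + 0.05)
  # a trial with an empty pair-2 window is flagged undefined
  trains <- c(list(c(0.02, 0.1)), lapply(2:5, function(k) {
    c(0.02, 0.1, 0.38, 0.45)
  }))
  set <- make_set(trains)
  wt <- within_trial_pair_correlation(set, 10)
  expect_false(wt$trials$valid[1])
  expect_true(all(wt$trials$valid[-1]))
})

test_that("feature_regression recovers exact linear relations and matches OLS oracle", {
  x <- seq(1, 5, length.out = 20)
  tab <- tibble::tibble(corrcoef = 2 * x + 1, f1 = x,
                        const = rep(3, 20))
  fr <- suppressWarnings(feature_regression(tab))  # perfect-fit lm warning
  r1 <- fr[fr$feature == "f1", ]
  expect_equal(r1$slope, 2, tolerance = 1e-12)
  expect_equal(r1$intercept, 1, tolerance = 1e-12)
  expect_equal(r1$r_squared, 1, tolerance = 1e-12)
  expect_false(fr$valid[fr$feature == "const"])
  # random data equals the closed-form normal equations
  set.seed(12)
  tab2 <- tibble::tibble(corrcoef = rnorm(30), f = rnorm(30))
  fr2 <- feature_regression(tab2)
  o <- oracle_ols(tab2$f, tab2$corrcoef)
  expect_equal(fr2$slope, o["slope"], ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(fr2$intercept, o["intercept"], ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(feature_regression(tab2[1:2, ]), ">= 3 rows")
})

test_that("synthetic feature tables are independent of reliability by construction", {
  tm <- default_templates()
  set <- simulate_series(series_spec("Var", n_renditions = 60, seed = 15),
                         tm, adaptation_model(1, 4, 5))
  ft <- synthesize_features(set, 10, seed = 2)
  expect_equal(nrow(ft), 59)
  expect_true(all(c("corrcoef", "similarity", "entropy_diff", "pitch_diff",
                    "duration_diff") %in% names(ft)))
  expect_true(all(ft$similarity <= 100))
})
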