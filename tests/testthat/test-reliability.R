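test_that("convolution produces unit-area kernels on the grid", {
  win <- c(0, 0.5)
  empty <- convolve_train(numeric(0), 10, win)
  expect_true(all(empty$values == 0))
  one <- convolve_train(0.25, 10, win)
  expect_equal(one$grid[which.max(one$values)], 0.25)
  # kernel mass: trapezoidal integral of 3 well-separated spikes = 3
  tr <- convolve_train(c(0.1, 0.25, 0.4), 10, win)
  integral <- sum((head(tr$values, -1) + tr$values[-1]) / 2) * 0.001
  expect_equal(integral, 3, tolerance = 0.01)
  expect_error(convolve_train(0.1, 0.5, win), "width_ms")
  expect_error(convolve_train(0.1, 250, win), "width_ms")
})

test_that("fwhm width interpretation narrows the kernel accordingly", {
  a <- convolve_train(0.25, 10, c(0, 0.5), width_type = "sigma")
  b <- convolve_train(0.25, 10, c(0, 0.5), width_type = "fwhm")
  expect_gt(max(b$values), max(a$values))
  expect_equal(max(b$values) / max(a$values), 2 * sqrt(2 * log(2)),
               tolerance = 1e-6)
})

test_that("corrcoef is 1 for identical trains regardless of rate", {
  for (n_spikes in c(3, 12, 40)) {
    t0 <- sort(runif(n_spikes, 0, 0.6))
    expect_equal(corrcoef(rep(list(t0), 10), 10, c(0, 0.6)), 1,
                 tolerance = 1e-12)
  }
})

test_that("corrcoef of two trains equals their plain Pearson r", {
  set.seed(31)
  a <- sort(runif(15, 0, 0.6)); b <- sort(runif(12, 0, 0.6))
  X <- cbind(convolve_train(a, 10, c(0, 0.6))$values,
             convolve_train(b, 10, c(0, 0.6))$values)
  expect_equal(corrcoef(list(a, b), 10, c(0, 0.6)), cor(X[, 1], X[, 2]),
               tolerance = 1e-12)
  expect_error(corrcoef(list(a), 10, c(0, 0.6)), "at least 2")
})

test_that("corrcoef is invariant to train ordering and handles empties", {
  set.seed(8)
  trains <- poisson_trains(8, 20, 0.6)
  v1 <- corrcoef(trains, 10, c(0, 0.6))
  v2 <- corrcoef(rev(trains), 10, c(0, 0.6))
  expect_equal(v1, v2, tolerance = 1e-12)
  # empty trains are excluded pairwise, not scored 0
  with_empty <- c(trains, list(numeric(0)))
  expect_equal(corrcoef(with_empty, 10, c(0, 0.6)), v1, tolerance = 1e-12)
  # all-degenerate set is undefined
  expect_true(is.na(corrcoef(list(numeric(0), numeric(0)), 10, c(0, 0.6))))
})

test_that("corrcoef matches the brute-force pairwise oracle", {
  set.seed(99)
  trains <- poisson_trains(7, 25, 0.4)
  expect_equal(corrcoef(trains, 10, c(0, 0.4)),
               oracle_corrcoef(trains, 10, c(0, 0.4)), tolerance = 1e-12)
})

test_that("block_matrix is symmetric, exact for identical trains, and separates templates", {
  t0 <- c(0.05, 0.2, 0.41)
  set <- make_set(rep(list(t0), 60))
  M <- block_matrix(set, 10)$matrix
  expect_true(all(abs(M - 1) < 1e-12))
  # blocks 1-3 one pattern, blocks 4-6 a disjoint pattern
  tA <- c(0.05, 0.10, 0.15); tB <- c(0.35, 0.40, 0.45)
  set2 <- make_set(c(rep(list(tA), 30), rep(list(tB), 30)))
  M2 <- block_matrix(set2, 5)$matrix
  expect_equal(M2, t(M2))
  expect_true(all(abs(M2[1:3, 1:3] - 1) < 1e-12))
  expect_true(all(abs(M2[4:6, 4:6] - 1) < 1e-12))
  expect_true(all(M2[1:3, 4:6] < 1))
  expect_error(block_matrix(make_set(poisson_trains(55, 10, 0.5)), 10),
               "blocks of 10")
})

test_that("permuted_null preserves counts, is reproducible, and sits below structured CorrCoef", {
  set.seed(3)
  base <- sort(runif(20, 0, 0.6))
  jittered <- lapply(1:10, function(i) sort(base + rnorm(20, 0, 0.002)))
  set <- make_set(jittered)
  obs <- set_corrcoef(set, 10)
  null <- permuted_null(set, 10, n_draws = 50, seed = 21)
  expect_gt(obs, mean(null) + 5 * sd(null))
  expect_identical(null, permuted_null(set, 10, n_draws = 50, seed = 21))
  # degenerate 0/1-spike trains behave like corrcoef's zero-variance rule
  tiny <- make_set(c(list(numeric(0)), rep(list(0.3), 3)))
  nd <- permuted_null(tiny, 10, n_draws = 5, seed = 4)
  expect_length(nd, 5)
  expect_true(all(is.finite(nd) | is.na(nd)))
})

test_that("reliability degrades monotonically with timing jitter", {
  base <- seq(0.05, 0.6, by = 0.05)
  mean_cc <- sapply(c(0, 0.005, 0.010, 0.020), function(sd_j) {
    mean(sapply(1:20, function(s) {
      set.seed(s * 1000 + round(sd_j * 1e5))
      trains <- lapply(1:10, function(i) sort(base + rnorm(length(base), 0, sd_j)))
      corrcoef(trains, 10, c(0, 0.7))
    }))
  })
  expect_true(all(diff(mean_cc) < 0))
})

test_that("width_sweep finds no difference when regimes are identical", {
  tm <- default_templates()
  ad <- adaptation_model(1, 4, 5)
  same <- lapply(1:6, function(u) {
    simulate_series(series_spec("Same", n_renditions = 20, seed = 100 + u),
                    tm, ad, unit_id = paste0("u", u))
  })
  var0 <- lapply(1:6, function(u) {
    simulate_series(series_spec("Var", n_renditions = 20,
                                duration_jitter_cv = 0, timing_jitter_sd = 0,
                                seed = 100 + u), tm, ad,
                    unit_id = paste0("u", u))
  })
  sw <- width_sweep(same, var0, widths_ms = c(10, 50), n_perm = 300,
                    seed = 1)
  # identical spike trains: difference is exactly 0, never significant
  expect_true(all(abs(sw$by_width$diff) < 1e-12))
  expect_true(all(sw$by_width$p_value >= 0.05))
  expect_equal(sw$crossover_width_ms, 10)
})

test_that("sweep and matrix tidiers return labeled long tables", {
  set <- make_set(rep(list(c(0.1, 0.3)), 60))
  td <- tidy(block_matrix(set, 10))
  expect_equal(nrow(td), 36)
  expect_true(all(c("block_i", "block_j", "corrcoef") %in% names(td)))
})
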