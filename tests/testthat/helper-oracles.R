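# Shared fixtures and independent oracles for the test suite.

# Build a minimal spike_train_set from a list of per-trial spike vectors and
# one shared ABAB boundary layout (durations in seconds).
make_set <- function(trains, dur_a = 0.12, dur_b = 0.16, gap = 0.04,
                     series = "Same", unit_id = "u1",
                     rendition_durs = NULL) {
  n <- length(trains)
  labels <- c("A", "B", "A", "B")
  ann <- purrr::map_dfr(seq_len(n), function(k) {
    d <- if (is.null(rendition_durs)) {
      c(dur_a, dur_b, dur_a, dur_b)
    } else rendition_durs[[k]]
    onsets <- cumsum(c(0, head(d, -1) + gap))
    tibble::tibble(trial = k, block = as.integer(ceiling(k / 10)),
                   seq_onset = k - 1, syllable = 1:4, label = labels,
                   onset = onsets, offset = onsets + d)
  })
  sp <- purrr::map_dfr(seq_len(n), function(k) {
    tibble::tibble(trial = k, time_s = trains[[k]])
  })
  spike_train_set(sp, ann, unit_id = unit_id, series_type = series,
                  n_trials = n)
}

# Homogeneous Poisson spike trains on [0, t1).
poisson_trains <- function(n_trials, rate, t1) {
  lapply(seq_len(n_trials), function(i) {
    sort(runif(rpois(1, rate * t1), 0, t1))
  })
}

# Independent oracle: convolved trace by explicit per-grid-point summation.
oracle_trace <- function(times, grid, sigma) {
  sapply(grid, function(g) {
    if (length(times) == 0) return(0)
    sum(exp(-(g - times)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi)))
  })
}

# Independent oracle: mean pairwise Pearson r over unordered pairs of
# convolved traces, explicit double loop, explicit Pearson formula.
oracle_corrcoef <- function(trains, width_ms, window, grid_step = 0.001) {
  sigma <- width_ms / 1000
  grid <- seq(window[1], window[2], by = grid_step)
  traces <- lapply(trains, oracle_trace, grid = grid, sigma = sigma)
  n <- length(traces)
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      x <- traces[[i]]; y <- traces[[j]]
      sx <- sqrt(sum((x - mean(x))^2)); sy <- sqrt(sum((y - mean(y))^2))
      vals <- c(vals, if (sx == 0 || sy == 0) NA_real_ else
        sum((x - mean(x)) * (y - mean(y))) / (sx * sy))
    }
  }
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

# Independent oracle: block-pair matrix by explicit double loop.
oracle_block_matrix <- function(trains, width_ms, window, n_per_block = 10,
                                grid_step = 0.001) {
  sigma <- width_ms / 1000
  grid <- seq(window[1], window[2], by = grid_step)
  traces <- lapply(trains, oracle_trace, grid = grid, sigma = sigma)
  pearson <- function(x, y) {
    sx <- sqrt(sum((x - mean(x))^2)); sy <- sqrt(sum((y - mean(y))^2))
    if (sx == 0 || sy == 0) NA_real_ else
      sum((x - mean(x)) * (y - mean(y))) / (sx * sy)
  }
  nb <- length(trains) %/% n_per_block
  M <- matrix(NA_real_, nb, nb)
  for (bi in seq_len(nb)) {
    for (bj in seq_len(nb)) {
      ti <- (bi - 1) * n_per_block + seq_len(n_per_block)
      tj <- (bj - 1) * n_per_block + seq_len(n_per_block)
      vals <- c()
      if (bi == bj) {
        for (a in seq_len(n_per_block - 1)) for (b in (a + 1):n_per_block) {
          vals <- c(vals, pearson(traces[[ti[a]]], traces[[tj[b]]]))
        }
      } else {
        for (a in ti) for (b in tj) {
          vals <- c(vals, pearson(traces[[a]], traces[[b]]))
        }
      }
      M[bi, bj] <- mean(vals, na.rm = TRUE)
    }
  }
  M
}

# Independent oracle: OLS slope/intercept from the closed-form normal
# equations.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}
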