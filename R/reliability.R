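#' Gaussian-kernel convolution of a spike train
#'
#' Smooths a spike train by placing a unit-area Gaussian kernel at each spike
#' time and sampling the sum on a uniform grid (default 1 ms step) spanning
#' the analysis window. Kernels are truncated at the window edges without
#' renormalization, so the trapezoidal integral of the trace approximates the
#' spike count up to edge losses. "Width" is the Gaussian sigma by default;
#' set `width_type = "fwhm"` to interpret it as full width at half maximum.
#'
#' @param times Numeric spike times, seconds.
#' @param width_ms Kernel width in milliseconds, in `[1, 200]`.
#' @param window Numeric `c(t0, t1)` analysis window, seconds.
#' @param grid_step Grid step, seconds (default 0.001).
#' @param width_type `"sigma"` (default) or `"fwhm"`.
#' @return A `convolved_train`: list with `grid` (s) and `values` (Hz-like,
#'   unit-area kernels).
#' @export
convolve_train <- function(times, width_ms, window, grid_step = 0.001,
                           width_type = c("sigma", "fwhm")) {
  width_type <- match.arg(width_type)
  if (width_ms < 1 || width_ms > 200) {
    stopf("width_ms must lie in [1, 200], got %g", width_ms)
  }
  sigma <- width_ms / 1000
  if (width_type == "fwhm") sigma <- sigma / (2 * sqrt(2 * log(2)))
  grid <- seq(window[1], window[2], by = grid_step)
  values <- kernel_trace(times, grid, sigma)
  structure(list(grid = grid, values = values, sigma = sigma),
            class = "convolved_train")
}

# Sum of unit-area Gaussians at `times`, evaluated on `grid`.
kernel_trace <- function(times, grid, sigma) {
  if (length(times) == 0) return(numeric(length(grid)))
  # outer() is fine at these sizes (grid ~1e3, spikes ~1e2)
  rowSums(outer(grid, times, function(g, s) dnorm(g, mean = s, sd = sigma)))
}

# Matrix of convolved traces (grid points x trains) on a shared window.
trace_matrix <- function(trains, width_ms, window, grid_step = 0.001,
                         width_type = "sigma") {
  sigma <- width_ms / 1000
  if (width_type == "fwhm") sigma <- sigma / (2 * sqrt(2 * log(2)))
  if (width_ms < 1 || width_ms > 200) {
    stopf("width_ms must lie in [1, 200], got %g", width_ms)
  }
  grid <- seq(window[1], window[2], by = grid_step)
  vapply(trains, kernel_trace, numeric(length(grid)), grid = grid,
         sigma = sigma)
}

# Pairwise Pearson matrix with NA for pairs involving a zero-variance trace.
pairwise_pearson <- function(X) {
  sds <- apply(X, 2, sd)
  R <- suppressWarnings(cor(X))
  R[sds == 0, ] <- NA_real_
  R[, sds == 0] <- NA_real_
  R
}

#' Spike-timing reliability (CorrCoef) of a group of trains
#'
#' The mean Pearson correlation over all unordered pairs of Gaussian-convolved
#' spike trains: high values mean the temporal pattern repeats reliably from
#' trial to trial, independent of overall firing-rate level. Pairs in which
#' either trace has zero variance (e.g. an empty train) are excluded; if every
#' pair is excluded the value is undefined (`NA`).
#'
#' @param trains List of >= 2 numeric spike-time vectors.
#' @param width_ms Gaussian kernel width, ms (see [convolve_train()]).
#' @param window Shared analysis window `c(t0, t1)`, seconds.
#' @param grid_step Grid step, seconds.
#' @param width_type `"sigma"` or `"fwhm"`.
#' @return Single numeric CorrCoef (or `NA` if undefined).
#' @export
corrcoef <- function(trains, width_ms, window, grid_step = 0.001,
                     width_type = "sigma") {
  if (length(trains) < 2) stopf("corrcoef needs at least 2 trains")
  X <- trace_matrix(trains, width_ms, window, grid_step, width_type)
  R <- pairwise_pearson(X)
  vals <- R[upper.tri(R)]
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

#' CorrCoef of a spike-train set
#'
#' Applies [corrcoef()] to (a subset of) a set's trials on the common evoked
#' window `[0, max syllable offset)`, baseline excluded.
#'
#' @param set A [spike_train_set()].
#' @param width_ms Kernel width, ms.
#' @param trials Optional trial indices (default: all).
#' @param ... Passed to [corrcoef()].
#' @return Single numeric CorrCoef.
#' @export
set_corrcoef <- function(set, width_ms = 10, trials = NULL, ...) {
  trains <- spike_trains(set)
  if (!is.null(trials)) trains <- trains[trials]
  win <- evoked_window(set)
  trains <- lapply(trains, function(t) t[t >= win[1] & t < win[2]])
  corrcoef(trains, width_ms, win, ...)
}

#' Block-pair CorrCoef matrix
#'
#' The 6x6 reliability matrix over blocks of ten trials. Diagonal entry
#' `(i, i)` is the mean Pearson correlation over the 45 unordered pairs of
#' trials within block `i`; off-diagonal entry `(i, j)` is the mean over the
#' 100 cross pairs between blocks `i` and `j` (trial 1 of block i vs each
#' trial of block j, etc.). The matrix is symmetric by construction.
#'
#' @param set A [spike_train_set()] with trials forming complete blocks of 10.
#' @param width_ms Kernel width, ms.
#' @param ... Passed to the convolution (grid step, width type).
#' @return A `corrcoef_matrix`: the matrix plus unit/series metadata. Has
#'   [tidy()] and [autoplot()] methods.
#' @export
block_matrix <- function(set, width_ms = 10, ...) {
  stopifnot(inherits(set, "spike_train_set"))
  blocks <- trial_blocks(set)
  if (set$n_trials %% 10 != 0) {
    stopf("block_matrix needs complete blocks of 10 trials, got %d trials",
          set$n_trials)
  }
  n_blocks <- set$n_trials %/% 10
  win <- evoked_window(set)
  trains <- lapply(spike_trains(set), function(t) t[t >= win[1] & t < win[2]])
  X <- trace_matrix(trains, width_ms, win, ...)
  R <- pairwise_pearson(X)
  M <- matrix(NA_real_, n_blocks, n_blocks,
              dimnames = list(paste0("block", seq_len(n_blocks)),
                              paste0("block", seq_len(n_blocks))))
  for (i in seq_len(n_blocks)) {
    for (j in i:n_blocks) {
      ri <- which(blocks == i)
      rj <- which(blocks == j)
      sub <- R[ri, rj, drop = FALSE]
      vals <- if (i == j) sub[upper.tri(sub)] else as.vector(sub)
      M[i, j] <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
      M[j, i] <- M[i, j]
    }
  }
  structure(list(matrix = M, unit_id = set$unit_id,
                 series = set$series_type, width_ms = width_ms,
                 n_per_block = 10),
            class = "corrcoef_matrix")
}

#' @export
print.corrcoef_matrix <- function(x, ...) {
  cat(sprintf("<corrcoef_matrix> unit %s, series %s, width %g ms\n",
              x$unit_id, x$series, x$width_ms))
  print(round(x$matrix, 3))
  invisible(x)
}

# Random redistribution of one train's spikes: count preserved, times
# uniform over the window ("uniform"), or inter-spike intervals shuffled
# and re-anchored at a uniform start ("isi_shuffle").
permute_train <- function(times, window, method = "uniform") {
  n <- length(times)
  if (n == 0) return(times)
  if (method == "uniform") {
    sort(runif(n, window[1], window[2]))
  } else {
    if (n == 1) return(runif(1, window[1], window[2]))
    isi <- diff(sort(times))
    span <- sum(isi)
    start <- runif(1, window[1], max(window[1], window[2] - span))
    start + c(0, cumsum(sample(isi)))
  }
}

#' Permutation null distribution of CorrCoef
#'
#' Reference distribution of the reliability index when spike timing carries
#' no information: per draw, every trial keeps its spike count but the spike
#' times are redistributed at random over the evoked window, and CorrCoef is
#' recomputed. Observed CorrCoefs well above this null indicate genuine
#' temporal organization.
#'
#' @param set A [spike_train_set()].
#' @param width_ms Kernel width, ms.
#' @param n_draws Number of permutation draws (>= 1).
#' @param seed Integer seed.
#' @param trials Optional trial subset.
#' @param method `"uniform"` (redraw times uniformly; default) or
#'   `"isi_shuffle"` (shuffle inter-spike intervals).
#' @param ... Passed to [corrcoef()].
#' @return Numeric vector of `n_draws` null CorrCoef values.
#' @export
permuted_null <- function(set, width_ms = 10, n_draws = 100, seed = NULL,
                          trials = NULL, method = c("uniform", "isi_shuffle"),
                          ...) {
  method <- match.arg(method)
  stopifnot(n_draws >= 1)
  trains <- spike_trains(set)
  if (!is.null(trials)) trains <- trains[trials]
  win <- evoked_window(set)
  trains <- lapply(trains, function(t) t[t >= win[1] & t < win[2]])
  with_rng(seed, {
    vapply(seq_len(n_draws), function(d) {
      perm <- lapply(trains, permute_train, window = win, method = method)
      corrcoef(perm, width_ms, win, ...)
    }, numeric(1))
  })
}

# Paired sign-flip permutation test on per-unit differences d.
# Returns the two-sided p-value for mean(d) != 0.
sign_flip_test <- function(d, n_perm = 1000, seed = NULL) {
  d <- d[!is.na(d)]
  if (length(d) == 0) return(NA_real_)
  obs <- abs(mean(d))
  with_rng(seed, {
    flips <- vapply(seq_len(n_perm), function(i) {
      abs(mean(d * sample(c(-1, 1), length(d), replace = TRUE)))
    }, numeric(1))
    (1 + sum(flips >= obs)) / (n_perm + 1)
  })
}

#' Kernel-width sweep of CorrCoef
#'
#' Recomputes per-unit CorrCoef for the Same and Var series over a range of
#' Gaussian kernel widths, together with a spike-time-permuted reference, and
#' tests the paired Same - Var difference at each width with a sign-flip
#' permutation test across units. Narrow kernels probe spike-timing
#' precision; wide kernels blur toward firing-rate similarity, so the
#' difference between regimes is expected to vanish beyond some width
#' (`crossover_width_ms`, the smallest width with p >= alpha).
#'
#' @param same_sets,var_sets Lists of [spike_train_set()]s, paired by unit.
#' @param widths_ms Kernel widths to sweep, ms (default
#'   `c(1, 2, 5, 10, 20, 50, 100, 150, 200)`).
#' @param n_perm Resamples for the sign-flip test (default 1000).
#' @param n_null_draws Permuted-reference draws per unit per width (default 1).
#' @param seed Integer seed.
#' @param alpha Significance level defining the crossover (default 0.05).
#' @param trials Optional trial subset used for every CorrCoef.
#' @return A `sweep_result`: `by_width` tibble (width_ms, mean_same, sem_same,
#'   mean_var, sem_var, mean_perm, diff, p_value), `by_unit` tibble, and
#'   `crossover_width_ms` (NA if the difference never loses significance).
#' @export
width_sweep <- function(same_sets, var_sets,
                        widths_ms = c(1, 2, 5, 10, 20, 50, 100, 150, 200),
                        n_perm = 1000, n_null_draws = 1, seed = NULL,
                        alpha = 0.05, trials = NULL) {
  stopifnot(length(same_sets) == length(var_sets), length(same_sets) >= 1,
            all(diff(widths_ms) > 0))
  n_units <- length(same_sets)
  by_unit <- purrr::map_dfr(seq_along(widths_ms), function(wi) {
    w <- widths_ms[wi]
    purrr::map_dfr(seq_len(n_units), function(u) {
      perm_seed <- child_seed(seed, sprintf("perm-w%g-u%d", w, u))
      perm_vals <- c(
        permuted_null(same_sets[[u]], w, n_draws = n_null_draws,
                      seed = perm_seed, trials = trials),
        permuted_null(var_sets[[u]], w, n_draws = n_null_draws,
                      seed = child_seed(perm_seed, "var"), trials = trials))
      tibble::tibble(
        width_ms = w, unit = u,
        same = set_corrcoef(same_sets[[u]], w, trials = trials),
        var = set_corrcoef(var_sets[[u]], w, trials = trials),
        perm = mean(perm_vals, na.rm = TRUE))
    })
  })
  by_width <- by_unit |>
    dplyr::group_by(.data$width_ms) |>
    dplyr::summarise(
      mean_same = mean(.data$same, na.rm = TRUE),
      sem_same = sd(.data$same, na.rm = TRUE) / sqrt(sum(!is.na(.data$same))),
      mean_var = mean(.data$var, na.rm = TRUE),
      sem_var = sd(.data$var, na.rm = TRUE) / sqrt(sum(!is.na(.data$var))),
      mean_perm = mean(.data$perm, na.rm = TRUE),
      diff = mean(.data$same - .data$var, na.rm = TRUE),
      .groups = "drop")
  pvals <- vapply(widths_ms, function(w) {
    d <- by_unit$same[by_unit$width_ms == w] - by_unit$var[by_unit$width_ms == w]
    sign_flip_test(d, n_perm = n_perm,
                   seed = child_seed(seed, sprintf("flip-w%g", w)))
  }, numeric(1))
  by_width$p_value <- pvals
  cross <- widths_ms[which(pvals >= alpha)]
  structure(
    list(by_width = by_width, by_unit = by_unit,
         crossover_width_ms = if (length(cross)) min(cross) else NA_real_,
         alpha = alpha, n_perm = n_perm,
         test = "paired sign-flip permutation across units"),
    class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d widths, %d units; crossover at %s ms\n",
              nrow(x$by_width), max(x$by_unit$unit),
              format(x$crossover_width_ms)))
  print(x$by_width)
  invisible(x)
}
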