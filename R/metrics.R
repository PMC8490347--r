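#' Firing rate in a half-open window
#'
#' Counts spikes with `t0 <= t < t1` and divides by the window length. The
#' half-open convention avoids double counting at shared boundaries.
#'
#' @param times Numeric spike times, seconds.
#' @param window Numeric `c(t0, t1)` with `t1 > t0`.
#' @return Rate in Hz.
#' @export
firing_rate <- function(times, window) {
  if (window[2] <= window[1]) stopf("window must satisfy t1 > t0")
  count_in_window(times, window[1], window[2]) / (window[2] - window[1])
}

#' Response strength index
#'
#' `RS = (E_FR - B_FR) / (E_FR + B_FR)`: a normalized contrast between the
#' evoked and spontaneous firing rates, in `[-1, 1]`; positive values mark
#' excitatory responses, negative values inhibitory ones. When both rates are
#' zero the index is undefined and `NA` is returned (degenerate trials are
#' flagged, never imputed as 0).
#'
#' @param e_fr Evoked firing rate, Hz (>= 0).
#' @param b_fr Spontaneous (baseline) firing rate, Hz (>= 0).
#' @return RS value(s); `NA` where `e_fr + b_fr == 0`.
#' @export
response_strength <- function(e_fr, b_fr) {
  stopifnot(all(e_fr >= 0), all(b_fr >= 0))
  out <- (e_fr - b_fr) / (e_fr + b_fr)
  out[e_fr + b_fr == 0] <- NA_real_
  out
}

#' Trial-level rates and response strength for a set
#'
#' For every trial: the evoked rate over that rendition's own sequence span
#' (onset of the first syllable to offset of the last, so varying-duration
#' renditions use their own window), the baseline rate over the 200 ms
#' pre-stimulus epoch `[-0.2, 0)`, and the RS index.
#'
#' @param set A [spike_train_set()].
#' @return Tibble: `unit_id`, `series`, `trial`, `block`, `e_fr`, `b_fr`,
#'   `rs`, `valid` (FALSE where RS is undefined).
#' @export
trial_rs <- function(set) {
  stopifnot(inherits(set, "spike_train_set"))
  trains <- spike_trains(set)
  ends <- set$renditions |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(end = max(.data$offset), .groups = "drop") |>
    dplyr::arrange(.data$trial)
  e <- vapply(seq_len(set$n_trials), function(k) {
    firing_rate(trains[[k]], c(0, ends$end[k]))
  }, numeric(1))
  b <- vapply(trains, firing_rate, numeric(1), window = c(-0.2, 0))
  rs <- response_strength(e, b)
  tibble::tibble(unit_id = set$unit_id, series = set$series_type,
                 trial = seq_len(set$n_trials), block = trial_blocks(set),
                 e_fr = e, b_fr = b, rs = rs, valid = !is.na(rs))
}

#' Block-level response strength
#'
#' Aggregates trial RS into one value per block of ten consecutive trials
#' (six blocks for the canonical 60-trial series). `method = "mean"` averages
#' the defined trial-level RS values; `method = "pooled"` recomputes RS from
#' the block's summed spike counts. A block is flagged invalid when more than
#' half of its trials have undefined RS.
#'
#' @param set A [spike_train_set()].
#' @param method `"mean"` (default) or `"pooled"`.
#' @return Tibble: `unit_id`, `series`, `block`, `rs`, `n_defined`, `valid`.
#' @export
block_rs <- function(set, method = c("mean", "pooled")) {
  method <- match.arg(method)
  tr <- trial_rs(set)
  if (method == "mean") {
    tr |>
      dplyr::group_by(.data$unit_id, .data$series, .data$block) |>
      dplyr::summarise(
        n_defined = sum(.data$valid),
        rs = if (sum(.data$valid) > 0) mean(.data$rs[.data$valid]) else NA_real_,
        valid = sum(.data$valid) > dplyr::n() / 2,
        .groups = "drop")
  } else {
    tr |>
      dplyr::group_by(.data$unit_id, .data$series, .data$block) |>
      dplyr::summarise(
        n_defined = sum(.data$valid),
        rs = response_strength(mean(.data$e_fr), mean(.data$b_fr)),
        valid = !is.na(response_strength(mean(.data$e_fr), mean(.data$b_fr))),
        .groups = "drop")
  }
}

#' Stimulus-specific adaptation rate
#'
#' Ordinary least-squares slope of the evoked firing rate against trial index
#' over the first ten renditions. A negative slope indicates adaptation of
#' the response with stimulus repetition. The fit is flagged invalid when the
#' unit fired no spike at all during the first trial (such units are excluded
#' from population comparisons rather than contributing a spurious slope).
#'
#' @param set A [spike_train_set()] with at least 10 trials.
#' @param n_trials Number of initial trials to regress over (default 10).
#' @return An `adaptation_fit` object with elements `slope` (Hz/trial),
#'   `intercept` (Hz), `n_points`, `valid`, and the per-trial data. Has
#'   [tidy()] and [glance()] methods.
#' @export
adaptation_rate <- function(set, n_trials = 10) {
  stopifnot(inherits(set, "spike_train_set"))
  if (set$n_trials < n_trials) {
    stopf("adaptation_rate needs >= %d trials, got %d", n_trials, set$n_trials)
  }
  tr <- trial_rs(set) |> dplyr::slice_head(n = n_trials)
  trains <- spike_trains(set)
  first_has_spike <- length(trains[[1]]) > 0
  fit <- lm(e_fr ~ trial, data = tr)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         n_points = n_trials, valid = first_has_spike,
         unit_id = set$unit_id, series = set$series_type,
         data = tr, fit = fit),
    class = "adaptation_fit")
}

#' @export
print.adaptation_fit <- function(x, ...) {
  cat(sprintf(
    "<adaptation_fit> unit %s (%s): slope %.3f Hz/trial over %d trials%s\n",
    x$unit_id, x$series, x$slope, x$n_points,
    if (x$valid) "" else " [invalid: no spike in first trial]"))
  invisible(x)
}
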