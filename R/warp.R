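#' Detect syllable boundaries from an amplitude envelope
#'
#' Computes the root-mean-square of the envelope in a sliding window and
#' returns the maximal runs where it exceeds a fraction of its peak as
#' syllable (onset, offset) intervals. Runs shorter than `min_duration_s` are
#' discarded as noise.
#'
#' @param values Non-negative amplitude samples on a uniform grid.
#' @param grid_step Grid step of `values`, seconds.
#' @param threshold_frac Threshold as a fraction of the peak RMS, in (0, 1).
#' @param rms_window_s Sliding RMS window, seconds (default 0.005).
#' @param min_duration_s Minimum syllable duration, seconds (default 0.020).
#' @param t0 Time of the first sample, seconds (default 0).
#' @return Tibble with columns `onset`, `offset` (seconds); zero rows (with a
#'   warning) when nothing crosses the threshold.
#' @export
detect_boundaries <- function(values, grid_step, threshold_frac = 0.5,
                              rms_window_s = 0.005, min_duration_s = 0.020,
                              t0 = 0) {
  stopifnot(threshold_frac > 0, threshold_frac < 1, all(values >= 0))
  k <- max(1L, round(rms_window_s / grid_step))
  ma <- stats::filter(values^2, rep(1 / k, k), sides = 2)
  rms <- sqrt(as.numeric(ma))
  rms[is.na(rms)] <- 0
  peak <- max(rms)
  if (peak == 0) {
    warn("envelope is silent: no syllable boundaries detected")
    return(tibble::tibble(onset = numeric(0), offset = numeric(0)))
  }
  above <- rms >= threshold_frac * peak
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths * grid_step >= min_duration_s)
  if (!any(keep)) {
    warn("no run above threshold exceeds the minimum syllable duration")
    return(tibble::tibble(onset = numeric(0), offset = numeric(0)))
  }
  tibble::tibble(onset = t0 + (starts[keep] - 1) * grid_step,
                 offset = t0 + ends[keep] * grid_step)
}

#' Reference timing for a set of renditions
#'
#' Per syllable label, the reference duration is the maximum duration
#' observed across all renditions and positions (`ref_stat = "max"`, the
#' default) or the mean (`ref_stat = "mean"`). Inter-syllable gaps get a
#' reference duration per gap position by the same statistic, so the warp map
#' stays continuous and invertible over the whole sequence span.
#'
#' @param renditions Rendition tibble (columns `trial`, `syllable`, `label`,
#'   `onset`, `offset`).
#' @param ref_stat `"max"` (default) or `"mean"`.
#' @return A `warp_reference`: `durations` (named by label), `gap_durations`
#'   (per gap position), `labels` (syllable label sequence).
#' @export
reference_timing <- function(renditions, ref_stat = c("max", "mean")) {
  ref_stat <- match.arg(ref_stat)
  stat <- if (ref_stat == "max") max else mean
  stopifnot(nrow(renditions) > 0)
  durs <- renditions |>
    dplyr::mutate(duration = .data$offset - .data$onset) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(ref = stat(.data$duration), .groups = "drop")
  gaps <- renditions |>
    dplyr::group_by(.data$trial) |>
    dplyr::arrange(.data$syllable, .by_group = TRUE) |>
    dplyr::reframe(gap_pos = seq_len(dplyr::n() - 1),
                   gap = .data$onset[-1] - head(.data$offset, -1)) |>
    dplyr::group_by(.data$gap_pos) |>
    dplyr::summarise(ref = stat(.data$gap), .groups = "drop")
  first <- renditions[renditions$trial == min(renditions$trial), ]
  first <- first[order(first$syllable), ]
  structure(list(
    durations = stats::setNames(durs$ref, durs$label),
    gap_durations = gaps$ref,
    labels = first$label), class = "warp_reference")
}

#' Build the piecewise-linear warp map for one rendition
#'
#' Maps the rendition's time axis onto the reference axis: each syllable is
#' linearly stretched or compressed to its label's reference duration, and
#' each inter-syllable gap to the reference gap for that position. The target
#' axis starts at 0 at the first syllable's onset. Segments are contiguous
#' and strictly increasing, so the map is invertible.
#'
#' @param rendition One trial's annotation rows (`syllable`, `label`,
#'   `onset`, `offset`).
#' @param reference A `warp_reference` from [reference_timing()].
#' @return A `warp_map`: tibble of segments (`src0`, `src1`, `dst0`, `dst1`).
#' @export
warp_map <- function(rendition, reference) {
  r <- rendition[order(rendition$syllable), ]
  n <- nrow(r)
  stopifnot(n >= 1, all(r$label %in% names(reference$durations)))
  src0 <- numeric(0); src1 <- numeric(0); dlen <- numeric(0)
  for (i in seq_len(n)) {
    src0 <- c(src0, r$onset[i]); src1 <- c(src1, r$offset[i])
    dlen <- c(dlen, unname(reference$durations[r$label[i]]))
    if (i < n) {
      src0 <- c(src0, r$offset[i]); src1 <- c(src1, r$onset[i + 1])
      dlen <- c(dlen, reference$gap_durations[i])
    }
  }
  if (any(src1 <= src0)) stopf("rendition segments must have positive length")
  dst1 <- cumsum(dlen)
  dst0 <- c(0, head(dst1, -1))
  structure(list(segments = tibble::tibble(src0 = src0, src1 = src1,
                                           dst0 = dst0, dst1 = dst1)),
            class = "warp_map")
}

#' Invert a warp map
#'
#' @param map A [warp_map()].
#' @return The inverse `warp_map` (source and target swapped).
#' @export
invert_warp_map <- function(map) {
  s <- map$segments
  structure(list(segments = tibble::tibble(src0 = s$dst0, src1 = s$dst1,
                                           dst0 = s$src0, dst1 = s$src1)),
            class = "warp_map")
}

#' Project spike times through a warp map
#'
#' Each spike inside a segment is mapped affinely within it; spikes before
#' the first or after the last segment are mapped by the affine extension of
#' the nearest segment. Ordering and spike counts are preserved.
#'
#' @param times Numeric spike times, seconds.
#' @param map A [warp_map()].
#' @return Warped spike times, same length and order class as input.
#' @export
warp_spikes <- function(times, map) {
  if (length(times) == 0) return(times)
  s <- map$segments
  slopes <- (s$dst1 - s$dst0) / (s$src1 - s$src0)
  idx <- findInterval(times, s$src0)
  idx[idx < 1] <- 1L
  idx[idx > nrow(s)] <- nrow(s)
  s$dst0[idx] + (times - s$src0[idx]) * slopes[idx]
}

#' Time-warp every trial of a set onto the reference axis
#'
#' Builds the reference timing from the set's own annotations, warps each
#' trial's spikes through its rendition's map, and returns a new set whose
#' annotations are the (identical) reference boundaries for every trial.
#'
#' @param set A [spike_train_set()].
#' @param ref_stat Reference statistic, see [reference_timing()].
#' @return A warped [spike_train_set()].
#' @export
warp_set <- function(set, ref_stat = "max") {
  reference <- reference_timing(set$renditions, ref_stat = ref_stat)
  trains <- spike_trains(set)
  ref_rend <- NULL
  warped <- purrr::map_dfr(seq_len(set$n_trials), function(k) {
    r <- set$renditions[set$renditions$trial == k, ]
    m <- warp_map(r, reference)
    tibble::tibble(trial = k, time_s = warp_spikes(trains[[k]], m))
  })
  # reference annotations: every trial shares the reference boundaries
  m1 <- warp_map(set$renditions[set$renditions$trial == 1, ], reference)
  syl_rows <- seq(1, nrow(m1$segments), by = 2)
  ref_ann <- purrr::map_dfr(seq_len(set$n_trials), function(k) {
    r <- set$renditions[set$renditions$trial == k, ]
    r <- r[order(r$syllable), ]
    tibble::tibble(trial = k,
                   block = as.integer(ceiling(k / 10)),
                   seq_onset = if ("seq_onset" %in% names(r)) r$seq_onset else 0,
                   syllable = r$syllable, label = r$label,
                   onset = m1$segments$dst0[syl_rows],
                   offset = m1$segments$dst1[syl_rows])
  })
  spike_train_set(warped, ref_ann, unit_id = set$unit_id,
                  series_type = set$series_type, n_trials = set$n_trials)
}

#' Reliability before and after time warping
#'
#' Quantifies how much of the trial-to-trial timing unreliability is
#' explained by syllable-duration variability: the between-block pooled
#' CorrCoef (mean of the off-diagonal entries of the block-pair matrix) is
#' computed on the raw trains and again after warping every rendition onto
#' the reference axis.
#'
#' @param set A [spike_train_set()] (typically a Var series).
#' @param width_ms Kernel width, ms.
#' @param ref_stat Reference statistic for the warp.
#' @return Tibble: `unit_id`, `series`, `width_ms`, `corrcoef_before`,
#'   `corrcoef_after`.
#' @export
warped_reliability <- function(set, width_ms = 10, ref_stat = "max") {
  before <- block_matrix(set, width_ms)
  after <- block_matrix(warp_set(set, ref_stat), width_ms)
  off_mean <- function(bm) {
    M <- bm$matrix
    mean(M[row(M) != col(M)], na.rm = TRUE)
  }
  tibble::tibble(unit_id = set$unit_id, series = set$series_type,
                 width_ms = width_ms,
                 corrcoef_before = off_mean(before),
                 corrcoef_after = off_mean(after))
}
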