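#' Construct a spike-train set
#'
#' A `spike_train_set` bundles everything the analysis needs for one unit and
#' one stimulus series: the spike times of every trial (sequence-relative
#' seconds, t = 0 at sequence onset) and the per-rendition stimulus
#' annotations (syllable labels, onsets and offsets). Sixty renditions grouped
#' into six blocks of ten is the canonical layout, but any positive number of
#' trials is accepted; block membership is `ceiling(trial / 10)`.
#'
#' @param spikes Tibble with columns `trial` (integer) and `time_s`
#'   (numeric seconds relative to sequence onset). One row per spike; trials
#'   with no spikes simply contribute no rows.
#' @param renditions Tibble with columns `trial`, `syllable` (1-based index
#'   within the sequence), `label` (e.g. `"A"`/`"B"`), `onset` and `offset`
#'   (sequence-relative seconds) and optionally `seq_onset` (absolute onset of
#'   the rendition, seconds).
#' @param unit_id Identifier for the unit (string).
#' @param series_type `"Same"` or `"Var"`.
#' @param n_trials Number of trials in the set. Defaults to the largest trial
#'   index present in `renditions`.
#'
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(spikes, renditions, unit_id = "unit1",
                            series_type = c("Same", "Var"),
                            n_trials = NULL) {
  series_type <- match.arg(series_type)
  spikes <- tibble::as_tibble(spikes)
  renditions <- tibble::as_tibble(renditions)
  stopifnot(all(c("trial", "time_s") %in% names(spikes)),
            all(c("trial", "syllable", "label", "onset", "offset") %in%
                  names(renditions)))
  if (any(renditions$offset <= renditions$onset)) {
    stopf("rendition annotations must have offset > onset")
  }
  n_trials <- n_trials %||% max(renditions$trial)
  if (nrow(spikes) > 0 && any(!spikes$trial %in% seq_len(n_trials))) {
    stopf("spike rows reference trials outside 1..%d", n_trials)
  }
  spikes <- dplyr::arrange(spikes, .data$trial, .data$time_s)
  structure(
    list(spikes = spikes, renditions = renditions,
         unit_id = as.character(unit_id), series_type = series_type,
         n_trials = as.integer(n_trials)),
    class = "spike_train_set"
  )
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set> unit %s, series %s: %d trials, %d spikes\n",
              x$unit_id, x$series_type, x$n_trials, nrow(x$spikes)))
  win <- evoked_window(x)
  cat(sprintf("  evoked window [0, %.3f) s; %d annotated syllables/trial\n",
              win[2], max(x$renditions$syllable)))
  invisible(x)
}

#' Extract per-trial spike-time vectors
#'
#' @param set A [spike_train_set()].
#' @return A list of numeric vectors, one per trial (empty trials give
#'   zero-length vectors), in trial order.
#' @export
spike_trains <- function(set) {
  stopifnot(inherits(set, "spike_train_set"))
  out <- vector("list", set$n_trials)
  idx <- split(set$spikes$time_s, factor(set$spikes$trial,
                                         levels = seq_len(set$n_trials)))
  for (k in seq_len(set$n_trials)) out[[k]] <- as.numeric(idx[[k]])
  out
}

#' Evoked analysis window of a set
#'
#' The evoked window runs from sequence onset (0) to the last syllable offset.
#' With varying renditions the common window ends at the maximum offset over
#' all renditions, so every trial's response is contained in it.
#'
#' @param set A [spike_train_set()].
#' @param trial Optional trial index; if given, that rendition's own window.
#' @return Numeric `c(t0, t1)` in seconds.
#' @export
evoked_window <- function(set, trial = NULL) {
  r <- set$renditions
  if (!is.null(trial)) r <- r[r$trial == trial, ]
  c(0, max(r$offset))
}

#' Per-trial block membership
#'
#' @param set A [spike_train_set()].
#' @return Integer vector: `ceiling(trial / 10)` for each trial.
#' @export
trial_blocks <- function(set) {
  as.integer(ceiling(seq_len(set$n_trials) / 10))
}
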