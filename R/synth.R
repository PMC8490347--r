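#' Syllable template
#'
#' Describes one syllable type of the playback sequence: its nominal duration
#' and the evoked firing-rate profile a responsive unit shows while the
#' syllable plays. The profile is an onset bump: silent until `latency`, then
#' an exponential decay from `amplitude` (Hz) with time constant `decay` (s),
#' truncated at the syllable offset. When a rendition stretches or compresses
#' the syllable, the profile is time-rescaled with it (integral preserved), so
#' response timing is locked to the sound, not to absolute time.
#'
#' @param label Syllable label, `"A"` or `"B"`.
#' @param base_duration Nominal syllable duration, seconds (> 0).
#' @param amplitude Peak evoked rate of the onset bump, Hz (>= 0).
#' @param latency Response latency after syllable onset, seconds.
#' @param decay Exponential decay constant of the bump, seconds.
#' @return A `syllable_template` object.
#' @export
syllable_template <- function(label, base_duration, amplitude = 60,
                              latency = 0.01, decay = 0.04) {
  stopifnot(base_duration > 0, amplitude >= 0, latency >= 0, decay > 0)
  structure(list(label = label, base_duration = base_duration,
                 amplitude = amplitude, latency = latency, decay = decay),
            class = "syllable_template")
}

#' Default A/B syllable templates
#'
#' Two syllable types whose durations (120 and 160 ms) and the 30-50 ms
#' inter-syllable gaps produce an ABAB sequence of roughly 0.7 s, matching the
#' zebra-finch playback design the generator emulates.
#'
#' @param amplitude Peak evoked rate, Hz, shared by both templates.
#' @return List of two `syllable_template`s named `A` and `B`.
#' @export
default_templates <- function(amplitude = 60) {
  list(A = syllable_template("A", 0.120, amplitude = amplitude),
       B = syllable_template("B", 0.160, amplitude = amplitude))
}

#' Series specification
#'
#' Parameters of one stimulus series: 60 renditions of an ABAB sequence at one
#' per second. In the `Same` regime every rendition is identical; in the `Var`
#' regime each rendition independently jitters the syllable durations
#' (lognormal, coefficient of variation `duration_jitter_cv`) and the response
#' timing within each syllable (Gaussian, SD `timing_jitter_sd`).
#'
#' @param series_type `"Same"` or `"Var"`.
#' @param n_renditions Number of renditions (default 60).
#' @param presentation_rate Sequence presentations per second (default 1).
#' @param inter_syllable_gap Silent gap between syllables, seconds
#'   (default 0.04, within the 30-50 ms range of the emulated stimuli).
#' @param duration_jitter_cv CV of per-rendition syllable-duration scaling
#'   (must be 0 for `Same`; default 0.1 for `Var`).
#' @param timing_jitter_sd SD of per-syllable spike-timing shifts, seconds
#'   (must be 0 for `Same`; default 0.010 for `Var`).
#' @param seed Integer seed for the series' own RNG stream.
#' @return A `series_spec` object.
#' @export
series_spec <- function(series_type = c("Same", "Var"), n_renditions = 60,
                        presentation_rate = 1, inter_syllable_gap = 0.04,
                        duration_jitter_cv = NULL, timing_jitter_sd = NULL,
                        seed = 1L) {
  series_type <- match.arg(series_type)
  if (is.null(duration_jitter_cv)) {
    duration_jitter_cv <- if (series_type == "Var") 0.1 else 0
  }
  if (is.null(timing_jitter_sd)) {
    timing_jitter_sd <- if (series_type == "Var") 0.010 else 0
  }
  if (series_type == "Same" &&
      (duration_jitter_cv != 0 || timing_jitter_sd != 0)) {
    stopf("Same series must have zero duration and timing jitter")
  }
  stopifnot(n_renditions > 0, presentation_rate > 0, inter_syllable_gap >= 0,
            duration_jitter_cv >= 0, timing_jitter_sd >= 0)
  structure(list(series_type = series_type,
                 n_renditions = as.integer(n_renditions),
                 presentation_rate = presentation_rate,
                 inter_syllable_gap = inter_syllable_gap,
                 duration_jitter_cv = duration_jitter_cv,
                 timing_jitter_sd = timing_jitter_sd,
                 seed = as.integer(seed)),
            class = "series_spec")
}

#' Repetition-adaptation model
#'
#' Multiplicative gain applied to the evoked response profile on trial `k`:
#' `gain(k) = g_inf + (1 - g_inf) * exp(-(k - 1) / tau)`, so the first trial
#' has gain 1 and the response decays towards the asymptote `g_inf` with an
#' e-folding constant of `tau` trials. `g_inf = 1` disables adaptation.
#'
#' @param g_inf Asymptotic gain in (0, 1].
#' @param tau E-folding constant in trials (> 0).
#' @param baseline_rate Spontaneous firing rate, Hz (>= 0).
#' @return An `adaptation_model` object.
#' @export
adaptation_model <- function(g_inf = 1, tau = 4, baseline_rate = 5) {
  stopifnot(g_inf > 0, g_inf <= 1, tau > 0, baseline_rate >= 0)
  structure(list(g_inf = g_inf, tau = tau, baseline_rate = baseline_rate),
            class = "adaptation_model")
}

#' Adaptation gain at given trials
#'
#' @param adapt An [adaptation_model()].
#' @param trial Trial indices (1-based).
#' @return Numeric gains in (0, 1].
#' @export
adaptation_gain <- function(adapt, trial) {
  adapt$g_inf + (1 - adapt$g_inf) * exp(-(trial - 1) / adapt$tau)
}

#' Generate rendition annotations for a series
#'
#' Builds the ABAB syllable boundaries of every rendition. `Same` series reuse
#' one set of boundaries; `Var` series scale each syllable's duration by an
#' independent lognormal factor with unit mean and the spec's CV (gaps stay
#' fixed). Sequence onsets are spaced at `1 / presentation_rate`.
#'
#' @param spec A [series_spec()].
#' @param templates List of two [syllable_template()]s named `A` and `B`.
#' @return Tibble with columns `trial`, `block`, `seq_onset`, `syllable`,
#'   `label`, `onset`, `offset` (onset/offset sequence-relative seconds).
#' @export
make_renditions <- function(spec, templates) {
  stopifnot(inherits(spec, "series_spec"),
            all(c("A", "B") %in% names(templates)))
  labels <- c("A", "B", "A", "B")
  base_dur <- vapply(templates[labels], `[[`, numeric(1), "base_duration")
  cv <- spec$duration_jitter_cv

  durs <- with_rng(child_seed(spec$seed, "renditions"), {
    if (cv == 0) {
      matrix(rep(base_dur, spec$n_renditions), nrow = spec$n_renditions,
             byrow = TRUE)
    } else {
      sdlog <- sqrt(log(1 + cv^2))
      # unit-mean lognormal scaling, resampled (bounded) if degenerate
      draw <- function() {
        f <- matrix(exp(rnorm(4 * spec$n_renditions, -sdlog^2 / 2, sdlog)),
                    nrow = spec$n_renditions)
        sweep(f, 2, base_dur, `*`)
      }
      d <- draw()
      tries <- 0
      while (any(d <= 0) && tries < 10) { d <- draw(); tries <- tries + 1 }
      if (any(d <= 0)) stopf("could not draw positive syllable durations")
      d
    }
  })

  rows <- purrr::map_dfr(seq_len(spec$n_renditions), function(k) {
    d <- durs[k, ]
    onsets <- cumsum(c(0, head(d, -1) + spec$inter_syllable_gap))
    tibble::tibble(
      trial = k, block = as.integer(ceiling(k / 10)),
      seq_onset = (k - 1) / spec$presentation_rate,
      syllable = 1:4, label = labels,
      onset = onsets, offset = onsets + d)
  })
  rows
}

# Evoked-rate profile of one syllable occurrence, time-rescaled to the
# realized duration (integral preserved).
syllable_rate <- function(t, tmpl, onset, duration, shift = 0) {
  scale <- tmpl$base_duration / duration
  u <- (t - onset - shift) * scale
  r <- ifelse(u >= tmpl$latency & u < tmpl$base_duration,
              tmpl$amplitude * exp(-(u - tmpl$latency) / tmpl$decay), 0)
  r * scale
}

#' Simulate spike trains for a set of renditions
#'
#' Draws one spike train per rendition from an inhomogeneous Poisson process
#' by thinning (Lewis-Shedler). The rate on trial `k` is
#' `baseline + gain(k) * sum over syllables of the (rescaled) template
#' profile`, each syllable optionally shifted by an independent Gaussian
#' timing jitter. The spontaneous epoch `[-0.2, 0)` is driven by the baseline
#' alone. No refractory period is imposed unless `dead_time > 0`.
#'
#' @param renditions Rendition tibble from [make_renditions()].
#' @param templates Templates named `A` and `B`.
#' @param adapt An [adaptation_model()].
#' @param timing_jitter_sd Per-syllable Gaussian timing jitter SD, seconds.
#' @param seed Integer seed (one RNG stream per set).
#' @param unit_id,series_type Passed to the returned [spike_train_set()].
#' @param margin Seconds of simulated time past the last syllable offset.
#' @param dead_time Optional absolute refractory period, seconds.
#' @return A [spike_train_set()].
#' @export
simulate_trains <- function(renditions, templates, adapt,
                            timing_jitter_sd = 0, seed = NULL,
                            unit_id = "unit1", series_type = "Same",
                            margin = 0.05, dead_time = 0) {
  stopifnot(inherits(adapt, "adaptation_model"), timing_jitter_sd >= 0)
  trials <- sort(unique(renditions$trial))
  spikes <- with_rng(seed, {
    purrr::map_dfr(trials, function(k) {
      r <- renditions[renditions$trial == k, ]
      gain <- adaptation_gain(adapt, k)
      shifts <- if (timing_jitter_sd > 0) {
        rnorm(nrow(r), 0, timing_jitter_sd)
      } else rep(0, nrow(r))
      t0 <- -0.2
      t1 <- max(r$offset) + margin
      rate_fun <- function(t) {
        evoked <- rep(0, length(t))
        for (i in seq_len(nrow(r))) {
          tmpl <- templates[[r$label[i]]]
          evoked <- evoked + syllable_rate(t, tmpl, r$onset[i],
                                           r$offset[i] - r$onset[i],
                                           shifts[i])
        }
        adapt$baseline_rate + gain * evoked
      }
      peak <- vapply(seq_len(nrow(r)), function(i) {
        tmpl <- templates[[r$label[i]]]
        tmpl$amplitude * tmpl$base_duration / (r$offset[i] - r$onset[i])
      }, numeric(1))
      rate_max <- adapt$baseline_rate + gain * max(c(peak, 0)) * 1.0001
      n_cand <- rpois(1, rate_max * (t1 - t0))
      cand <- sort(runif(n_cand, t0, t1))
      keep <- runif(n_cand) < rate_fun(cand) / rate_max
      times <- cand[keep]
      if (dead_time > 0 && length(times) > 1) {
        ok <- c(TRUE, diff(times) >= dead_time)
        # enforce sequentially: rebuild keeping only spikes >= dead_time apart
        out <- times[1]
        for (tt in times[-1]) if (tt - out[length(out)] >= dead_time) {
          out <- c(out, tt)
        }
        times <- out
      }
      tibble::tibble(trial = k, time_s = times)
    })
  })
  spike_train_set(spikes, renditions, unit_id = unit_id,
                  series_type = series_type, n_trials = max(trials))
}

#' Simulate one unit's responses to a series
#'
#' Convenience wrapper: builds renditions with [make_renditions()] and spike
#' trains with [simulate_trains()], both seeded from the spec's seed.
#'
#' @inheritParams make_renditions
#' @inheritParams simulate_trains
#' @return A [spike_train_set()].
#' @export
simulate_series <- function(spec, templates = default_templates(),
                            adapt = adaptation_model(), unit_id = "unit1") {
  rend <- make_renditions(spec, templates)
  simulate_trains(rend, templates, adapt,
                  timing_jitter_sd = spec$timing_jitter_sd,
                  seed = child_seed(spec$seed, "trains"),
                  unit_id = unit_id, series_type = spec$series_type)
}

#' Expected evoked spike count per trial (analytic)
#'
#' Closed-form expectation of the spike count in a rendition's evoked window
#' under the generator model: baseline mass plus the gain-scaled integral of
#' each syllable's rate bump (time-rescaling preserves the integral).
#' Useful as an independent oracle for rate and adaptation estimates.
#'
#' @param renditions Rendition tibble (one or more trials).
#' @param templates Templates named `A` and `B`.
#' @param adapt An [adaptation_model()].
#' @return Tibble with `trial`, `duration`, `expected_count`, `expected_rate`.
#' @export
expected_evoked_count <- function(renditions, templates, adapt) {
  integral <- function(tmpl) {
    tmpl$amplitude * tmpl$decay *
      (1 - exp(-(tmpl$base_duration - tmpl$latency) / tmpl$decay))
  }
  renditions |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(
      duration = max(.data$offset),
      evoked_mass = sum(vapply(templates[.data$label], integral, numeric(1))),
      .groups = "drop") |>
    dplyr::mutate(
      gain = adaptation_gain(adapt, .data$trial),
      expected_count = adapt$baseline_rate * .data$duration +
        .data$gain * .data$evoked_mass,
      expected_rate = .data$expected_count / .data$duration) |>
    dplyr::select("trial", "duration", "expected_count", "expected_rate")
}
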