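#' Write / read the spike-table format
#'
#' The on-disk spike table is a UTF-8 CSV with one row per spike:
#' `unit_id` (string), `series` (`Same`/`Var`), `trial` (1..60), `time_s`
#' (seconds relative to sequence onset, 6 decimals). Times are sorted within
#' each (unit, series, trial); a round trip is lossless at 1e-6 s.
#'
#' @param sets A [spike_train_set()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(sets, path) {
  if (inherits(sets, "spike_train_set")) sets <- list(sets)
  tab <- purrr::map_dfr(sets, function(s) {
    dplyr::mutate(s$spikes, unit_id = s$unit_id, series = s$series_type)
  }) |>
    dplyr::mutate(time_s = round(.data$time_s, 6)) |>
    dplyr::arrange(.data$unit_id, .data$series, .data$trial, .data$time_s) |>
    dplyr::select("unit_id", "series", "trial", "time_s")
  readr::write_csv(tab, path)
  invisible(path)
}

#' @rdname write_spike_table
#' @param max_trial Largest admissible trial index (default 60).
#' @return `read_spike_table()`: tibble with columns `unit_id`, `series`,
#'   `trial`, `time_s`.
#' @export
read_spike_table <- function(path, max_trial = 60) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    unit_id = readr::col_character(), series = readr::col_character(),
    trial = readr::col_integer(), time_s = readr::col_double()))
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    stopf("malformed spike table %s: first problem at line %d (%s)",
          path, probs$row[1] + 1L, probs$expected[1])
  }
  if (nrow(tab) > 0) {
    if (!all(tab$series %in% c("Same", "Var"))) {
      stopf("spike table %s: series must be 'Same' or 'Var'", path)
    }
    if (any(tab$trial < 1 | tab$trial > max_trial)) {
      bad <- which(tab$trial < 1 | tab$trial > max_trial)[1]
      stopf("spike table %s: trial index %d out of 1..%d (row %d)",
            path, tab$trial[bad], max_trial, bad)
    }
    sorted <- tab |>
      dplyr::group_by(.data$unit_id, .data$series, .data$trial) |>
      dplyr::mutate(unsorted = is.unsorted(.data$time_s)) |>
      dplyr::ungroup()
    if (any(sorted$unsorted)) {
      warn("spike times were not sorted within trials; sorting")
      tab <- dplyr::arrange(tab, .data$unit_id, .data$series, .data$trial,
                            .data$time_s)
    }
  }
  tab
}

#' Write / read the annotation-table format
#'
#' CSV with one row per syllable occurrence: `series`, `trial`,
#' `syllable_index` (1..4), `label` (`A`/`B`), `onset_s`, `offset_s`
#' (sequence-relative seconds, 6 decimals).
#'
#' @param renditions Rendition tibble (as in [spike_train_set()]) with a
#'   `series` column, or a named list `list(Same = ..., Var = ...)`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(renditions, path) {
  if (is.list(renditions) && !is.data.frame(renditions)) {
    renditions <- purrr::imap_dfr(renditions, function(r, nm) {
      dplyr::mutate(r, series = nm)
    })
  }
  tab <- renditions |>
    dplyr::transmute(series = .data$series, trial = .data$trial,
                     syllable_index = .data$syllable, label = .data$label,
                     onset_s = round(.data$onset, 6),
                     offset_s = round(.data$offset, 6)) |>
    dplyr::arrange(.data$series, .data$trial, .data$syllable_index)
  readr::write_csv(tab, path)
  invisible(path)
}

#' @rdname write_annotation_table
#' @export
read_annotation_table <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    series = readr::col_character(), trial = readr::col_integer(),
    syllable_index = readr::col_integer(), label = readr::col_character(),
    onset_s = readr::col_double(), offset_s = readr::col_double()))
  if (nrow(readr::problems(tab)) > 0) {
    stopf("malformed annotation table %s (line %d)",
          path, readr::problems(tab)$row[1] + 1L)
  }
  if (any(tab$offset_s <= tab$onset_s)) {
    stopf("annotation table %s: offsets must exceed onsets", path)
  }
  tab
}

#' Assemble spike-train sets from spike and annotation tables
#'
#' @param spikes Spike tibble from [read_spike_table()].
#' @param annotations Annotation tibble from [read_annotation_table()].
#' @return Named list of [spike_train_set()]s, one per (unit, series), names
#'   `"<unit_id>.<series>"`.
#' @export
tables_to_sets <- function(spikes, annotations) {
  combos <- dplyr::distinct(spikes, .data$unit_id, .data$series)
  out <- purrr::pmap(combos, function(unit_id, series) {
    sp <- spikes[spikes$unit_id == unit_id & spikes$series == series, ]
    an <- annotations[annotations$series == series, ]
    if (nrow(an) == 0) stopf("no annotations for series %s", series)
    rend <- tibble::tibble(trial = an$trial,
                           block = as.integer(ceiling(an$trial / 10)),
                           seq_onset = an$trial - 1,
                           syllable = an$syllable_index, label = an$label,
                           onset = an$onset_s, offset = an$offset_s)
    spike_train_set(tibble::tibble(trial = sp$trial, time_s = sp$time_s),
                    rend, unit_id = unit_id, series_type = series)
  })
  stats::setNames(out, paste(combos$unit_id, combos$series, sep = "."))
}

default_config <- function() {
  list(
    seed = 1L, n_units = 20L,
    templates = list(duration_a = 0.120, duration_b = 0.160,
                     amplitude = 60, latency = 0.01, decay = 0.04),
    series = list(n_renditions = 60L, presentation_rate = 1,
                  inter_syllable_gap = 0.04,
                  var_duration_jitter_cv = 0.1,
                  var_timing_jitter_sd = 0.010),
    adaptation = list(g_inf = 0.6, tau = 4, baseline_rate = 5),
    analysis = list(width_ms = 10,
                    widths_ms = c(5, 10, 20, 50, 100, 200),
                    n_perm = 100, alpha = 0.05))
}

#' Read and validate a run configuration
#'
#' Configurations are YAML files mirroring [default_config()]: generator
#' templates, series parameters, adaptation model, analysis settings and the
#' global seed. Unknown keys (at top level or within a section) are rejected
#' so typos cannot silently fall back to defaults; omitted keys take the
#' defaults.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Validated config list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  for (k in names(user)) {
    if (is.list(cfg[[k]])) {
      badk <- setdiff(names(user[[k]]), names(cfg[[k]]))
      if (length(badk)) {
        stopf("unknown config key(s) under '%s': %s", k,
              paste(badk, collapse = ", "))
      }
      cfg[[k]][names(user[[k]])] <- user[[k]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  stopifnot(cfg$n_units >= 1, cfg$seed == as.integer(cfg$seed))
  cfg
}

config_templates <- function(cfg) {
  t <- cfg$templates
  list(A = syllable_template("A", t$duration_a, t$amplitude, t$latency, t$decay),
       B = syllable_template("B", t$duration_b, t$amplitude, t$latency, t$decay))
}

#' Simulate the full two-series study defined by a configuration
#'
#' Generates `n_units` synthetic units, each presented with one Same and one
#' Var series, every series on its own RNG substream derived from the global
#' seed (so any unit/series can be regenerated independently).
#'
#' @param cfg Config list from [read_run_config()].
#' @return List with `same` and `var` (lists of [spike_train_set()]s, one
#'   per unit).
#' @export
simulate_study <- function(cfg = read_run_config()) {
  templates <- config_templates(cfg)
  adapt <- adaptation_model(cfg$adaptation$g_inf, cfg$adaptation$tau,
                            cfg$adaptation$baseline_rate)
  s <- cfg$series
  make_unit <- function(u, type) {
    jcv <- if (type == "Var") s$var_duration_jitter_cv else 0
    jsd <- if (type == "Var") s$var_timing_jitter_sd else 0
    spec <- series_spec(type, s$n_renditions, s$presentation_rate,
                        s$inter_syllable_gap, duration_jitter_cv = jcv,
                        timing_jitter_sd = jsd,
                        seed = child_seed(cfg$seed, sprintf("%s-u%d", type, u)))
    simulate_series(spec, templates, adapt, unit_id = sprintf("unit%02d", u))
  }
  list(same = purrr::map(seq_len(cfg$n_units), make_unit, type = "Same"),
       var = purrr::map(seq_len(cfg$n_units), make_unit, type = "Var"))
}

#' Run the full analysis pipeline and write its outputs
#'
#' Simulates the configured study, runs every analysis stage, and writes CSV
#' outputs to `out_dir`: spike and annotation tables, trial/block RS tables,
#' adaptation fits, block-pair CorrCoef matrices (tidy long format), the
#' kernel-width sweep, before/after warp reliability, AB-pair metrics, and a
#' `run_info.txt` recording the seed and a hash of the configuration.
#' Identical config and seed give byte-identical numeric outputs.
#'
#' @param cfg Config list from [read_run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Named list of the tables written, invisibly.
#' @export
run_pipeline <- function(cfg = read_run_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_study(cfg)
  both <- c(study$same, study$var)
  w <- cfg$analysis$width_ms

  write_spike_table(both, file.path(out_dir, "spikes.csv"))
  write_annotation_table(
    list(Same = study$same[[1]]$renditions, Var = study$var[[1]]$renditions),
    file.path(out_dir, "annotations.csv"))

  rs_trial <- purrr::map_dfr(both, trial_rs) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ round(.x, 6)))
  rs_block <- purrr::map_dfr(both, block_rs) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ round(.x, 6)))
  adapt_tab <- purrr::map_dfr(both, function(s) tidy(adaptation_rate(s))) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ round(.x, 6)))
  mats <- purrr::map_dfr(both, function(s) tidy(block_matrix(s, w))) |>
    dplyr::mutate(corrcoef = round(.data$corrcoef, 6))
  sweep <- width_sweep(study$same, study$var,
                       widths_ms = cfg$analysis$widths_ms,
                       n_perm = cfg$analysis$n_perm,
                       seed = child_seed(cfg$seed, "sweep"),
                       alpha = cfg$analysis$alpha)
  sweep_tab <- dplyr::mutate(sweep$by_width,
                             dplyr::across(dplyr::where(is.numeric),
                                           ~ round(.x, 6)))
  warp_tab <- purrr::map_dfr(study$var, warped_reliability, width_ms = w) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ round(.x, 6)))
  pair_tab <- purrr::map_dfr(both, function(s) pair_metrics(s, w)$trials) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ round(.x, 6)))

  readr::write_csv(rs_trial, file.path(out_dir, "rs_trial.csv"))
  readr::write_csv(rs_block, file.path(out_dir, "rs_block.csv"))
  readr::write_csv(adapt_tab, file.path(out_dir, "adaptation.csv"))
  readr::write_csv(mats, file.path(out_dir, "corrcoef_matrices.csv"))
  readr::write_csv(sweep_tab, file.path(out_dir, "width_sweep.csv"))
  readr::write_csv(warp_tab, file.path(out_dir, "warp_reliability.csv"))
  readr::write_csv(pair_tab, file.path(out_dir, "pair_metrics.csv"))
  writeLines(c(sprintf("seed: %d", cfg$seed),
               sprintf("config_hash: %s", rlang::hash(cfg)),
               sprintf("crossover_width_ms: %s",
                       format(sweep$crossover_width_ms))),
             file.path(out_dir, "run_info.txt"))
  invisible(list(rs_trial = rs_trial, rs_block = rs_block,
                 adaptation = adapt_tab, matrices = mats,
                 sweep = sweep, warp = warp_tab, pairs = pair_tab))
}
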