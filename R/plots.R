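#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_ribbon
#'   geom_point scale_fill_viridis_c scale_x_log10 labs theme_minimal
#' @export
ggplot2::autoplot

#' Heatmap of a block-pair CorrCoef matrix
#'
#' @param object A `corrcoef_matrix` from [block_matrix()].
#' @param ... Unused.
#' @return A ggplot: blocks on both axes, fill = CorrCoef.
#' @export
autoplot.corrcoef_matrix <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$block_j, y = .data$block_i,
                fill = .data$corrcoef)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(min(0, min(d$corrcoef, na.rm = TRUE)), 1),
                         name = "CorrCoef") +
    ggplot2::scale_y_reverse(breaks = 1:6) +
    ggplot2::scale_x_continuous(breaks = 1:6) +
    labs(x = "block", y = "block",
         title = sprintf("Spike-timing reliability, unit %s (%s), %g ms kernel",
                         object$unit_id, object$series, object$width_ms)) +
    theme_minimal()
}

#' Kernel-width sweep curves
#'
#' Mean CorrCoef against kernel width for the Same series, the Var series and
#' the spike-time-permuted reference, with SEM ribbons where available.
#'
#' @param object A `sweep_result` from [width_sweep()].
#' @param ... Unused.
#' @return A ggplot with a log-scaled width axis.
#' @export
autoplot.sweep_result <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$width_ms, y = .data$mean_corrcoef,
                colour = .data$series, fill = .data$series)) +
    geom_ribbon(aes(ymin = .data$mean_corrcoef - .data$sem,
                    ymax = .data$mean_corrcoef + .data$sem),
                alpha = 0.2, colour = NA, na.rm = TRUE) +
    geom_line() + geom_point() +
    scale_x_log10() +
    labs(x = "Gaussian kernel width (ms)", y = "mean CorrCoef",
         title = "Reliability vs kernel width") +
    theme_minimal()
}

#' Raster plot of a spike-train set
#'
#' @param object A [spike_train_set()].
#' @param ... Unused.
#' @return A ggplot raster (trials on y, time on x) with syllable spans
#'   shaded.
#' @export
autoplot.spike_train_set <- function(object, ...) {
  sp <- object$spikes
  syl <- object$renditions
  ggplot() +
    ggplot2::geom_rect(data = syl,
                       aes(xmin = .data$onset, xmax = .data$offset,
                           ymin = .data$trial - 0.5, ymax = .data$trial + 0.5),
                       fill = "grey85") +
    geom_point(data = sp, aes(x = .data$time_s, y = .data$trial),
               shape = "|", size = 2) +
    labs(x = "time from sequence onset (s)", y = "trial",
         title = sprintf("unit %s, %s series", object$unit_id,
                         object$series_type)) +
    theme_minimal()
}

#' Block-level response-strength curves
#'
#' @param block_tab Tibble from [block_rs()] (possibly several units/series
#'   row-bound).
#' @return A ggplot of mean block RS per series with SEM ribbons.
#' @export
plot_block_rs <- function(block_tab) {
  d <- block_tab |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$series, .data$block) |>
    dplyr::summarise(mean_rs = mean(.data$rs),
                     sem = sd(.data$rs) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot(d, aes(x = .data$block, y = .data$mean_rs,
                colour = .data$series, fill = .data$series)) +
    geom_ribbon(aes(ymin = .data$mean_rs - .data$sem,
                    ymax = .data$mean_rs + .data$sem),
                alpha = 0.2, colour = NA) +
    geom_line() + geom_point() +
    ggplot2::scale_x_continuous(breaks = 1:6) +
    labs(x = "block (10 trials)", y = "mean RS", title = "Response strength") +
    theme_minimal()
}
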