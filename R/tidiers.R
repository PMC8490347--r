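#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an adaptation fit
#'
#' @param x An `adaptation_fit` from [adaptation_rate()].
#' @param ... Unused.
#' @return One-row tibble: `unit_id`, `series`, `slope`, `intercept`,
#'   `n_points`, `valid`.
#' @export
tidy.adaptation_fit <- function(x, ...) {
  tibble::tibble(unit_id = x$unit_id, series = x$series, slope = x$slope,
                 intercept = x$intercept, n_points = x$n_points,
                 valid = x$valid)
}

#' @rdname tidy.adaptation_fit
#' @return `glance()`: one-row tibble with fit summary statistics
#'   (`r_squared`, `sigma`, `p_value`).
#' @export
glance.adaptation_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(r_squared = sm$r.squared, sigma = sm$sigma,
                 p_value = sm$coefficients[2, 4], n = x$n_points)
}

#' Tidy a block-pair CorrCoef matrix
#'
#' @param x A `corrcoef_matrix` from [block_matrix()].
#' @param ... Unused.
#' @return Long tibble: `unit_id`, `series`, `width_ms`, `block_i`,
#'   `block_j`, `corrcoef` (all entries, including the symmetric ones).
#' @export
tidy.corrcoef_matrix <- function(x, ...) {
  M <- x$matrix
  n <- nrow(M)
  tibble::tibble(unit_id = x$unit_id, series = x$series,
                 width_ms = x$width_ms,
                 block_i = rep(seq_len(n), times = n),
                 block_j = rep(seq_len(n), each = n),
                 corrcoef = as.vector(M))
}

#' Tidy a kernel-width sweep
#'
#' @param x A `sweep_result` from [width_sweep()].
#' @param ... Unused.
#' @return Long tibble: `width_ms`, `series` (`Same`, `Var`, `Permuted`),
#'   `mean_corrcoef`, `sem`, plus `diff` and `p_value` on the Same rows.
#' @export
tidy.sweep_result <- function(x, ...) {
  b <- x$by_width
  dplyr::bind_rows(
    tibble::tibble(width_ms = b$width_ms, series = "Same",
                   mean_corrcoef = b$mean_same, sem = b$sem_same,
                   diff = b$diff, p_value = b$p_value),
    tibble::tibble(width_ms = b$width_ms, series = "Var",
                   mean_corrcoef = b$mean_var, sem = b$sem_var,
                   diff = NA_real_, p_value = NA_real_),
    tibble::tibble(width_ms = b$width_ms, series = "Permuted",
                   mean_corrcoef = b$mean_perm, sem = NA_real_,
                   diff = NA_real_, p_value = NA_real_))
}

#' @rdname tidy.sweep_result
#' @return `glance()`: one-row tibble with `crossover_width_ms`, `alpha`,
#'   `n_perm`.
#' @export
glance.sweep_result <- function(x, ...) {
  tibble::tibble(crossover_width_ms = x$crossover_width_ms,
                 alpha = x$alpha, n_perm = x$n_perm)
}
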