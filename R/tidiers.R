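# broom-style tidiers for the result objects.

#' Tidy barrier metrics into one row per side and metric
#'
#' @param x A [barrier_metrics()] object.
#' @param ... Unused.
#' @return A tibble `metric`, `side`, `value`.
#' @method tidy barrier_metrics
#' @export
tidy.barrier_metrics <- function(x, ...) {
  tibble(metric = c("d", "d", "w", "w"),
         side = c("left", "right", "left", "right"),
         value = c(x$d_left, x$d_right, x$w_left, x$w_right))
}

#' One-row summary of barrier metrics
#'
#' @inheritParams tidy.barrier_metrics
#' @return A one-row tibble `d`, `w`, `d_left`, `d_right`, `w_left`,
#'   `w_right`, `d_defined`.
#' @method glance barrier_metrics
#' @export
glance.barrier_metrics <- function(x, ...) {
  tibble(d = x$d, w = x$w, d_left = x$d_left, d_right = x$d_right,
         w_left = x$w_left, w_right = x$w_right, d_defined = x$d_defined)
}

#' Tidy a profile comparison into its per-offset differences
#'
#' @param x A [compare_conditions()] result.
#' @param ... Unused.
#' @return The `difference` tibble (`offset`, `delta`).
#' @method tidy profile_comparison
#' @export
tidy.profile_comparison <- function(x, ...) x$difference

#' One-row summary of a profile comparison
#'
#' @inheritParams tidy.profile_comparison
#' @return A one-row tibble `central_delta`, `flank_amplitude_delta`, `w`,
#'   `d`.
#' @method glance profile_comparison
#' @export
glance.profile_comparison <- function(x, ...) {
  tibble(central_delta = x$central_delta,
         flank_amplitude_delta = x$flank_amplitude_delta,
         w = x$w, d = x$d)
}
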