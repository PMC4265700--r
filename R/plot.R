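#' Plot a deviation distribution
#'
#' Bar chart of the binned deviation percentages, colored with the same
#' blue-green-red diverging map used for deviation inspection.
#'
#' @param object a `deviation_summary` (from [summarize_deviation()]).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.deviation_summary <- function(object, ...) {
  bins <- object$bins |>
    dplyr::mutate(mid = (.data$lower + .data$upper) / 2)
  rng <- max(abs(c(bins$lower, bins$upper)))
  cols <- colorize_deviation(bins$mid, range = rng)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$mid, y = .data$percent)) +
    ggplot2::geom_col(fill = cols$hex, color = "grey30",
                      width = (bins$upper - bins$lower) * 0.95) +
    ggplot2::geom_vline(xintercept = object$mean, linetype = "dashed") +
    ggplot2::labs(x = "signed deviation (mm)", y = "vertices (%)",
                  title = sprintf("mean %.4f mm, %.1f%% within %.3f mm",
                                  object$mean, object$coverage,
                                  object$threshold)) +
    ggplot2::theme_minimal()
}

#' Plot a stress-strain curve with an optional Ogden fit
#'
#' @param object an `ogden_fit` (from [fit_ogden()]) or a
#'   [stress_strain_curve()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ogden_fit <- function(object, ...) {
  grid <- tibble::tibble(stretch = seq(min(object$curve$stretch),
                                       max(object$curve$stretch),
                                       length.out = 200))
  grid$stress_mpa <- uniaxial_stress(grid$stretch, object$params)
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$stretch, y = .data$stress_mpa)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, color = "firebrick") +
    ggplot2::labs(x = "stretch", y = "uniaxial stress (MPa)",
                  title = sprintf("Ogden order %d fit, RMS %.3g MPa",
                                  object$params$N, object$rms)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ogden_fit
#' @export
autoplot.stress_strain_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$stretch, y = .data$stress_mpa)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "stretch", y = "uniaxial stress (MPa)") +
    ggplot2::theme_minimal()
}

#' Plot per-method error rates
#'
#' @param object an `error_rate_report` (from [build_report()]).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.error_rate_report <- function(object, ...) {
  ggplot2::ggplot(object$eta,
                  ggplot2::aes(x = .data$quantity, y = .data$eta,
                               fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = expression(eta),
                  title = sprintf("error rates vs %s", object$reference)) +
    ggplot2::theme_minimal()
}
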