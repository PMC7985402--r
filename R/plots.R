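#' Plot a permutation null distribution
#'
#' Histogram of the null NSE values with the observed NSE marked.
#'
#' @param object A `permutation_null`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.permutation_null <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_nse)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_nse,
                        colour = "purple", linewidth = 1) +
    ggplot2::labs(
      x = "NSE under outcome permutation",
      y = "count",
      title = sprintf("observed NSE %.4f, p = %.4g",
                      object$observed_nse, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the electrode-averaged importance profile
#'
#' @param profile Output of [frequency_profile()].
#' @param peaks Optional peak frequencies (from [find_peaks()]) to mark.
#' @param threshold_sd Draw the mean + k SD selection line.
#' @return A ggplot object.
#' @export
plot_frequency_profile <- function(profile, peaks = NULL, threshold_sd = 1) {
  cut <- mean(profile$importance) + threshold_sd * sd(profile$importance)
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$freq, y = .data$importance)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = cut, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "frequency (Hz)",
                  y = "importance (electrode mean)") +
    ggplot2::theme_minimal()
  if (length(peaks)) {
    p <- p + ggplot2::geom_vline(xintercept = peaks, colour = "purple",
                                 alpha = 0.5)
  }
  p
}

#' Scalp topography of importance at one frequency
#'
#' Schematic top view (nose up): one point per electrode coloured by
#' importance, with a head outline.
#'
#' @param topography Output of [importance_topography()].
#' @return A ggplot object.
#' @export
plot_topography <- function(topography) {
  theta <- seq(0, 2 * pi, length.out = 200)
  head <- tibble(x = 1.15 * cos(theta), y = 1.15 * sin(theta))
  ggplot2::ggplot(topography, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = head, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$importance), size = 4) +
    ggplot2::geom_text(ggplot2::aes(label = .data$channel), size = 2,
                       vjust = -1.2) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
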