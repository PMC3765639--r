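#' Plot a grayscale image
#'
#' @param img Numeric matrix.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_gray <- function(img, title = NULL) {
  stop_not_matrix(img)
  df <- tidyr::expand_grid(col = seq_len(ncol(img)),
                           row = seq_len(nrow(img)))
  df$value <- as.vector(img) # column-major; expand_grid varies `row` fastest
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot a centered amplitude spectrum
#'
#' Displays `log1p(amplitude)`, min-max scaled — the same compression the
#' binarization thresholds.
#'
#' @param spec Matrix from [amplitude_spectrum()].
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spec, title = NULL) {
  plot_gray(log1p(spec), title = title)
}

#' @describeIn run_experiment_monotonicity Mean index (with SD ribbons)
#'   against jitter, one line per method.
#' @param object A `bw_jitter_experiment`.
#' @export
autoplot.bw_jitter_experiment <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$jitter, y = .data$mean_index,
                               colour = .data$method,
                               fill = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_index -
                                        .data$sd_index,
                                      ymax = .data$mean_index +
                                        .data$sd_index),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "angular jitter SD (degrees)",
                  y = "collagen orientation index",
                  colour = "method", fill = "method") +
    ggplot2::theme_minimal()
}

#' @describeIn run_experiment_rotation Mean index against pre-rotation
#'   angle, one line per condition.
#' @param object A `bw_rotation_experiment`.
#' @export
autoplot.bw_rotation_experiment <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$angle, y = .data$mean_index,
                               colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_index -
                                          .data$sd_index,
                                        ymax = .data$mean_index +
                                          .data$sd_index),
                           width = 0.8) +
    ggplot2::labs(x = "pre-rotation (degrees)",
                  y = "collagen orientation index",
                  colour = "phantom") +
    ggplot2::theme_minimal()
}
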