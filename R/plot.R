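#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a range-of-motion projection
#'
#' @param object A [range_of_motion()] result.
#' @param ... Unused.
#' @return A ggplot raster of the temporal-mean image.
#' @method autoplot range_of_motion_map
#' @export
autoplot.range_of_motion_map <- function(object, ...) {
  d <- dim(object$image)
  df <- tibble::tibble(
    x = rep(0:(d[2] - 1), each = d[1]),
    y = rep(0:(d[1] - 1), times = d[2]),
    intensity = as.vector(object$image)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Range of motion (%.3g s mean)",
                                  object$time_window),
                  x = "x (px)", y = "y (px)", fill = "mean\nintensity")
}

#' Plot a kymograph
#'
#' @param object A [extract_kymograph()] result.
#' @param ... Unused.
#' @return A ggplot raster, path angle vs time.
#' @method autoplot kymograph
#' @export
autoplot.kymograph <- function(object, ...) {
  fps <- attr(object, "fps")
  df <- tidy_kymograph(object)
  df$time_s <- df$frame / fps
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$angle_deg,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = "Tip-path line-scan kymograph",
                  x = "time (s)", y = "path angle (deg)", fill = "intensity")
}

#' Plot an angle trace
#'
#' @param object An `angle_trace`.
#' @param ... Unused.
#' @return A ggplot line plot; low-signal (interpolated) frames are marked.
#' @method autoplot angle_trace
#' @export
autoplot.angle_trace <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$angle_deg)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "tip angle (deg)",
                  title = "Tip-angle trace")
  if (any(df$quality != "ok")) {
    p <- p + ggplot2::geom_point(
      data = df[df$quality != "ok", ],
      color = "firebrick", size = 0.8)
  }
  p
}

#' Plot a power spectrum with the interpolated peak
#'
#' @param object A [dominant_frequency()] result.
#' @param ... Unused.
#' @return A ggplot of spectral power vs frequency.
#' @method autoplot frequency_estimate
#' @export
autoplot.frequency_estimate <- function(object, ...) {
  if (is.null(object$spectrum)) abort_input("estimate carries no spectrum")
  p <- ggplot2::ggplot(object$spectrum,
                       ggplot2::aes(.data$frequency, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "power",
                  title = if (is.na(object$frequency)) "Power spectrum (no peak)"
                          else sprintf("Power spectrum: peak %.3f Hz", object$frequency))
  if (!is.na(object$frequency)) {
    p <- p + ggplot2::geom_vline(xintercept = object$frequency,
                                 linetype = "dashed", color = "firebrick")
  }
  p
}

#' Plot dwell fractions per path bin
#'
#' @param object A [dwell_fractions()] result.
#' @param ... Unused.
#' @return A ggplot bar chart; bin 1 is wall-proximal.
#' @method autoplot dwell_fractions
#' @export
autoplot.dwell_fractions <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(factor(.data$bin), .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "path bin (1 = wall-proximal)", y = "dwell fraction",
                  title = "Dwell time per path bin")
}

#' @importFrom rlang .data
NULL
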