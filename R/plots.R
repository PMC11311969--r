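#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an emission spectrum with its conformer components
#'
#' @param object an [convolve_spectrum()] result
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.emission_spectrum <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              -"wavelength", names_to = "component",
                              values_to = "value")
  long$component <- sub("^conformer_", "Conf-", long$component)
  long$component[long$component == "intensity"] <- "total"
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "intensity (a.u.)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a decay or anisotropy curve
#'
#' Intensity histograms are drawn on a log10 count scale, anisotropy traces
#' on a linear scale.
#'
#' @param object a [new_curve()]
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.decay_curve <- function(object, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$t, .data$y)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)",
                  y = if (curve_kind(object) == "anisotropy") "r(t)" else "counts") +
    ggplot2::theme_minimal()
  if (curve_kind(object) == "intensity") p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a 2-D membrane thickness map
#'
#' @param object a [thickness_map()]
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.thickness_map <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$x, .data$y, fill = .data$thickness)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "blue", high = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", fill = "thickness (nm)") +
    ggplot2::theme_minimal()
}

#' Plot an angular distribution histogram
#'
#' @param object an [angle_distribution()] result
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.angular_distribution <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$bin_mid, .data$count)) +
    ggplot2::geom_col(width = object$bin_hi[1] - object$bin_lo[1]) +
    ggplot2::geom_vline(xintercept = attr(object, "mode_angle"),
                        linetype = "dashed") +
    ggplot2::labs(x = "angle to membrane normal (deg)", y = "frames") +
    ggplot2::theme_minimal()
}

#' Plot a probe/phosphorus depth profile
#'
#' @param object a [depth_profile()]
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.depth_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$z_mid, .data$density,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "|z - membrane centre| (nm)", y = "density (1/nm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot deuterium order parameters per carbon
#'
#' @param profile result of [deuterium_order_parameters()], or several
#'   row-bound with a `tail` column
#' @return a ggplot
#' @export
plot_order_parameters <- function(profile) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(.data$carbon, -.data$scd))
  if ("tail" %in% names(profile)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$tail)) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$tail))
  } else {
    p <- p + ggplot2::geom_line() + ggplot2::geom_point()
  }
  p + ggplot2::labs(x = "carbon (glycerol to terminal methyl)",
                    y = expression(-S[CD])) +
    ggplot2::theme_minimal()
}
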