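#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrum
#'
#' @param object A `spectrum` from [histogram_energies()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spectrum
#' @export
autoplot.spectrum <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$bin_center, y = .data$counts)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = paste0("energy (", attr(object, "unit_label"), ")"),
                  y = "counts") +
    ggplot2::theme_minimal()
}

#' Plot the source-plane slice of an ML-EM image
#'
#' @param object An `mlem_image`.
#' @param z_mm Plane to show (default: central plane).
#' @param ... Unused.
#' @return A ggplot raster of the slice.
#' @method autoplot mlem_image
#' @export
autoplot.mlem_image <- function(object, z_mm = NULL, ...) {
  g <- object$grid
  if (is.null(z_mm)) {
    z_mm <- g$origin_mm[3] + g$voxel_size_mm * (g$dims[3] - 1) / 2
  }
  slice <- extract_plane(object, z_mm)
  ggplot2::ggplot(slice, ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                                      fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  fill = "intensity",
                  title = sprintf("ML-EM image, z = %.1f mm (%d iterations)",
                                  attr(slice, "z_mm"),
                                  object$iteration_count)) +
    ggplot2::theme_minimal()
}

#' Plot an image profile with its Gaussian fit
#'
#' @param object A `profile_fit` from [profile_fwhm()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot profile_fit
#' @export
autoplot.profile_fit <- function(object, ...) {
  dat <- tibble::tibble(pos = object$positions_mm, value = object$values)
  xx <- seq(min(dat$pos), max(dat$pos), length.out = 400)
  fitline <- tibble::tibble(pos = xx, value = object$fit$fitted(xx))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fitline, colour = "red") +
    ggplot2::labs(x = paste0(object$axis, " (mm)"), y = "intensity",
                  title = sprintf("%s profile: FWHM %.2f mm", object$axis,
                                  object$fwhm_mm)) +
    ggplot2::theme_minimal()
}

#' Plot a calibration curve with its fit points
#'
#' @param object A `calibration_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot calibration_curve
#' @export
autoplot.calibration_curve <- function(object, ...) {
  ggplot2::ggplot(object$fit_points,
                  ggplot2::aes(x = .data$adc, y = .data$kev)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "red") +
    ggplot2::labs(x = "photopeak position (ADC)", y = "line energy (keV)") +
    ggplot2::theme_minimal()
}
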