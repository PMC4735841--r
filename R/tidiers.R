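#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a photopeak fit
#'
#' @param x A [fit_photopeak()] object.
#' @param ... Unused.
#' @return One-row tibble with the fitted peak parameters.
#' @method tidy photopeak_fit
#' @export
tidy.photopeak_fit <- function(x, ...) {
  tibble::tibble(centroid = x$centroid, sigma = x$sigma,
                 amplitude = x$amplitude, background = x$background,
                 fwhm_percent = x$fwhm_percent,
                 window_lo = x$fit_window[1], window_hi = x$fit_window[2])
}

#' @rdname tidy.photopeak_fit
#' @method glance photopeak_fit
#' @export
glance.photopeak_fit <- function(x, ...) {
  tibble::tibble(n_counts = x$n_counts,
                 deviance = x$fit$deviance,
                 converged = x$fit$converged)
}

#' Tidy a calibration curve
#'
#' @param x A [build_calibration()] curve.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate` for slope and intercept.
#' @method tidy calibration_curve
#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble::tibble(term = c("intercept_kev", "slope_kev_per_adc"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.calibration_curve
#' @method glance calibration_curve
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_points = nrow(x$fit_points))
}

#' Tidy an image profile fit
#'
#' @param x A [profile_fwhm()] object.
#' @param ... Unused.
#' @return One-row tibble with centroid and FWHM.
#' @method tidy profile_fit
#' @export
tidy.profile_fit <- function(x, ...) {
  tibble::tibble(axis = x$axis, centroid_mm = x$centroid_mm,
                 sigma_mm = x$sigma_mm, fwhm_mm = x$fwhm_mm,
                 under_resolved = x$under_resolved)
}

#' Summaries of an ML-EM image
#'
#' @param x An [mlem_reconstruct()] image.
#' @param ... Unused.
#' @return One-row tibble: iterations, events, final log-likelihood,
#'   maximum-voxel position.
#' @method glance mlem_image
#' @export
glance.mlem_image <- function(x, ...) {
  idx <- which(x$values == max(x$values), arr.ind = TRUE)[1, ]
  g <- x$grid
  tibble::tibble(
    iteration_count = x$iteration_count,
    n_events = x$n_events,
    loglik = if (is.null(x$loglik)) NA_real_ else
      x$loglik[length(x$loglik)],
    max_x_mm = g$origin_mm[1] + (idx[1] - 1) * g$voxel_size_mm,
    max_y_mm = g$origin_mm[2] + (idx[2] - 1) * g$voxel_size_mm,
    max_z_mm = g$origin_mm[3] + (idx[3] - 1) * g$voxel_size_mm)
}
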