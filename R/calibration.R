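#' Histogram energies (or ADC values) into a spectrum
#'
#' Fixed-width histogram; values outside `range` are dropped (their count is
#' recorded in the `n_dropped` attribute and reported via a message).
#'
#' @param values Numeric vector.
#' @param bin_width Bin width (> 0), same unit as `values`.
#' @param range Length-2 numeric, histogram range; the upper edge is pushed
#'   up to a whole number of bins.
#' @param unit_label Unit of the binned axis ("keV" or "ADC").
#' @return A tibble of class `spectrum` with columns `bin_center`, `counts`;
#'   attributes `bin_edges`, `bin_width`, `unit_label`, `n_dropped`.
#' @export
histogram_energies <- function(values, bin_width, range = NULL,
                               unit_label = "keV") {
  stopifnot(bin_width > 0)
  if (is.null(range)) {
    range <- if (length(values) == 0) c(0, bin_width) else
      c(floor(min(values) / bin_width) * bin_width, max(values))
  }
  n_bins <- max(1L, ceiling((range[2] - range[1]) / bin_width - 1e-12))
  edges <- range[1] + bin_width * (0:n_bins)
  inside <- values >= edges[1] & values <= edges[n_bins + 1]
  n_dropped <- sum(!inside)
  if (n_dropped > 0) {
    message(n_dropped, " value(s) outside histogram range dropped")
  }
  idx <- pmin(pmax(floor((values[inside] - edges[1]) / bin_width) + 1, 1),
              n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(tibble::tibble(bin_center = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                           counts = as.integer(counts)),
            class = c("spectrum", class(tibble::tibble())),
            bin_edges = edges, bin_width = bin_width,
            unit_label = unit_label, n_dropped = n_dropped)
}

#' Write / read a spectrum as two-column delimited text
#'
#' @param spectrum A [histogram_energies()] spectrum.
#' @param path File path.
#' @export
write_spectrum <- function(spectrum, path) {
  readr::write_csv(tibble::as_tibble(spectrum), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @param unit_label Unit label to attach on read.
#' @export
read_spectrum <- function(path, unit_label = "keV") {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  bw <- diff(tab$bin_center[1:2])
  structure(tab, class = c("spectrum", class(tibble::tibble())),
            bin_edges = c(tab$bin_center - bw / 2,
                          tab$bin_center[nrow(tab)] + bw / 2),
            bin_width = bw, unit_label = unit_label, n_dropped = 0)
}

#' Fit a Gaussian photopeak (plus constant background) in a window
#'
#' Least-squares fit of `A exp(-(x - mu)^2 / (2 sigma^2)) + b` to the
#' spectrum counts inside `window`, via Levenberg-Marquardt. The reported
#' `fwhm_percent` is `100 * 2.3548 * sigma / centroid`.
#'
#' @param spectrum A `spectrum`.
#' @param window Length-2 numeric `(lo, hi)` in spectrum units; must contain
#'   at least 5 bins with nonzero counts.
#' @return Object of class `photopeak_fit`: fields `centroid`, `sigma`,
#'   `amplitude`, `background`, `fwhm_percent`, `fit_window`, `n_counts`,
#'   `fit` (the nls object).
#' @export
fit_photopeak <- function(spectrum, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  sel <- spectrum$bin_center >= window[1] & spectrum$bin_center <= window[2]
  x <- spectrum$bin_center[sel]
  y <- as.numeric(spectrum$counts[sel])
  if (sum(y > 0) < 5) {
    stop("photopeak window must contain at least 5 non-empty bins",
         call. = FALSE)
  }
  b0 <- min(y)
  a0 <- max(y) - b0
  if (a0 <= 0) stop("no peak above background in window", call. = FALSE)
  mu0 <- x[which.max(y)]
  s0 <- max(diff(window) / 6, diff(x[1:2]))
  fit <- gauss_const_fit(x, y, c(a = a0, m = mu0, s = s0, b = b0),
                         lower = c(0, window[1], 1e-6, 0),
                         upper = c(Inf, window[2], diff(window), Inf))
  if (!fit$converged) {
    stop("photopeak fit failed to converge: ", fit$message, call. = FALSE)
  }
  cf <- fit$coefficients
  structure(list(centroid = unname(cf["m"]), sigma = unname(cf["s"]),
                 amplitude = unname(cf["a"]), background = unname(cf["b"]),
                 fwhm_percent = 100 * 2 * sqrt(2 * log(2)) *
                   unname(cf["s"]) / unname(cf["m"]),
                 fit_window = window, n_counts = sum(y), fit = fit),
            class = "photopeak_fit")
}

# Gaussian + constant least squares via Levenberg-Marquardt (nls.lm), with
# box constraints; robust to exact-fit synthetic data
gauss_const_fit <- function(x, y, start, lower, upper) {
  resid_fn <- function(p) {
    y - (p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) + p[4])
  }
  res <- minpack.lm::nls.lm(par = unname(start), fn = resid_fn,
                            lower = unname(lower), upper = unname(upper),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500))
  cf <- res$par
  names(cf) <- names(start)
  list(coefficients = cf, deviance = res$deviance,
       converged = res$info %in% 1:4, message = res$message,
       fitted = function(xx) cf[1] * exp(-(xx - cf[2])^2 /
                                           (2 * cf[3]^2)) + cf[4])
}

#' @export
print.photopeak_fit <- function(x, ...) {
  cat(sprintf(
    "<photopeak_fit> centroid %.2f, sigma %.3f (FWHM %.2f%%), window [%g, %g]\n",
    x$centroid, x$sigma, x$fwhm_percent, x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

#' Build a linear energy calibration from photopeak positions
#'
#' Ordinary least-squares line `keV = slope * ADC + intercept` through the
#' fitted peak positions of sources with known line energies.
#'
#' @param fit_points Data frame with columns `adc` (fitted centroid, ADC
#'   counts) and `kev` (known line energy); at least 2 distinct ADC values.
#' @return Object of class `calibration_curve`: `slope` (keV/ADC, > 0),
#'   `intercept` (keV), `r_squared`, `fit_points`, `fit` (the lm object).
#' @export
build_calibration <- function(fit_points) {
  fit_points <- tibble::as_tibble(fit_points)
  stopifnot(all(c("adc", "kev") %in% names(fit_points)))
  if (nrow(fit_points) < 2 || length(unique(fit_points$adc)) < 2) {
    stop("need at least 2 distinct ADC fit points", call. = FALSE)
  }
  fit <- stats::lm(kev ~ adc, data = fit_points)
  r2 <- if (nrow(fit_points) == 2) 1 else summary(fit)$r.squared
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, fit_points = fit_points, fit = fit),
            class = "calibration_curve")
}

#' Apply or invert a calibration curve
#'
#' @param curve A [build_calibration()] curve.
#' @param adc ADC values to convert to keV.
#' @return Energies in keV.
#' @export
apply_calibration <- function(curve, adc) {
  curve$slope * adc + curve$intercept
}

#' @rdname apply_calibration
#' @param kev Energies in keV to convert back to ADC.
#' @export
invert_calibration <- function(curve, kev) {
  (kev - curve$intercept) / curve$slope
}

#' Linear gain-temperature model
#'
#' Gain factor `1 + slope * (T - T_ref)` relative to the reference
#' temperature, with the measured slope of about -5 %/degC as default.
#' Valid over a documented window (default 10-40 degC) inside which the
#' factor stays positive.
#'
#' @param reference_temp_c Reference temperature in degC.
#' @param slope_per_degc Fractional gain change per degC.
#' @param valid_range_c Supported temperature window.
#' @return Object of class `temperature_model`.
#' @export
temperature_model <- function(reference_temp_c = 25.5,
                              slope_per_degc = -0.05,
                              valid_range_c = c(10, 40)) {
  m <- structure(list(reference_temp_c = reference_temp_c,
                      slope_per_degc = slope_per_degc,
                      valid_range_c = valid_range_c),
                 class = "temperature_model")
  if (gain_factor(m, valid_range_c[1]) <= 0 ||
      gain_factor(m, valid_range_c[2]) <= 0) {
    stop("gain factor not positive over the validity window", call. = FALSE)
  }
  m
}

#' Gain factor at a temperature
#'
#' @param model A [temperature_model()].
#' @param temperature_c Temperature in degC, inside the validity window.
#' @return Dimensionless gain factor (1 at the reference temperature).
#' @export
gain_factor <- function(model, temperature_c) {
  if (any(temperature_c < model$valid_range_c[1] |
          temperature_c > model$valid_range_c[2])) {
    stop("temperature outside model validity window", call. = FALSE)
  }
  1 + model$slope_per_degc * (temperature_c - model$reference_temp_c)
}

#' Fit the gain-temperature slope from measured gains
#'
#' Least-squares line through (temperature, gain), normalized by the fitted
#' gain at the reference temperature, so the result is a fractional slope
#' per degC directly comparable to the model slope.
#'
#' @param gains Data frame with columns `temperature_c` and `gain`; at least
#'   3 distinct temperatures.
#' @param reference_temp_c Normalization temperature.
#' @return List with `slope_per_degc`, `slope_se`, `gain_at_reference`,
#'   `fit` (lm object).
#' @export
fit_temperature_slope <- function(gains, reference_temp_c = 25.5) {
  gains <- tibble::as_tibble(gains)
  stopifnot(all(c("temperature_c", "gain") %in% names(gains)))
  if (length(unique(gains$temperature_c)) < 3) {
    stop("need at least 3 distinct temperatures", call. = FALSE)
  }
  fit <- stats::lm(gain ~ temperature_c, data = gains)
  g_ref <- unname(stats::predict(fit, tibble::tibble(
    temperature_c = reference_temp_c)))
  sl <- unname(stats::coef(fit)[2]) / g_ref
  se <- summary(fit)$coefficients[2, 2] / abs(g_ref)
  list(slope_per_degc = sl, slope_se = se, gain_at_reference = g_ref,
       fit = fit)
}

#' Software channel equalization factors
#'
#' Multiplicative correction factors `f_ch = grand_mean / mean_ch` that make
#' every channel's corrected mean signal equal to the grand mean (the
#' software analogue of the per-channel bias-DAC adjustment). Channel means
#' should be estimated from more than 10 000 events.
#'
#' @param mean_signals 8 x 8 numeric matrix of per-channel mean signals
#'   (all > 0).
#' @return 8 x 8 matrix of correction factors.
#' @export
equalize_channels <- function(mean_signals) {
  stopifnot(is.matrix(mean_signals))
  dead <- which(!(mean_signals > 0))
  if (length(dead) > 0) {
    stop("dead channel(s) (non-positive mean signal) at index: ",
         paste(dead, collapse = ", "), call. = FALSE)
  }
  mean(mean_signals) / mean_signals
}
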