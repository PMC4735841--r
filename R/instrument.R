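#' Specification of one LaBr3 detector layer
#'
#' Coordinates are millimetres in the telescope frame: origin at the centre
#' of the layer-1 entrance face, +z from the source towards layer 3 (the
#' source sits on the -z side).
#'
#' @param index Layer index 1..3.
#' @param size_x_mm,size_y_mm Transverse crystal size in mm.
#' @param thickness_mm Crystal thickness along z in mm.
#' @param z_entry_mm z of the entrance face in the telescope frame.
#' @param energy_resolution_511 FWHM/E at 511 keV (fraction, e.g. 0.064).
#' @param position_fwhm_mm Transverse position resolution, FWHM in mm.
#' @param threshold_kev Trigger threshold on measured energy, keV.
#' @return An object of class `layer_spec`.
#' @export
layer_spec <- function(index, size_x_mm, size_y_mm, thickness_mm, z_entry_mm,
                       energy_resolution_511, position_fwhm_mm = 1.0,
                       threshold_kev = 50) {
  stopifnot(thickness_mm > 0, size_x_mm > 0, size_y_mm > 0,
            energy_resolution_511 > 0, energy_resolution_511 < 1,
            threshold_kev >= 0)
  structure(list(index = index, size_x_mm = size_x_mm, size_y_mm = size_y_mm,
                 thickness_mm = thickness_mm, z_entry_mm = z_entry_mm,
                 energy_resolution_511 = energy_resolution_511,
                 position_fwhm_mm = position_fwhm_mm,
                 threshold_kev = threshold_kev),
            class = "layer_spec")
}

#' Assemble a telescope geometry from layer gaps
#'
#' @param layers List of three [layer_spec()] objects ordered by increasing
#'   `z_entry_mm`.
#' @param source_to_layer1_mm Distance from the source plane to the layer-1
#'   entrance face, mm.
#' @param coincidence_window_ns Width of the triple-coincidence window, ns.
#' @param spacing_mode How the configured inter-layer distances were
#'   interpreted when the layer z positions were computed ("face" =
#'   exit-face to entrance-face gaps, "center" = centre-to-centre);
#'   informational, carried for config round-trips.
#' @return An object of class `telescope_geometry`.
#' @export
telescope_geometry <- function(layers, source_to_layer1_mm = 35,
                               coincidence_window_ns = 25,
                               spacing_mode = "face") {
  z <- vapply(layers, function(l) l$z_entry_mm, numeric(1))
  if (any(diff(z) <= 0)) {
    stop("layers must have strictly increasing z_entry_mm", call. = FALSE)
  }
  structure(list(layers = layers,
                 source_to_layer1_mm = source_to_layer1_mm,
                 coincidence_window_ns = coincidence_window_ns,
                 spacing_mode = spacing_mode),
            class = "telescope_geometry")
}

#' The default three-layer prototype geometry
#'
#' Layer 1: 27.2 x 26.8 x 5 mm, 6.4% FWHM at 511 keV. Layer 2: 32 x 36 x
#' 5 mm, 7.4%. Layer 3: 32 x 36 x 10 mm, 7.2%. Position blur 1 mm FWHM and
#' 50 keV threshold on all layers; source 35 mm from layer 1; inter-layer
#' distances 60 and 65 mm; 25 ns coincidence window.
#'
#' @param spacing_mode `"face"` (default): the 60/65 mm distances are gaps
#'   between adjacent crystal faces; `"center"`: centre-to-centre distances.
#' @return A [telescope_geometry()].
#' @export
default_prototype <- function(spacing_mode = c("face", "center")) {
  spacing_mode <- match.arg(spacing_mode)
  t1 <- 5; t2 <- 5; t3 <- 10
  d12 <- 60; d23 <- 65
  if (spacing_mode == "face") {
    z1 <- 0
    z2 <- z1 + t1 + d12
    z3 <- z2 + t2 + d23
  } else {
    z1 <- 0
    c1 <- t1 / 2
    c2 <- c1 + d12
    c3 <- c2 + d23
    z2 <- c2 - t2 / 2
    z3 <- c3 - t3 / 2
  }
  telescope_geometry(
    layers = list(
      layer_spec(1, 27.2, 26.8, t1, z1, 0.064),
      layer_spec(2, 32.0, 36.0, t2, z2, 0.074),
      layer_spec(3, 32.0, 36.0, t3, z3, 0.072)
    ),
    source_to_layer1_mm = 35,
    coincidence_window_ns = 25,
    spacing_mode = spacing_mode
  )
}

#' @export
print.telescope_geometry <- function(x, ...) {
  cat("<telescope_geometry> (", x$spacing_mode, " spacing)\n", sep = "")
  for (l in x$layers) {
    cat(sprintf(
      "  layer %d: %.1f x %.1f x %.1f mm at z = %.1f mm, %.1f%% FWHM @511, %.0f keV threshold\n",
      l$index, l$size_x_mm, l$size_y_mm, l$thickness_mm, l$z_entry_mm,
      100 * l$energy_resolution_511, l$threshold_kev))
  }
  cat(sprintf("  source at z = %.1f mm; coincidence window %.0f ns\n",
              -x$source_to_layer1_mm, x$coincidence_window_ns))
  invisible(x)
}

#' Distance of a layer entrance face from the source
#'
#' @param geometry A [telescope_geometry()].
#' @param index Layer index.
#' @return Distance in mm along the optical axis.
#' @export
z_front_from_source <- function(geometry, index) {
  geometry$layers[[index]]$z_entry_mm + geometry$source_to_layer1_mm
}

#' Mid-plane z of a layer (the reported interaction depth)
#' @inheritParams z_front_from_source
#' @return z in mm, telescope frame.
#' @export
layer_midplane <- function(geometry, index) {
  l <- geometry$layers[[index]]
  l$z_entry_mm + l$thickness_mm / 2
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Energy resolution model of a layer
#'
#' FWHM(E) = `energy_resolution_511` * 511 * sqrt(E / 511) keV: the relative
#' resolution scales as 1/sqrt(E) (photostatistics), anchored at the measured
#' 511 keV value.
#'
#' @param layer A [layer_spec()].
#' @param e_kev Energy in keV.
#' @return FWHM in keV (0 at 0 keV).
#' @export
energy_fwhm_kev <- function(layer, e_kev) {
  layer$energy_resolution_511 * 511 * sqrt(pmax(e_kev, 0) / 511)
}

#' Apply the Gaussian energy response of a layer
#'
#' Draws from a Gaussian centred on the true energy with the layer's
#' energy-dependent FWHM; negative draws are clamped to 0. Uses the global
#' RNG stream.
#'
#' @param layer A [layer_spec()].
#' @param e_true True deposited energies in keV (>= 0). Vectorized.
#' @return Measured energies in keV.
#' @export
apply_energy_response <- function(layer, e_true) {
  if (any(e_true < 0)) stop("e_true must be >= 0", call. = FALSE)
  sigma <- fwhm_to_sigma(energy_fwhm_kev(layer, e_true))
  pmax(e_true + stats::rnorm(length(e_true), 0, 1) * sigma, 0)
}

#' Apply the position response of a layer
#'
#' Transverse (x, y) coordinates are blurred with a Gaussian of FWHM
#' `position_fwhm_mm` and clamped to the crystal bounds; the reported z is
#' the layer mid-plane (no depth-of-interaction information).
#'
#' @param layer A [layer_spec()].
#' @param xyz Numeric matrix (n x 3) of true positions in mm, inside the
#'   layer volume.
#' @return Matrix (n x 3) of measured positions.
#' @export
apply_position_response <- function(layer, xyz) {
  xyz <- rbind(xyz)
  hx <- layer$size_x_mm / 2
  hy <- layer$size_y_mm / 2
  inside <- abs(xyz[, 1]) <= hx + 1e-9 & abs(xyz[, 2]) <= hy + 1e-9 &
    xyz[, 3] >= layer$z_entry_mm - 1e-9 &
    xyz[, 3] <= layer$z_entry_mm + layer$thickness_mm + 1e-9
  if (!all(inside)) stop("position outside layer volume", call. = FALSE)
  if (isTRUE(layer$ideal)) return(xyz) # blur-free oracle mode: exact readout
  s <- fwhm_to_sigma(layer$position_fwhm_mm)
  n <- nrow(xyz)
  cbind(
    pmin(pmax(xyz[, 1] + stats::rnorm(n, 0, s), -hx), hx),
    pmin(pmax(xyz[, 2] + stats::rnorm(n, 0, s), -hy), hy),
    rep(layer$z_entry_mm + layer$thickness_mm / 2, n)
  )
}

#' Does a measured energy pass the layer trigger threshold?
#'
#' Inclusive at the boundary: `e_measured >= threshold_kev`.
#'
#' @param layer A [layer_spec()].
#' @param e_measured Measured energy in keV.
#' @return Logical vector.
#' @export
passes_threshold <- function(layer, e_measured) {
  e_measured >= layer$threshold_kev
}

#' Per-channel gain map of an 8 x 8 SiPM readout
#'
#' @param gains 8 x 8 numeric matrix of multiplicative gains (> 0),
#'   nominal 1.0.
#' @param layer_index Which layer the map belongs to.
#' @return Object of class `channel_gain_map`.
#' @export
channel_gain_map <- function(gains = matrix(1, 8, 8), layer_index = 1) {
  stopifnot(is.matrix(gains), all(dim(gains) == c(8, 8)), all(gains > 0))
  structure(list(layer_index = layer_index, gains = gains),
            class = "channel_gain_map")
}

#' Uniformity metric of a channel response grid
#'
#' Standard deviation over mean of the per-channel values (the figure the
#' equalization procedure drives towards zero).
#'
#' @param x A `channel_gain_map` or a numeric matrix/vector of channel means.
#' @return Scalar stdev/mean.
#' @export
uniformity <- function(x) {
  v <- as.numeric(if (inherits(x, "channel_gain_map")) x$gains else x)
  stats::sd(v) / mean(v)
}
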