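#' Reshape list-mode events (3 rows per event) into one-row triples
#'
#' @param events Long list-mode tibble with columns `event_id`, `layer`,
#'   `x_mm,y_mm,z_mm`, `e_kev` (from [run_experiment()] or
#'   [read_listmode()]).
#' @return Wide tibble with one row per event: `event_id`, `e1,e2,e3`,
#'   `x1..z3`, `total_kev`.
#' @export
triples_from_events <- function(events) {
  if (nrow(events) == 0) {
    return(tibble::tibble(event_id = integer(), e1 = numeric(),
                          e2 = numeric(), e3 = numeric(),
                          x1 = numeric(), y1 = numeric(), z1 = numeric(),
                          x2 = numeric(), y2 = numeric(), z2 = numeric(),
                          x3 = numeric(), y3 = numeric(), z3 = numeric(),
                          total_kev = numeric()))
  }
  wide <- events |>
    dplyr::select(dplyr::all_of(c("event_id", "layer", "x_mm", "y_mm",
                                  "z_mm", "e_kev"))) |>
    tidyr::pivot_wider(names_from = "layer",
                       values_from = c("x_mm", "y_mm", "z_mm", "e_kev"),
                       names_glue = "{.value}_{layer}")
  need <- as.vector(outer(c("x_mm", "y_mm", "z_mm", "e_kev"), 1:3,
                          paste, sep = "_"))
  missing <- setdiff(need, names(wide))
  if (length(missing) > 0) {
    stop("events are not complete triples; missing layer columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    event_id = wide$event_id,
    e1 = wide$e_kev_1, e2 = wide$e_kev_2, e3 = wide$e_kev_3,
    x1 = wide$x_mm_1, y1 = wide$y_mm_1, z1 = wide$z_mm_1,
    x2 = wide$x_mm_2, y2 = wide$y_mm_2, z2 = wide$z_mm_2,
    x3 = wide$x_mm_3, y3 = wide$y_mm_3, z3 = wide$z_mm_3,
    total_kev = wide$e_kev_1 + wide$e_kev_2 + wide$e_kev_3)
}

#' Select triples by total (sum) energy
#'
#' Keeps events whose summed deposit lies inside the window (inclusive),
#' preserving order. The default 800-1400 keV window brackets the 1275 keV
#' full-energy peak and excludes the 511 keV one.
#'
#' @param triples Tibble from [triples_from_events()].
#' @param sum_window Length-2 numeric `(lo, hi)` in keV.
#' @return Filtered tibble; the pass fraction is reported via a message and
#'   stored in the `pass_fraction` attribute.
#' @export
select_events <- function(triples, sum_window = c(800, 1400)) {
  stopifnot(sum_window[1] < sum_window[2])
  keep <- triples$total_kev >= sum_window[1] &
    triples$total_kev <= sum_window[2]
  out <- triples[keep, ]
  frac <- if (nrow(triples) > 0) mean(keep) else NA_real_
  message(sprintf("sum-energy cut [%g, %g] keV kept %d / %d events",
                  sum_window[1], sum_window[2], nrow(out), nrow(triples)))
  attr(out, "pass_fraction") <- frac
  out
}

#' Cosine of the measured second-scatter angle
#'
#' Angle between the segments r1 -> r2 and r2 -> r3, clipped to \[-1, 1\].
#'
#' @param r1,r2,r3 Interaction positions: numeric length-3 vectors or
#'   n x 3 matrices.
#' @return Cosine(s) of the inter-segment angle.
#' @export
geometric_cos_angle <- function(r1, r2, r3) {
  r1 <- rbind(r1); r2 <- rbind(r2); r3 <- rbind(r3)
  a <- r2 - r1
  b <- r3 - r2
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  if (any(na == 0 | nb == 0)) {
    stop("degenerate geometry: coincident interaction points",
         call. = FALSE)
  }
  as.numeric(pmin(pmax(rowSums(a * b) / (na * nb), -1), 1))
}

#' Incident photon energy from a three-interaction event
#'
#' Three-Compton estimator: with deposits `e1` in the first and `e2` in the
#' second layer, and the geometrically measured second-scatter angle, the
#' photon energy after the first scatter is
#' \eqn{E_1 = e_2/2 + \sqrt{e_2^2/4 + e_2 m_e c^2 / (1 - \cos\theta_2)}}
#' and the incident energy is `E0 = e1 + E1`. The third deposit is not
#' needed (the estimator is robust to incomplete absorption in layer 3).
#'
#' @param e1,e2 Deposited energies (keV, > 0) in layers 1 and 2.
#' @param cos_theta2 Cosine of the second-scatter angle
#'   ([geometric_cos_angle()]); values above `1 - eps` are degenerate
#'   (straight-through geometry).
#' @param on_invalid `"error"` or `"na"` for degenerate elements.
#' @param eps Degeneracy guard on `1 - cos_theta2` (default 1e-9).
#' @return Incident energy estimate in keV (always > e1 + e2).
#' @export
incident_energy_from_triple <- function(e1, e2, cos_theta2,
                                        on_invalid = c("error", "na"),
                                        eps = 1e-9) {
  on_invalid <- match.arg(on_invalid)
  if (any(e1 <= 0) || any(e2 <= 0)) {
    stop("deposited energies must be > 0", call. = FALSE)
  }
  bad <- cos_theta2 >= 1 - eps
  if (any(bad) && on_invalid == "error") {
    stop("degenerate kinematics: cos_theta2 too close to 1", call. = FALSE)
  }
  ct <- ifelse(bad, NA_real_, cos_theta2)
  e1 + e2 / 2 + sqrt(e2^2 / 4 + e2 * electron_rest_kev / (1 - ct))
}

# first-order (delta-method) sigma of the half-angle for one set of triples;
# numerical partial derivatives
half_angle_of <- function(e1, e2, ct2) {
  e0 <- e1 + e2 / 2 + sqrt(e2^2 / 4 + e2 * electron_rest_kev / (1 - ct2))
  c1 <- 1 - electron_rest_kev * (1 / (e0 - e1) - 1 / e0)
  acos(pmin(pmax(c1, -1), 1))
}

#' Build Compton cones from triple events
#'
#' For each triple: apex at the layer-1 interaction; axis the unit vector
#' from the layer-2 towards the layer-1 interaction (pointing back at the
#' source); opening half-angle from the first-scatter Compton relation with
#' the three-interaction incident-energy estimate. The per-event angular
#' uncertainty `sigma_rad` combines, in quadrature and to first order:
#' energy blur on e1 and e2 (layer FWHM model), position blur (transverse
#' FWHM plus thickness/sqrt(12) in depth) propagated through the
#' second-scatter angle, and the axis direction uncertainty from the blur of
#' the two apex-defining positions. Events that are kinematically
#' inconsistent after blurring (|cos theta1| > 1, degenerate geometry, or
#' cos theta2 ~ 1) are dropped; counts by reason are reported in the
#' `rejections` attribute.
#'
#' @param triples Tibble from [triples_from_events()].
#' @param geometry The [telescope_geometry()] (for the response model used
#'   in uncertainty propagation).
#' @return Tibble of class `cone_set`: `event_id`, `apex_x/y/z_mm`,
#'   `axis_x/y/z`, `half_angle_rad`, `sigma_rad`, `e0_kev`.
#' @export
cone_from_triples <- function(triples, geometry) {
  n <- nrow(triples)
  r1 <- cbind(triples$x1, triples$y1, triples$z1)
  r2 <- cbind(triples$x2, triples$y2, triples$z2)
  r3 <- cbind(triples$x3, triples$y3, triples$z3)
  sep12 <- sqrt(rowSums((r1 - r2)^2))
  sep23 <- sqrt(rowSums((r3 - r2)^2))
  degen <- sep12 == 0 | sep23 == 0
  ct2 <- rep(NA_real_, n)
  ct2[!degen] <- geometric_cos_angle(r1[!degen, , drop = FALSE],
                                     r2[!degen, , drop = FALSE],
                                     r3[!degen, , drop = FALSE])
  straight <- !degen & ct2 >= 1 - 1e-9
  ok <- !degen & !straight
  e0 <- rep(NA_real_, n)
  e0[ok] <- incident_energy_from_triple(triples$e1[ok], triples$e2[ok],
                                        ct2[ok], on_invalid = "na")
  ct1 <- 1 - electron_rest_kev * (1 / (e0 - triples$e1) - 1 / e0)
  inconsistent <- ok & (ct1 < -1 | ct1 > 1)
  ok <- ok & !inconsistent
  half <- acos(pmin(pmax(ct1, -1), 1))
  flat <- ok & (half <= 0 | half >= pi)
  ok <- ok & !flat

  # --- first-order uncertainty propagation ---
  e1 <- triples$e1; e2 <- triples$e2
  s_e1 <- fwhm_to_sigma(energy_fwhm_kev(geometry$layers[[1]], e1))
  s_e2 <- fwhm_to_sigma(energy_fwhm_kev(geometry$layers[[2]], e2))
  d <- 1e-3
  dth_de1 <- (half_angle_of(e1 + d, e2, ct2) -
                half_angle_of(e1 - d, e2, ct2)) / (2 * d)
  dth_de2 <- (half_angle_of(e1, e2 + d, ct2) -
                half_angle_of(e1, e2 - d, ct2)) / (2 * d)
  dc <- 1e-5
  ct2m <- pmin(ct2 + dc, 1 - 1e-9)
  dth_dct2 <- (half_angle_of(e1, e2, ct2m) -
                 half_angle_of(e1, e2, ct2 - dc)) / (ct2m - ct2 + dc)
  # position-blur variance of cos(theta2): numerical partials wrt the 9
  # coordinates, transverse sigma from the layer FWHM model, depth sigma
  # thickness/sqrt(12) (mid-plane convention carries no depth information)
  s_t <- vapply(geometry$layers,
                function(l) fwhm_to_sigma(l$position_fwhm_mm), numeric(1))
  s_z <- vapply(geometry$layers,
                function(l) l$thickness_mm / sqrt(12), numeric(1))
  var_ct2 <- rep(0, n)
  dp <- 1e-3
  pts <- list(r1, r2, r3)
  for (k in 1:3) {
    for (ax in 1:3) {
      pp <- pts; pm <- pts
      pp[[k]][, ax] <- pp[[k]][, ax] + dp
      pm[[k]][, ax] <- pm[[k]][, ax] - dp
      up <- suppressWarnings((geometric_cos_angle(pp[[1]], pp[[2]], pp[[3]]) -
                                geometric_cos_angle(pm[[1]], pm[[2]],
                                                    pm[[3]])) / (2 * dp))
      s_ax <- if (ax == 3) s_z[k] else s_t[k]
      var_ct2 <- var_ct2 + (up * s_ax)^2
    }
  }
  # axis direction uncertainty from the blur of r1 and r2
  var_axis <- (2 * s_t[1]^2 + 2 * s_t[2]^2 +
                 s_z[1]^2 + s_z[2]^2) / (3 * pmax(sep12, 1e-6)^2)
  sigma <- sqrt((dth_de1 * s_e1)^2 + (dth_de2 * s_e2)^2 +
                  dth_dct2^2 * var_ct2 + var_axis)

  axis <- (r1 - r2) / sep12
  out <- tibble::tibble(
    event_id = triples$event_id[ok],
    apex_x_mm = r1[ok, 1], apex_y_mm = r1[ok, 2], apex_z_mm = r1[ok, 3],
    axis_x = axis[ok, 1], axis_y = axis[ok, 2], axis_z = axis[ok, 3],
    half_angle_rad = half[ok], sigma_rad = sigma[ok], e0_kev = e0[ok])
  attr(out, "rejections") <- c(degenerate = sum(degen),
                               straight_through = sum(straight),
                               kinematically_inconsistent =
                                 sum(inconsistent),
                               flat_cone = sum(flat))
  class(out) <- c("cone_set", class(tibble::tibble()))
  out
}

#' Read and write cone files
#'
#' CSV with one row per cone, the on-disk interchange format between the
#' event processor and the reconstructor.
#'
#' @param cones A `cone_set` tibble.
#' @param path File path.
#' @export
write_cones <- function(cones, path) {
  readr::write_csv(tibble::as_tibble(cones), path)
  invisible(path)
}

#' @rdname write_cones
#' @export
read_cones <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  class(out) <- c("cone_set", class(tibble::tibble()))
  out
}

#' Read a list-mode event file
#'
#' @param path CSV written by [run_experiment()] (columns `event_id`,
#'   `layer`, `x_mm`, `y_mm`, `z_mm`, `e_kev`, `t_ns`).
#' @return Long list-mode tibble.
#' @export
read_listmode <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
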