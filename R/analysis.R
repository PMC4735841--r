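#' Coincidence sum spectrum of triple events
#'
#' Histogram of the per-event total deposited energy (sum of the three
#' layers).
#'
#' @param triples Tibble from [triples_from_events()].
#' @param bin_width_kev Bin width in keV.
#' @param range_kev Histogram range.
#' @return A `spectrum` (see [histogram_energies()]).
#' @export
sum_spectrum <- function(triples, bin_width_kev = 10,
                         range_kev = c(0, 2100)) {
  histogram_energies(triples$total_kev, bin_width_kev, range_kev,
                     unit_label = "keV")
}

#' Locate and fit the expected photopeaks of a spectrum
#'
#' Runs [fit_photopeak()] in a window of half-width `search_half_width`
#' around each expected line; a line whose window holds fewer than
#' `min_counts` counts is reported absent rather than fitted.
#'
#' @param spectrum A `spectrum`.
#' @param expected_kev Expected line energies (keV); windows must not
#'   overlap.
#' @param search_half_width_kev Window half-width per line (recycled across
#'   lines); a sensible choice is about 3 expected peak sigma.
#' @param min_counts Minimum window counts for a fit attempt.
#' @return Tibble with one row per expected line: `expected_kev`, `present`,
#'   `centroid`, `sigma`, `fwhm_percent`, `n_counts`.
#' @export
find_photopeaks <- function(spectrum, expected_kev,
                            search_half_width_kev = 150, min_counts = 50) {
  o <- order(expected_kev)
  expected_kev <- expected_kev[o]
  hw <- rep_len(search_half_width_kev, length(expected_kev))[o]
  if (length(expected_kev) > 1 &&
      any(diff(expected_kev) < hw[-length(hw)] + hw[-1])) {
    stop("photopeak search windows overlap", call. = FALSE)
  }
  rows <- lapply(seq_along(expected_kev), function(k) {
    e0 <- expected_kev[k]
    win <- c(e0 - hw[k], e0 + hw[k])
    sel <- spectrum$bin_center >= win[1] & spectrum$bin_center <= win[2]
    nc <- sum(spectrum$counts[sel])
    if (nc < min_counts) {
      return(tibble::tibble(expected_kev = e0, present = FALSE,
                            centroid = NA_real_, sigma = NA_real_,
                            fwhm_percent = NA_real_, n_counts = nc))
    }
    fit <- tryCatch(fit_photopeak(spectrum, win), error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(expected_kev = e0, present = FALSE,
                            centroid = NA_real_, sigma = NA_real_,
                            fwhm_percent = NA_real_, n_counts = nc))
    }
    tibble::tibble(expected_kev = e0, present = TRUE,
                   centroid = fit$centroid, sigma = fit$sigma,
                   fwhm_percent = fit$fwhm_percent, n_counts = nc)
  })
  dplyr::bind_rows(rows)
}

#' Gaussian-fit FWHM of an image profile through the maximum
#'
#' Extracts the 1D row (`axis = "x"`) or column (`axis = "y"`) of an image
#' slice through its maximum voxel (ties broken towards the grid centre)
#' and fits Gaussian + constant; the FWHM is reported in mm. A fitted FWHM
#' below one voxel pitch is flagged under-resolved.
#'
#' @param slice A slice tibble from [extract_plane()] (or an `mlem_image`,
#'   in which case its central plane is used).
#' @param axis `"x"` or `"y"`.
#' @return Object of class `profile_fit`: `axis`, `positions_mm`, `values`,
#'   `centroid_mm`, `fwhm_mm`, `sigma_mm`, `under_resolved`, `fit_window`.
#' @export
profile_fwhm <- function(slice, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (inherits(slice, "mlem_image")) {
    g <- slice$grid
    zmid <- g$origin_mm[3] + g$voxel_size_mm * (g$dims[3] - 1) / 2
    slice <- extract_plane(slice, zmid)
  }
  m <- attr(slice, "matrix")
  gx <- attr(slice, "x_mm"); gy <- attr(slice, "y_mm")
  pitch <- if (length(gx) > 1) diff(gx[1:2]) else diff(gy[1:2])
  # maximum voxel; break ties towards the grid centre
  mx <- max(m)
  cand <- which(m == mx, arr.ind = TRUE)
  if (nrow(cand) > 1) {
    ctr <- (dim(m) + 1) / 2
    d2 <- (cand[, 1] - ctr[1])^2 + (cand[, 2] - ctr[2])^2
    cand <- cand[which.min(d2), , drop = FALSE]
  }
  if (axis == "x") {
    pos <- gx; val <- m[, cand[1, 2]]
  } else {
    pos <- gy; val <- m[cand[1, 1], ]
  }
  b0 <- min(val); a0 <- max(val) - b0
  s0 <- max(3 * pitch, pitch)
  fit <- gauss_const_fit(pos, val,
                         c(a = a0, m = pos[which.max(val)], s = s0,
                           b = b0),
                         lower = c(0, min(pos), pitch / 10, 0),
                         upper = c(Inf, max(pos), diff(range(pos)), Inf))
  if (!fit$converged) {
    stop("profile fit failed: ", fit$message, "\nprofile: ",
         paste(signif(val, 4), collapse = " "), call. = FALSE)
  }
  cf <- fit$coefficients
  fwhm <- 2 * sqrt(2 * log(2)) * unname(cf["s"])
  structure(list(axis = axis, positions_mm = pos, values = val,
                 centroid_mm = unname(cf["m"]), sigma_mm = unname(cf["s"]),
                 fwhm_mm = fwhm, under_resolved = fwhm < pitch,
                 fit_window = range(pos), fit = fit),
            class = "profile_fit")
}

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf("<profile_fit> %s profile: centroid %.2f mm, FWHM %.2f mm%s\n",
              x$axis, x$centroid_mm, x$fwhm_mm,
              if (x$under_resolved) " (under-resolved)" else ""))
  invisible(x)
}

#' Triple-coincidence detection efficiency
#'
#' Headline number: triples per 1275 keV photon geometrically incident on
#' the first detector layer -- the definition under which the measured
#' interaction chain reproduces the printed efficiency of the prototype
#' (see the methods vignette for the analysis behind this choice). The
#' per-4-pi-emitted, per-decay and sum-windowed variants are reported
#' alongside so alternative definitions are inspectable. The binomial
#' standard error refers to the headline number.
#'
#' @param counts The `counts` list returned by [run_experiment()] (or any
#'   list providing `n_emitted_1275_equivalent`, `n_incident_1275`,
#'   `n_triples`, `n_decays_equivalent`).
#' @param triples Optional triples tibble of the same run, used for the
#'   sum-windowed variant.
#' @param sum_window Sum-energy window for the windowed variant, keV.
#' @return Tibble of class `efficiency_report` with `n_decays`,
#'   `n_emitted_1275`, `n_incident_1275`, `n_triples`,
#'   `n_triples_in_window`, `efficiency_per_incident_1275`,
#'   `efficiency_per_emitted_1275`, `efficiency_per_decay`,
#'   `efficiency_windowed`, `binomial_sigma`.
#' @export
compute_efficiency <- function(counts, triples = NULL,
                               sum_window = c(800, 1400)) {
  n_em <- counts$n_emitted_1275_equivalent
  n_inc <- counts$n_incident_1275 %||% NA_real_
  n_tr <- counts$n_triples
  stopifnot(n_em >= 0, n_tr >= 0)
  if (n_tr > n_em) stop("more triples than emitted photons: mismatched run",
                        call. = FALSE)
  n_win <- if (is.null(triples)) NA_integer_ else
    sum(triples$total_kev >= sum_window[1] &
          triples$total_kev <= sum_window[2])
  eff_inc <- if (!is.na(n_inc) && n_inc > 0) n_tr / n_inc else NA_real_
  eff_em <- if (n_em > 0) n_tr / n_em else 0
  sig <- if (!is.na(eff_inc)) sqrt(eff_inc * (1 - eff_inc) / n_inc) else 0
  structure(tibble::tibble(
    n_decays = counts$n_decays_equivalent,
    n_emitted_1275 = n_em, n_incident_1275 = n_inc, n_triples = n_tr,
    n_triples_in_window = n_win,
    efficiency_per_incident_1275 = eff_inc,
    efficiency_per_emitted_1275 = eff_em,
    efficiency_per_decay = if (counts$n_decays_equivalent > 0)
      n_tr / counts$n_decays_equivalent else 0,
    efficiency_windowed = if (n_em > 0 && !is.na(n_win)) n_win / n_em else
      NA_real_,
    binomial_sigma = sig),
    class = c("efficiency_report", class(tibble::tibble())))
}
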