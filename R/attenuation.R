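#' Linear attenuation coefficients for LaBr3
#'
#' Embedded table of Compton and photoelectric linear attenuation
#' coefficients for LaBr3 (density 5.08 g/cm^3, Z/A = 162/378.617), covering
#' 30-2000 keV. The Compton column is the exact Klein-Nishina total
#' cross-section times the electron density, so free-path sampling is
#' consistent with the package's angular sampling. The photoelectric column
#' is semi-empirical: classic above-K-edge lead photoelectric values scaled
#' to La and Br by Z^4.5 and the atomic-mass ratio, then mass-weighted
#' (La and Br K edges lie below 30 keV, so the curve is edge-free over the
#' table range). Accuracy: few percent on the Compton part above 200 keV,
#' roughly 10-30 percent on the (sub-dominant above 300 keV) photoelectric
#' part -- adequate for design-study work. Rayleigh scattering and pair
#' production are deliberately not modelled.
#'
#' @return An [attenuation_table()] for LaBr3.
#' @export
labr3_attenuation <- function() {
  tab <- tibble::tribble(
    ~energy_kev, ~mu_compton_mm, ~mu_pe_mm,
      30, 0.0782103, 8.50759,
      40, 0.0757552, 3.97544,
      50, 0.0734997, 2.20338,
      60, 0.0714201, 1.36045,
      80, 0.0677112, 0.635711,
     100, 0.0644994, 0.352342,
     150, 0.0580667, 0.120576,
     200, 0.0532074, 0.055595,
     300, 0.0462657, 0.0190611,
     400, 0.0414525, 0.00887948,
     500, 0.0378511, 0.00490969,
     600, 0.0350147, 0.00323975,
     800, 0.0307556, 0.00168127,
    1000, 0.0276465, 0.00101082,
    1275, 0.0244647, 0.000589098,
    1500, 0.0224589, 0.000410515,
    2000, 0.0191580, 0.000216604
  )
  attenuation_table(tab, material_name = "LaBr3")
}

#' Construct an attenuation table
#'
#' @param tab A data frame with columns `energy_kev` (strictly ascending),
#'   `mu_compton_mm` and `mu_pe_mm` (linear attenuation coefficients in
#'   mm^-1, all > 0).
#' @param material_name Label for the material.
#' @return A tibble of class `attenuation_table`.
#' @export
attenuation_table <- function(tab, material_name = "unknown") {
  tab <- tibble::as_tibble(tab)
  stopifnot(all(c("energy_kev", "mu_compton_mm", "mu_pe_mm") %in% names(tab)))
  if (any(diff(tab$energy_kev) <= 0)) {
    stop("energies must be strictly ascending", call. = FALSE)
  }
  if (any(tab$mu_compton_mm <= 0) || any(tab$mu_pe_mm <= 0)) {
    stop("all attenuation coefficients must be > 0", call. = FALSE)
  }
  structure(tab,
            class = c("attenuation_table", class(tibble::tibble())),
            material_name = material_name)
}

#' Interpolate an attenuation coefficient
#'
#' Log-log linear interpolation between the table nodes; exact at the nodes.
#'
#' @param table An [attenuation_table()].
#' @param e Photon energy (keV), within the table range. Vectorized.
#' @param process One of `"compton"`, `"photoelectric"`, `"total"`.
#' @return Linear attenuation coefficient(s) in mm^-1.
#' @export
mu <- function(table, e, process = c("total", "compton", "photoelectric")) {
  process <- match.arg(process)
  rng <- range(table$energy_kev)
  if (any(e < rng[1] | e > rng[2])) {
    stop("energy outside attenuation table range [", rng[1], ", ", rng[2],
         "] keV", call. = FALSE)
  }
  le <- log(table$energy_kev)
  interp <- function(col) {
    exp(stats::approx(le, log(col), xout = log(e))$y)
  }
  switch(process,
         compton = interp(table$mu_compton_mm),
         photoelectric = interp(table$mu_pe_mm),
         total = interp(table$mu_compton_mm) + interp(table$mu_pe_mm))
}

#' Read or write an attenuation table as delimited text
#'
#' Plain CSV with columns `energy_kev`, `mu_compton_mm`, `mu_pe_mm`.
#'
#' @param table An [attenuation_table()].
#' @param path File path.
#' @return `read_attenuation()` returns an [attenuation_table()];
#'   `write_attenuation()` returns `path` invisibly.
#' @export
write_attenuation <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path)
  invisible(path)
}

#' @rdname write_attenuation
#' @param material_name Material label to attach on read.
#' @export
read_attenuation <- function(path, material_name = "unknown") {
  attenuation_table(readr::read_csv(path, show_col_types = FALSE),
                    material_name = material_name)
}
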